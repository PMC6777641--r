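# Fixture tables built in code. table1/table2 are the worked example inputs
# shipped in inst/extdata (phosphate dose-response, strigolactone-analog
# experiment); rebuilding them here keeps tests independent of extdata.

table1_df <- function() {
  data.frame(
    Samples = rep(c("Low phosphate", "Medium phosphate", "High phosphate"),
                  each = 7),
    Replicates = rep(LETTERS[1:7], 3),
    Total = c(88, 95, 87, 74, 95, 93, 80,
              79, 72, 52, 80, 53, 63, 62,
              21, 7, 5, 18, 7, 17, 2),
    Hyphopodia = c(4, 4, 6, 5, 3, 4, 4,
                   4, 3, 2, 4, 2, 4, 4,
                   2, 1, 1, 2, 1, 2, 0),
    IntrHyphae = c(88, 95, 87, 74, 95, 93, 80,
                   79, 72, 52, 80, 53, 63, 62,
                   21, 7, 5, 18, 7, 17, 2),
    Arbuscule = c(78, 76, 70, 62, 79, 85, 59,
                  61, 59, 40, 63, 41, 49, 48,
                  21, 5, 5, 18, 5, 11, 2),
    Vesicle = c(40, 35, 31, 27, 25, 41, 20,
                27, 20, 21, 29, 15, 25, 24,
                8, 2, 2, 6, 1, 2, 1),
    stringsAsFactors = FALSE
  )
}

table2_df <- function() {
  data.frame(
    Samples = c(rep("Control", 6), rep("GR24 10-7M", 6),
                rep("MP3 10-8M", 6), rep("MP1 10-7M", 6)),
    Replicates = as.character(c(1, 1, 1, 2, 2, 2,
                                1, 1, 1, 2, 2, 3,
                                1, 1, 1, 2, 2, 2,
                                1, 1, 1, 2, 2, 2)),
    Scoring = c("3A3", "5A3", "3A3", "4A3", "2A3", "2A3",
                "3A3", "3A3", "3A3", "5A3", "5A3", "5A3",
                "4A3", "5A3", "4A3", "3A2", "5A3", "5A3",
                "3A2", "5A2", "1A2", "3A2", "2A3", "2A3"),
    stringsAsFactors = FALSE
  )
}

write_csv_fixture <- function(df, path = tempfile(fileext = ".csv")) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

read_grid_df <- function(df, ...) {
  read_colonization_table(write_csv_fixture(df), "grid", ...)
}

read_trouvelot_df <- function(df, ...) {
  read_colonization_table(write_csv_fixture(df), "trouvelot", ...)
}

table1_ds <- function() read_grid_df(table1_df())
table2_ds <- function() read_trouvelot_df(table2_df())

# minimal code -> (myc, arb) table for feeding tally_classes in tests
parse_scores_df <- function(codes) {
  codes <- toupper(codes)
  data.frame(
    myc_class = ifelse(codes == "0", 0L, as.integer(substr(codes, 1, 1))),
    arb_class = ifelse(codes == "0", 0L, as.integer(substr(codes, 3, 3)))
  )
}

# random valid class tallies for property tests
random_tally <- function() {
  n <- sample(1:40, 1)
  myc <- sample(0:5, n, replace = TRUE)
  arb <- ifelse(myc == 0, 0, sample(0:3, n, replace = TRUE))
  tally_classes(data.frame(myc_class = myc, arb_class = arb))
}
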