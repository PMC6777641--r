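# Reading, validation and CSV export of colonization tables.
#
# Two input dialects share the first two columns (Samples, Replicates):
#   grid      — one column per scored structure, values are percentages;
#   trouvelot — a single Scoring column of fragment score codes.
# The first sample (file order) is the experimental control. Rows sharing
# (sample, replicate) are technical replicates of one biological replicate.

trouvelot_score_pattern <- "^(0|[1-5]A[0-3])$"

canonical_name <- function(x) {
  canon <- c(ID_COLUMNS, GRID_VARIABLES, "Scoring", "trt")
  idx <- match(tolower(trimws(x)), tolower(canon))
  out <- canon[idx]
  out[is.na(idx)] <- trimws(x)[is.na(idx)]
  out
}

allowed_columns <- function(scoring_type) {
  switch(scoring_type,
    grid = c(ID_COLUMNS, GRID_VARIABLES, "trt"),
    trouvelot = c(ID_COLUMNS, "Scoring", "trt")
  )
}

required_columns <- function(scoring_type) {
  switch(scoring_type,
    grid = ID_COLUMNS,
    trouvelot = c(ID_COLUMNS, "Scoring")
  )
}

#' Validate raw colonization records
#'
#' Runs the full quality check on a parsed table before it becomes a dataset:
#' (1) the table has at least one data row, (2) column names belong to the
#' dialect and the required ones are present, (3) no cell is empty or NA,
#' (4) grid values are numeric percentages in \[0, 100\],
#' (5) Trouvelot score codes match the score grammar (\code{"0"} or
#' \code{"<class>A<arbuscule>"} with class 1--5 and arbuscule 0--3).
#' All issues are collected, not just the first.
#'
#' @param records data frame of raw (character) cells with a header-derived
#'   set of column names; typically produced by reading a CSV with all
#'   columns as character.
#' @param scoring_type \code{"grid"} or \code{"trouvelot"}.
#' @return An object of class \code{am_validation}: a list with \code{ok}
#'   (logical) and \code{issues}, a data frame with columns \code{row}
#'   (1-based file row, the header counting as row 1), \code{column} and
#'   \code{message}. \code{ok} is \code{TRUE} iff \code{issues} is empty.
#' @examples
#' rec <- data.frame(Samples = "wt", Replicates = "A", Total = "88")
#' am_validate(rec, "grid")$ok
#' @export
am_validate <- function(records, scoring_type = c("grid", "trouvelot")) {
  scoring_type <- match.arg(scoring_type)
  issues <- list()
  add <- function(row, column, message) {
    issues[[length(issues) + 1L]] <<- data.frame(
      row = as.integer(row), column = column, message = message,
      stringsAsFactors = FALSE
    )
  }

  names(records) <- canonical_name(names(records))

  # 1. dimensions
  if (nrow(records) == 0L) {
    add(NA_integer_, NA_character_, "empty dataset: no data rows")
  }

  # 2. column names
  missing_cols <- setdiff(required_columns(scoring_type), names(records))
  for (col in missing_cols) {
    add(1L, col, sprintf("missing required column '%s'", col))
  }
  unknown <- setdiff(names(records), allowed_columns(scoring_type))
  for (col in unknown) {
    add(1L, col, sprintf(
      "unknown column '%s' for scoring type '%s' (allowed: %s)",
      col, scoring_type, paste(allowed_columns(scoring_type), collapse = ", ")
    ))
  }
  if (scoring_type == "grid" &&
      length(intersect(GRID_VARIABLES, names(records))) == 0L &&
      nrow(records) > 0L) {
    add(1L, NA_character_, sprintf(
      "no variable column present; expected at least one of: %s",
      paste(GRID_VARIABLES, collapse = ", ")
    ))
  }

  present <- intersect(allowed_columns(scoring_type), names(records))

  # 3. empty / NA cells
  for (col in present) {
    cells <- trimws(as.character(records[[col]]))
    bad <- which(is.na(cells) | cells == "" | toupper(cells) == "NA")
    for (i in bad) add(i + 1L, col, "empty or NA cell")
  }

  # 4. grid values numeric and within [0, 100]
  if (scoring_type == "grid") {
    for (col in intersect(GRID_VARIABLES, present)) {
      cells <- trimws(as.character(records[[col]]))
      num <- suppressWarnings(as.numeric(cells))
      nonnum <- which(!is.na(cells) & cells != "" & toupper(cells) != "NA" &
                        is.na(num))
      for (i in nonnum) {
        add(i + 1L, col, sprintf("non-numeric value '%s'", cells[i]))
      }
      oob <- which(!is.na(num) & (num < 0 | num > 100 | !is.finite(num)))
      for (i in oob) {
        add(i + 1L, col,
            sprintf("value %s outside the percentage range [0, 100]", cells[i]))
      }
    }
  }

  # 5. trouvelot score grammar
  if (scoring_type == "trouvelot" && "Scoring" %in% present) {
    codes <- toupper(trimws(as.character(records[["Scoring"]])))
    bad <- which(!is.na(codes) & codes != "" & codes != "NA" &
                   !grepl(trouvelot_score_pattern, codes))
    for (i in bad) {
      add(i + 1L, "Scoring", sprintf(
        "invalid score code '%s' (expected '0' or '<1-5>A<0-3>')",
        trimws(as.character(records[["Scoring"]]))[i]
      ))
    }
  }

  issues <- if (length(issues)) do.call(rbind, issues) else
    data.frame(row = integer(), column = character(), message = character(),
               stringsAsFactors = FALSE)
  structure(list(ok = nrow(issues) == 0L, issues = issues),
            class = "am_validation")
}

#' @export
print.am_validation <- function(x, ...) {
  if (x$ok) {
    cat("Validation passed: no issues.\n")
  } else {
    cat(sprintf("Validation failed: %d issue(s)\n", nrow(x$issues)))
    for (i in seq_len(nrow(x$issues))) {
      cat(sprintf("  row %s, column %s: %s\n",
                  x$issues$row[i], x$issues$column[i], x$issues$message[i]))
    }
  }
  invisible(x)
}

new_am_dataset <- function(df, scoring_type) {
  sample_order <- unique(as.character(df$Samples))
  structure(df,
            class = c(paste0("am_", scoring_type), "am_dataset", "data.frame"),
            scoring_type = scoring_type,
            sample_order = sample_order)
}

#' Order of samples in a dataset
#'
#' Samples appear in first-appearance file order; the first one is the
#' control used by asterisk annotation.
#'
#' @param ds an \code{am_dataset}.
#' @return Character vector of unique sample labels.
#' @export
sample_order <- function(ds) attr(ds, "sample_order")

#' Scoring type of a dataset
#' @param ds an \code{am_dataset}.
#' @return \code{"grid"} or \code{"trouvelot"}.
#' @export
scoring_type <- function(ds) attr(ds, "scoring_type")

#' Read a colonization table
#'
#' Reads a delimited text file (or text connection) holding either a
#' gridline-intersect table (columns \code{Samples, Replicates} plus any of
#' \code{Total, Hyphopodia, IntrHyphae, Arbuscule, Vesicle}, percentage
#' values) or a Trouvelot table (\code{Samples, Replicates, Scoring} with
#' codes such as \code{"3A2"}). Header names are matched case-insensitively
#' after trimming. An optional \code{trt} column (second experimental factor,
#' used by \code{\link{anova_two_way}}) is accepted in both dialects; any
#' other column is rejected. The read is atomic: if validation fails no
#' dataset is returned and every issue is reported in the error message.
#'
#' @param source path to a file, or a connection.
#' @param scoring_type \code{"grid"} or \code{"trouvelot"}.
#' @param delim field delimiter, comma by default.
#' @return An \code{am_dataset}: a data frame with canonical column names,
#'   rows in file order, and attributes \code{scoring_type} and
#'   \code{sample_order} (unique samples in first-appearance order; the
#'   first is the control).
#' @examples
#' path <- system.file("extdata", "grid_phosphate.csv", package = "amquant")
#' ds <- read_colonization_table(path, "grid")
#' sample_order(ds)
#' @export
read_colonization_table <- function(source, scoring_type = c("grid", "trouvelot"),
                                    delim = ",") {
  scoring_type <- match.arg(scoring_type)
  raw <- read.csv(source, sep = delim, colClasses = "character",
                  check.names = FALSE, strip.white = TRUE,
                  blank.lines.skip = TRUE)
  names(raw) <- canonical_name(names(raw))

  report <- am_validate(raw, scoring_type)
  if (!report$ok) {
    msgs <- sprintf("row %s, column %s: %s", report$issues$row,
                    report$issues$column, report$issues$message)
    stop(sprintf("invalid %s table (%d issue(s)):\n  %s", scoring_type,
                 nrow(report$issues), paste(msgs, collapse = "\n  ")),
         call. = FALSE)
  }

  keep <- intersect(allowed_columns(scoring_type), names(raw))
  df <- raw[, keep, drop = FALSE]
  df$Samples <- trimws(df$Samples)
  df$Replicates <- trimws(df$Replicates)
  if (scoring_type == "grid") {
    for (col in intersect(GRID_VARIABLES, names(df))) {
      df[[col]] <- as.numeric(df[[col]])
    }
  } else {
    df$Scoring <- toupper(trimws(df$Scoring))
  }
  if ("trt" %in% names(df)) df$trt <- trimws(df$trt)
  rownames(df) <- NULL
  new_am_dataset(df, scoring_type)
}

#' @export
print.am_dataset <- function(x, ...) {
  cat(sprintf("Colonization dataset (%s scoring): %d record(s), %d sample(s)\n",
              scoring_type(x), nrow(x), length(sample_order(x))))
  cat("Samples (first = control):", paste(sample_order(x), collapse = ", "),
      "\n\n")
  print.data.frame(x, ...)
  invisible(x)
}

format_numeric_cols <- function(df, digits = 6) {
  for (col in names(df)) {
    if (is.numeric(df[[col]])) df[[col]] <- round(df[[col]], digits)
  }
  df
}

#' Write the per-replicate and per-sample summary tables
#'
#' Writes \code{<basename>_per_Replicate.csv} and
#' \code{<basename>_per_Sample.csv} (comma-delimited, header row, UTF-8,
#' numbers rounded to 6 decimals).
#'
#' @param summary an \code{am_summary_tables} object from
#'   \code{\link{am_summary}}.
#' @param basename output path prefix, e.g. \code{"Exp001"}.
#' @return Invisibly, the two file paths (named \code{per_replicate},
#'   \code{per_sample}).
#' @export
write_summary_tables <- function(summary, basename) {
  stopifnot(inherits(summary, "am_summary_tables"))
  paths <- c(per_replicate = paste0(basename, "_per_Replicate.csv"),
             per_sample = paste0(basename, "_per_Sample.csv"))
  write.csv(format_numeric_cols(summary$per_replicate), paths[["per_replicate"]],
            row.names = FALSE, fileEncoding = "UTF-8")
  write.csv(format_numeric_cols(summary$per_sample), paths[["per_sample"]],
            row.names = FALSE, fileEncoding = "UTF-8")
  invisible(paths)
}

#' Write the pairwise statistics table
#'
#' Writes \code{<basename>_stat.csv}: the first two columns name the
#' compared sample pair, the remaining columns hold the (adjusted) p value
#' for each variable.
#'
#' @param stat an \code{am_comparison} object from \code{\link{am_stat}}.
#' @param basename output path prefix.
#' @return Invisibly, the file path.
#' @export
write_stat_table <- function(stat, basename) {
  stopifnot(inherits(stat, "am_comparison"))
  path <- paste0(basename, "_stat.csv")
  write.csv(format_numeric_cols(comparison_wide(stat)), path,
            row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
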