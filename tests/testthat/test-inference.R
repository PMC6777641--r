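test_that("rank_midties implements the midrank convention", {
  expect_equal(rank_midties(c(10, 20, 30)), c(1, 2, 3))
  expect_equal(rank_midties(c(5, 5, 9)), c(1.5, 1.5, 3))
  set.seed(2)
  for (i in 1:20) {
    x <- sample(1:8, sample(3:30, 1), replace = TRUE)
    r <- rank_midties(x)
    expect_equal(sum(r), length(x) * (length(x) + 1) / 2)
    expect_equal(r, rank(x))   # base R midrank as reference
  }
})

test_that("kruskal_wallis matches the reference implementation", {
  # all group configurations with total N <= 8, random tied-ish data
  set.seed(31)
  for (k in 2:4) {
    for (rep in 1:15) {
      sizes <- sample(1:4, k, replace = TRUE)
      if (sum(sizes) > 8 || sum(sizes) < 3) next
      groups <- lapply(sizes, function(n) sample(1:5, n, replace = TRUE))
      if (length(unique(unlist(groups))) == 1L) next
      res <- kruskal_wallis(groups)
      ora <- oracle_kw(groups)
      expect_equal(res$H, ora$H, tolerance = 1e-12)
      expect_equal(res$p, ora$p, tolerance = 1e-12)
    }
  }
})

test_that("kruskal_wallis handles degenerate and strong-signal inputs", {
  same <- kruskal_wallis(list(c(1, 2, 3), c(1, 2, 3)))
  expect_equal(oracle_kw(list(c(1, 2, 3), c(1, 2, 3)))$H, same$H,
               tolerance = 1e-12)

  const <- kruskal_wallis(list(c(4, 4), c(4, 4, 4)))
  expect_equal(const$H, 0)
  expect_equal(const$p, 1)

  expect_error(kruskal_wallis(list(1:3)), "at least 2 groups")

  df <- table1_df()
  groups <- split(df$Total, df$Samples)[unique(df$Samples)]
  res <- kruskal_wallis(groups)
  expect_gt(res$H, 15)
  expect_lt(res$p, 0.001)
  expect_equal(res$H, oracle_kw(groups)$H, tolerance = 1e-12)
})

test_that("kruskal_wallis is invariant under strictly monotone transforms", {
  set.seed(13)
  groups <- lapply(1:3, function(i) runif(6) * 10 + i)
  h0 <- kruskal_wallis(groups)$H
  expect_equal(kruskal_wallis(lapply(groups, exp))$H, h0)
  expect_equal(kruskal_wallis(lapply(groups, function(x) x^3))$H, h0)
})

test_that("chi-square approximation tracks the exact permutation null", {
  # logged comparison on a 2 x 3 design; the approximation is coarse at
  # this size, so only sanity bounds are asserted
  g1 <- c(1.2, 3.4, 2.2)
  g2 <- c(5.6, 4.8, 7.1)
  p_perm <- oracle_kw_permutation_p(g1, g2)
  p_chisq <- kruskal_wallis(list(g1, g2))$p
  expect_true(abs(p_perm - p_chisq) < 0.1)
})

test_that("pairwise rank-LSD matches hand arithmetic and is symmetric", {
  df <- table1_df()
  groups <- split(df$Total, df$Samples)[unique(df$Samples)]
  cmp <- pairwise_lsd_on_ranks(groups)
  expect_equal(nrow(cmp), 3L)
  expect_equal(cmp$sample_i[1], "Low phosphate")  # ordering follows input

  # hand arithmetic oracle for one pair
  r <- rank(unlist(groups))
  g <- rep(seq_along(groups), lengths(groups))
  Rbar <- tapply(r, g, mean)
  N <- length(r); k <- 3
  H <- oracle_kw(groups)$H
  S2 <- sum((r - mean(r))^2) / (N - 1)
  tval <- abs(Rbar[1] - Rbar[3]) /
    sqrt(S2 * (N - 1 - H) / (N - k) * (1 / 7 + 1 / 7))
  p_hand <- 2 * stats::pt(-tval, N - k)
  p_pkg <- cmp$p[cmp$sample_i == "Low phosphate" &
                   cmp$sample_j == "High phosphate"]
  expect_equal(p_pkg, unname(p_hand), tolerance = 1e-12)
  expect_lt(p_pkg, 0.01)

  # symmetry: reversing group order gives the same p for the same pair
  cmp_rev <- pairwise_lsd_on_ranks(rev(groups))
  expect_equal(sort(cmp$p), sort(cmp_rev$p), tolerance = 1e-12)

  # identical values everywhere -> all p = 1
  flat <- pairwise_lsd_on_ranks(list(a = c(3, 3), b = c(3, 3), c = c(3, 3)))
  expect_equal(flat$p, rep(1, 3))

  expect_error(pairwise_lsd_on_ranks(list(a = 1, b = 2)),
               "residual degrees of freedom")
})

test_that("adjust_pvalues implements the standard corrections", {
  expect_equal(adjust_pvalues(c(0.01, 0.02, 0.03), "bonferroni"),
               c(0.03, 0.06, 0.09))
  expect_equal(adjust_pvalues(c(0.01, 0.02, 0.03), "BH"),
               c(0.03, 0.03, 0.03))
  expect_equal(adjust_pvalues(c(0.01, 0.02, 0.03), "none"),
               c(0.01, 0.02, 0.03))
  expect_equal(adjust_pvalues(c(0.5, 0.9), "bonferroni"), c(1, 1))  # clipped
  expect_equal(adjust_pvalues(c(0.04, 0.01), "fdr"),
               adjust_pvalues(c(0.04, 0.01), "BH"))
  expect_error(adjust_pvalues(0.5, "tukey"), "holm")

  set.seed(77)
  for (i in 1:50) {
    p <- runif(sample(2:10, 1))
    expect_true(all(adjust_pvalues(p, "holm") >= p))
    expect_true(all(adjust_pvalues(p, "bonferroni") >=
                      adjust_pvalues(p, "holm") - 1e-12))
    expect_true(all(adjust_pvalues(p, "holm") >=
                      adjust_pvalues(p, "hochberg") - 1e-12))
  }
})

test_that("am_stat tests each variable independently with per-family adjustment", {
  cmp <- am_stat(table1_ds(), method = "fdr")
  expect_equal(nrow(cmp), 3L * 5L)
  expect_true(all(cmp$p_adj >= cmp$p_raw - 1e-12))
  wide <- comparison_wide(cmp)
  expect_equal(dim(wide), c(3L, 7L))

  cmp2 <- am_stat(table2_ds(), method = "fdr")
  expect_equal(nrow(comparison_wide(cmp2)), 6L)  # C(4,2)

  # permuting Vesicle never changes Total's p values
  df <- table1_df()
  set.seed(21)
  df$Vesicle <- sample(df$Vesicle)
  cmp3 <- am_stat(read_grid_df(df), method = "fdr")
  expect_equal(cmp3$p_adj[cmp3$variable == "Total"],
               cmp$p_adj[cmp$variable == "Total"])
  expect_false(isTRUE(all.equal(cmp3$p_adj[cmp3$variable == "Vesicle"],
                                cmp$p_adj[cmp$variable == "Vesicle"])))

  single <- read_grid_df(data.frame(Samples = "X", Replicates = c("1", "2"),
                                    Total = c(1, 2)))
  expect_error(am_stat(single), "at least 2 samples")
})

test_that("compact letter display obeys sharing iff non-significance", {
  cmp <- data.frame(sample_i = c("A", "A", "B"), sample_j = c("B", "C", "C"),
                    p_adj = c(0.001, 0.001, 0.8))
  expect_equal(compact_letter_display(cmp, alpha = 0.05),
               c(A = "a", B = "b", C = "b"))

  all_same <- data.frame(sample_i = c("A", "A", "B"),
                         sample_j = c("B", "C", "C"), p_adj = rep(1, 3))
  expect_equal(unname(compact_letter_display(all_same)), rep("a", 3))

  all_diff <- data.frame(sample_i = c("A", "A", "B"),
                         sample_j = c("B", "C", "C"), p_adj = rep(0, 3))
  expect_equal(compact_letter_display(all_diff), c(A = "a", B = "b", C = "c"))

  expect_error(compact_letter_display(cmp[1:2, ]), "incomplete pair coverage")
})

test_that("CLD is sound and complete for every pattern with k <= 4", {
  for (k in 2:4) {
    smp <- LETTERS[1:k]
    pairs <- t(utils::combn(k, 2))
    n_pairs <- nrow(pairs)
    for (mask in 0:(2^n_pairs - 1)) {
      sig <- as.logical(bitwAnd(mask, 2^(seq_len(n_pairs) - 1)))
      cmp <- data.frame(sample_i = smp[pairs[, 1]], sample_j = smp[pairs[, 2]],
                        p_adj = ifelse(sig, 0.001, 0.5))
      letters_map <- compact_letter_display(cmp, alpha = 0.05, samples = smp)
      expect_true(all(nchar(letters_map) >= 1))
      for (r in seq_len(n_pairs)) {
        share <- length(intersect(
          strsplit(letters_map[[smp[pairs[r, 1]]]], "")[[1]],
          strsplit(letters_map[[smp[pairs[r, 2]]]], "")[[1]])) > 0
        expect_equal(share, !sig[r],
                     info = sprintf("k=%d mask=%d pair=%d", k, mask, r))
      }
    }
  }
})

test_that("asterisks mark only significant non-control samples", {
  cmp <- data.frame(sample_i = c("ctl", "ctl", "X"),
                    sample_j = c("X", "Y", "Y"),
                    p_adj = c(0.03, 0.005, 0.5))
  expect_equal(asterisks_vs_control(cmp, "ctl", alpha = 0.01),
               c(ctl = "", X = "", Y = "*"))   # 0.03 not flagged at 0.01
  expect_equal(asterisks_vs_control(cmp, "ctl", alpha = 0.05),
               c(ctl = "", X = "*", Y = "*"))
  expect_error(asterisks_vs_control(cmp, "Z"), "absent")
})

test_that("one-way analysis is the am_stat alias plus omnibus results", {
  a1 <- anova_one_way(table1_ds(), method = "fdr")
  expect_equal(as.data.frame(a1$pairwise),
               as.data.frame(am_stat(table1_ds(), method = "fdr")))
  expect_lt(a1$omnibus$p[a1$omnibus$variable == "Total"], 0.001)

  flat <- read_grid_df(data.frame(Samples = rep(c("A", "B"), each = 3),
                                  Replicates = rep(1:3, 2), Total = rep(7, 6)))
  expect_equal(anova_one_way(flat)$omnibus$p, 1)
})

test_that("two-way ANOVA recovers closed-form sums of squares", {
  # balanced 2x2, additive effects, no noise
  df <- expand.grid(Samples = c("wt", "mut"), trt = c("sand", "clay"),
                    Replicates = c("1", "2"), stringsAsFactors = FALSE)
  effect_s <- ifelse(df$Samples == "wt", 10, -10)
  effect_t <- ifelse(df$trt == "sand", 5, -5)
  df$Total <- 50 + effect_s + effect_t
  ds <- read_grid_df(df[, c("Samples", "Replicates", "trt", "Total")])
  # zero-noise designs make stats::anova warn about a perfect fit; expected
  res <- suppressWarnings(anova_two_way(ds))
  tab <- res$Total$table
  # SS = n * effect^2 summed over levels
  expect_equal(tab$sum_sq[tab$term == "sample"], 8 * 10^2, tolerance = 1e-9)
  expect_equal(tab$sum_sq[tab$term == "trt"], 8 * 5^2, tolerance = 1e-9)
  expect_equal(tab$sum_sq[tab$term == "sample:trt"], 0, tolerance = 1e-9)
  expect_equal(sum(tab$df), nrow(df) - 1)

  # identical cell values: residual SS 0, F flagged NA
  df$Total <- 42
  res2 <- suppressWarnings(
    anova_two_way(read_grid_df(df[, c("Samples", "Replicates",
                                      "trt", "Total")])))
  expect_equal(res2$Total$table$sum_sq[4], 0, tolerance = 1e-9)
  expect_true(all(is.na(res2$Total$table$F)))

  # diagnostics contract
  expect_equal(nrow(res$Total$qq), nrow(df))
  expect_false(is.unsorted(res$Total$qq$sample))
  expect_equal(nrow(res$Total$diagnostics), nrow(df))

  expect_error(anova_two_way(table1_ds()), "'trt' column")
})
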