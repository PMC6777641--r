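# Per-variable nonparametric inference: Kruskal-Wallis omnibus, rank-based
# Fisher-LSD pairwise comparisons, p-value adjustment, and the plot
# annotations (compact letter display, asterisks vs control).
#
# Colonization percentages are bounded and often skewed, so the default
# analysis is rank-based throughout. Every test is run independently per
# variable: a p value for arbuscules says nothing about vesicles.

ADJUST_METHODS <- c("none", "holm", "hommel", "hochberg", "bonferroni",
                    "BH", "BY", "fdr")

#' Midrank (average-tie) ranking
#'
#' Ranks a numeric vector, assigning tied values the mean of the ranks they
#' span, so ranks always sum to N(N+1)/2.
#'
#' @param values numeric vector, finite, non-empty.
#' @return Numeric vector of ranks.
#' @examples
#' rank_midties(c(5, 5, 9))  # 1.5 1.5 3
#' @export
rank_midties <- function(values) {
  stopifnot(length(values) >= 1L, all(is.finite(values)))
  o <- order(values)
  sorted <- values[o]
  ranks_sorted <- numeric(length(values))
  i <- 1L
  while (i <= length(sorted)) {
    j <- i
    while (j < length(sorted) && sorted[j + 1L] == sorted[i]) j <- j + 1L
    ranks_sorted[i:j] <- (i + j) / 2
    i <- j + 1L
  }
  ranks <- numeric(length(values))
  ranks[o] <- ranks_sorted
  ranks
}

#' Kruskal-Wallis omnibus test
#'
#' Rank-based k-sample test with the standard ties correction
#' \eqn{H / (1 - \sum(t^3 - t)/(N^3 - N))}; the p value comes from the
#' chi-square upper tail with k-1 degrees of freedom. When every observation
#' is identical the statistic is defined as 0 with p = 1.
#'
#' @param groups list of numeric vectors, one per sample (>= 2 groups, each
#'   non-empty).
#' @return List of class \code{am_kw} with \code{H}, \code{df}, \code{p}.
#' @export
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L) {
    stop("kruskal_wallis() needs at least 2 groups", call. = FALSE)
  }
  sizes <- lengths(groups)
  stopifnot(all(sizes >= 1L))
  x <- unlist(groups, use.names = FALSE)
  N <- length(x)
  k <- length(groups)
  if (length(unique(x)) == 1L) {
    return(structure(list(H = 0, df = k - 1L, p = 1), class = "am_kw"))
  }
  r <- rank_midties(x)
  g <- rep(seq_along(groups), sizes)
  Rbar <- tapply(r, g, mean)
  H <- 12 / (N * (N + 1)) * sum(sizes * Rbar^2) - 3 * (N + 1)
  ties <- table(x)
  H <- H / (1 - sum(ties^3 - ties) / (N^3 - N))
  structure(list(H = unname(H), df = k - 1L,
                 p = pchisq(unname(H), k - 1L, lower.tail = FALSE)),
            class = "am_kw")
}

#' @export
print.am_kw <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis: H = %.4f, df = %d, p = %.4g\n", x$H, x$df, x$p))
  invisible(x)
}

#' Pairwise Fisher-LSD comparisons on ranks
#'
#' After a Kruskal-Wallis omnibus, each pair of samples is compared on the
#' pooled midranks with the least-significant-difference criterion:
#' \deqn{t_{ij} = |\bar R_i - \bar R_j| \Big/
#'   \sqrt{S^2 \frac{N-1-H}{N-k}\left(\frac1{n_i}+\frac1{n_j}\right)}}
#' where \eqn{S^2} is the (ties-respecting) sample variance of the pooled
#' ranks and \eqn{H} the omnibus statistic; p values are two-sided from the
#' t distribution with N-k degrees of freedom. This is the conventional
#' rank-based LSD procedure of agricultural statistics.
#'
#' @param groups list of numeric vectors, one per sample; names (if any) are
#'   used as sample labels.
#' @return Data frame with one row per unordered pair, in sample order:
#'   columns \code{sample_i}, \code{sample_j}, \code{p}.
#' @export
pairwise_lsd_on_ranks <- function(groups) {
  kw <- kruskal_wallis(groups)
  labels <- names(groups) %||% as.character(seq_along(groups))
  sizes <- lengths(groups)
  N <- sum(sizes)
  k <- length(groups)
  if (N - k <= 0L) {
    stop("no residual degrees of freedom (N - k <= 0): ",
         "need more than one observation overall beyond the group count",
         call. = FALSE)
  }
  r <- rank_midties(unlist(groups, use.names = FALSE))
  g <- rep(seq_along(groups), sizes)
  Rbar <- tapply(r, g, mean)
  S2 <- var(r)
  deflate <- (N - 1 - kw$H) / (N - k)

  pairs <- which(upper.tri(diag(k)), arr.ind = TRUE)
  pairs <- pairs[order(pairs[, "row"], pairs[, "col"]), , drop = FALSE]
  p <- apply(pairs, 1L, function(ij) {
    i <- ij[[1L]]; j <- ij[[2L]]
    se <- sqrt(S2 * deflate * (1 / sizes[i] + 1 / sizes[j]))
    diff <- abs(Rbar[i] - Rbar[j])
    if (!is.finite(se) || se == 0) {
      if (diff == 0) 1 else 0
    } else {
      2 * pt(-diff / se, df = N - k)
    }
  })
  data.frame(sample_i = labels[pairs[, 1L]], sample_j = labels[pairs[, 2L]],
             p = as.numeric(p), stringsAsFactors = FALSE)
}

#' Adjust p values for multiple testing
#'
#' Supported methods: none, holm, hommel, hochberg, bonferroni, BH
#' (Benjamini-Hochberg), BY (Benjamini-Yekutieli) and fdr (alias of BH).
#' Method names are matched case-insensitively; results are clipped to
#' \[0, 1\] and returned in input order.
#'
#' @param p numeric vector of p values in \[0, 1\].
#' @param method adjustment method name.
#' @return Adjusted p values.
#' @examples
#' adjust_pvalues(c(0.01, 0.02, 0.03), "BH")
#' @export
adjust_pvalues <- function(p, method = "none") {
  stopifnot(is.numeric(p), all(p >= 0 & p <= 1))
  idx <- match(tolower(method), tolower(ADJUST_METHODS))
  if (length(method) != 1L || is.na(idx)) {
    stop(sprintf("unknown adjustment method '%s'; valid methods: %s",
                 paste(method, collapse = ","),
                 paste(ADJUST_METHODS, collapse = ", ")), call. = FALSE)
  }
  pmin(1, pmax(0, stats::p.adjust(p, method = ADJUST_METHODS[idx])))
}

#' Per-variable pairwise statistics for a colonization dataset
#'
#' Collapses the dataset to biological-replicate values (grid variables, or
#' the Trouvelot indices F, M, m, a, A), then for each variable runs
#' \code{\link{pairwise_lsd_on_ranks}} over the samples and adjusts the
#' resulting p values within that variable's family of pairwise comparisons.
#' Families are never pooled across variables: each structure or index is
#' tested on its own.
#'
#' @param ds an \code{am_dataset} with at least two samples.
#' @param method adjustment method (see \code{\link{adjust_pvalues}}).
#' @return An object of class \code{am_comparison}: a long data frame with
#'   columns \code{sample_i}, \code{sample_j}, \code{variable},
#'   \code{p_raw}, \code{p_adj}, plus attributes \code{method},
#'   \code{sample_order} and \code{variables}. Use
#'   \code{\link{comparison_wide}} for the one-row-per-pair layout.
#' @examples
#' path <- system.file("extdata", "grid_phosphate.csv", package = "amquant")
#' am_stat(read_colonization_table(path, "grid"), method = "fdr")
#' @export
am_stat <- function(ds, method = "none") {
  stopifnot(inherits(ds, "am_dataset"))
  samples <- sample_order(ds)
  if (length(samples) < 2L) {
    stop("statistical comparison needs at least 2 samples", call. = FALSE)
  }
  per_rep <- replicate_values(ds)
  vars <- setdiff(names(per_rep), c(ID_COLUMNS, "trt"))

  blocks <- lapply(vars, function(v) {
    groups <- lapply(samples, function(s) per_rep[[v]][per_rep$Samples == s])
    names(groups) <- samples
    cmp <- pairwise_lsd_on_ranks(groups)
    data.frame(sample_i = cmp$sample_i, sample_j = cmp$sample_j,
               variable = v, p_raw = cmp$p,
               p_adj = adjust_pvalues(cmp$p, method),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, blocks)
  rownames(out) <- NULL
  structure(out,
            class = c("am_comparison", "data.frame"),
            method = method, sample_order = samples, variables = vars)
}

#' Wide layout of a comparison table
#'
#' One row per sample pair; first two columns the pair, then one column of
#' adjusted p values per variable.
#'
#' @param cmp an \code{am_comparison}.
#' @return Data frame.
#' @export
comparison_wide <- function(cmp) {
  stopifnot(inherits(cmp, "am_comparison"))
  vars <- attr(cmp, "variables")
  key <- unique(data.frame(sample_i = cmp$sample_i, sample_j = cmp$sample_j,
                           stringsAsFactors = FALSE))
  out <- key
  for (v in vars) {
    sub <- cmp[cmp$variable == v, , drop = FALSE]
    out[[v]] <- sub$p_adj[match(paste(key$sample_i, key$sample_j, sep = "\r"),
                                paste(sub$sample_i, sub$sample_j, sep = "\r"))]
  }
  rownames(out) <- NULL
  out
}

#' @export
print.am_comparison <- function(x, ...) {
  cat(sprintf("Pairwise comparisons (Kruskal-Wallis rank LSD, adjustment: %s)\n",
              attr(x, "method")))
  print.data.frame(comparison_wide(x), ...)
  invisible(x)
}

# One-variable pair rows -> named pair p lookup; validates full coverage.
pair_p_matrix <- function(pairs, samples) {
  p <- matrix(NA_real_, length(samples), length(samples),
              dimnames = list(samples, samples))
  for (i in seq_len(nrow(pairs))) {
    a <- pairs$sample_i[i]; b <- pairs$sample_j[i]
    pv <- if ("p_adj" %in% names(pairs)) pairs$p_adj[i] else pairs$p[i]
    p[a, b] <- pv
    p[b, a] <- pv
  }
  diag(p) <- 1
  if (anyNA(p)) {
    stop("incomplete pair coverage: every pair of samples must have a p value",
         call. = FALSE)
  }
  p
}

#' Compact letter display
#'
#' Assigns letters to samples so that two samples share at least one letter
#' if and only if their adjusted p value is >= alpha (insert-and-absorb
#' algorithm). Letters are assigned a, b, c, ... scanning samples in sample
#' order.
#'
#' @param cmp pair rows for a single variable: a data frame with columns
#'   \code{sample_i}, \code{sample_j} and \code{p_adj} (or \code{p}),
#'   covering every pair of the samples present.
#' @param alpha significance threshold, default 0.05.
#' @param samples optional explicit sample order; defaults to
#'   first-appearance order in \code{cmp}.
#' @return Named character vector mapping each sample to its letters.
#' @examples
#' cmp <- data.frame(sample_i = c("A", "A", "B"), sample_j = c("B", "C", "C"),
#'                   p_adj = c(0.001, 0.001, 0.8))
#' compact_letter_display(cmp, alpha = 0.05)  # A:"a", B:"b", C:"b"
#' @export
compact_letter_display <- function(cmp, alpha = 0.05, samples = NULL) {
  stopifnot(alpha > 0, alpha < 1)
  samples <- samples %||% unique(c(rbind(cmp$sample_i, cmp$sample_j)))
  p <- pair_p_matrix(cmp, samples)

  # insert-and-absorb over index sets
  cols <- list(seq_along(samples))
  sig <- which(p < alpha & upper.tri(p), arr.ind = TRUE)
  if (nrow(sig)) {
    for (s in seq_len(nrow(sig))) {
      i <- sig[s, 1L]; j <- sig[s, 2L]
      hit <- vapply(cols, function(cc) i %in% cc && j %in% cc, logical(1))
      if (!any(hit)) next
      new_cols <- list()
      for (ci in seq_along(cols)) {
        if (hit[ci]) {
          new_cols <- c(new_cols, list(setdiff(cols[[ci]], i)),
                        list(setdiff(cols[[ci]], j)))
        } else {
          new_cols <- c(new_cols, list(cols[[ci]]))
        }
      }
      new_cols <- Filter(length, new_cols)
      # absorb columns contained in another column
      keep <- rep(TRUE, length(new_cols))
      for (ci in seq_along(new_cols)) {
        for (cj in seq_along(new_cols)) {
          if (ci != cj && keep[cj] &&
              all(new_cols[[ci]] %in% new_cols[[cj]]) &&
              (length(new_cols[[ci]]) < length(new_cols[[cj]]) || ci > cj)) {
            keep[ci] <- FALSE
            break
          }
        }
      }
      cols <- new_cols[keep]
    }
  }
  cols <- cols[order(vapply(cols, min, numeric(1)))]
  letters_pool <- c(letters, paste0(rep(letters, each = 26), letters))
  marks <- vapply(seq_along(samples), function(i) {
    paste(letters_pool[which(vapply(cols, function(cc) i %in% cc,
                                    logical(1)))], collapse = "")
  }, character(1))
  setNames(marks, samples)
}

#' Asterisk annotation against the control
#'
#' Marks each treated sample with \code{"*"} when its adjusted p value
#' against the control is below alpha; the control itself and
#' non-significant samples get the empty mark. P values between the chosen
#' alpha and 1 are simply not flagged (single-tier annotation).
#'
#' @param cmp pair rows for a single variable (as in
#'   \code{\link{compact_letter_display}}).
#' @param control the control sample label; must appear in the comparisons.
#' @param alpha significance threshold, default 0.05.
#' @param samples optional explicit sample order.
#' @return Named character vector mapping each sample to \code{"*"} or
#'   \code{""}.
#' @export
asterisks_vs_control <- function(cmp, control, alpha = 0.05, samples = NULL) {
  stopifnot(alpha > 0, alpha < 1)
  samples <- samples %||% unique(c(rbind(cmp$sample_i, cmp$sample_j)))
  if (!control %in% samples) {
    stop(sprintf("control sample '%s' is absent from the comparisons", control),
         call. = FALSE)
  }
  p <- pair_p_matrix(cmp, samples)
  marks <- ifelse(samples != control & p[control, ] < alpha, "*", "")
  setNames(marks, samples)
}

# sample x variable annotation table for the plots module
build_annotations <- function(cmp, style, alpha) {
  samples <- attr(cmp, "sample_order")
  vars <- attr(cmp, "variables")
  rows <- lapply(vars, function(v) {
    sub <- cmp[cmp$variable == v, , drop = FALSE]
    marks <- switch(style,
      letters = compact_letter_display(sub, alpha, samples = samples),
      asterisks = asterisks_vs_control(sub, control = samples[1L],
                                       alpha = alpha, samples = samples))
    data.frame(Samples = samples, variable = v, mark = unname(marks),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
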