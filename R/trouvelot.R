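# Trouvelot scoring: parse score codes, tally fragment classes, and compute
# the colonization indices per biological replicate.
#
# Each root fragment carries a mycorrhization class 0-5 (0 = uncolonized,
# 5 = fully colonized) and an arbuscule class A0-A3. The standard
# class-intensity weights (Mycocalc convention) are 1, 5, 30, 70 and 95% for
# classes 1-5, and 10, 50, 100% for arbuscule classes A1-A3.

MYC_WEIGHTS <- c(`1` = 1, `2` = 5, `3` = 30, `4` = 70, `5` = 95)
ARB_WEIGHTS <- c(`1` = 10, `2` = 50, `3` = 100)

#' Parse a Trouvelot score code
#'
#' Accepts exactly \code{"0"} (uncolonized fragment) or
#' \code{"<c>A<a>"} with mycorrhization class c in 1..5 and arbuscule class
#' a in 0..3, case-insensitively after trimming. A bare nonzero class
#' without an A part (e.g. \code{"3"}) is rejected: explicit arbuscule
#' scoring is required.
#'
#' @param code score code text, e.g. \code{"3A2"}.
#' @return A list with integer fields \code{myc_class} and \code{arb_class}.
#' @examples
#' parse_score("3A3")
#' parse_score("0")
#' @export
parse_score <- function(code) {
  stopifnot(is.character(code), length(code) == 1L)
  x <- toupper(trimws(code))
  if (!nzchar(x) || !grepl(trouvelot_score_pattern, x)) {
    stop(sprintf("invalid score code '%s' (expected '0' or '<1-5>A<0-3>')",
                 code), call. = FALSE)
  }
  if (x == "0") {
    list(myc_class = 0L, arb_class = 0L)
  } else {
    list(myc_class = as.integer(substr(x, 1L, 1L)),
         arb_class = as.integer(substr(x, 3L, 3L)))
  }
}

#' Format a Trouvelot score
#'
#' Inverse of \code{\link{parse_score}} over the 21 valid codes.
#'
#' @param score a list with \code{myc_class} and \code{arb_class}.
#' @return The canonical code text.
#' @export
format_score <- function(score) {
  if (score$myc_class == 0L) "0" else
    sprintf("%dA%d", score$myc_class, score$arb_class)
}

# Vectorized parse for internal use; input assumed pre-validated.
parse_scores <- function(codes) {
  x <- toupper(trimws(codes))
  bad <- !grepl(trouvelot_score_pattern, x)
  if (any(bad)) {
    stop(sprintf("invalid score code(s): %s",
                 paste(unique(codes[bad]), collapse = ", ")), call. = FALSE)
  }
  myc <- ifelse(x == "0", 0L, as.integer(substr(x, 1L, 1L)))
  arb <- ifelse(x == "0", 0L, as.integer(substr(x, 3L, 3L)))
  data.frame(myc_class = myc, arb_class = arb)
}

#' Tally fragment classes
#'
#' Counts fragments per mycorrhization class and per (mycorrhization,
#' arbuscule) class pair.
#'
#' @param scores a data frame with columns \code{myc_class}, \code{arb_class}
#'   (one row per fragment), or a list of \code{\link{parse_score}} results.
#' @return An object of class \code{am_class_counts}: list with \code{N}
#'   (total fragments), \code{n} (length-6 vector, classes 0..5) and
#'   \code{nA} (6 x 4 matrix of joint counts, arbuscule classes 0..3).
#' @export
tally_classes <- function(scores) {
  if (is.list(scores) && !is.data.frame(scores)) {
    scores <- data.frame(myc_class = vapply(scores, `[[`, 1L, "myc_class"),
                         arb_class = vapply(scores, `[[`, 1L, "arb_class"))
  }
  if (nrow(scores) == 0L) stop("no fragments to tally", call. = FALSE)
  stopifnot(all(scores$myc_class %in% 0:5), all(scores$arb_class %in% 0:3))
  nA <- matrix(0L, nrow = 6L, ncol = 4L,
               dimnames = list(myc = 0:5, arb = 0:3))
  for (i in seq_len(nrow(scores))) {
    nA[scores$myc_class[i] + 1L, scores$arb_class[i] + 1L] <-
      nA[scores$myc_class[i] + 1L, scores$arb_class[i] + 1L] + 1L
  }
  structure(list(N = nrow(scores), n = rowSums(nA), nA = nA),
            class = "am_class_counts")
}

#' Compute the Trouvelot colonization indices
#'
#' From class counts over the N fragments of one biological replicate:
#' \deqn{F = 100 (N - n_0) / N}
#' \deqn{M = (95 n_5 + 70 n_4 + 30 n_3 + 5 n_2 + n_1) / N}
#' \deqn{m = M N / (N - n_0)} (0 when no fragment is colonized),
#' \code{mA_j} the arbuscule-class-j share of intensity within colonized
#' fragments, \deqn{a = (100 mA_3 + 50 mA_2 + 10 mA_1)/100,\quad A = a M / 100.}
#' F is the frequency of mycorrhiza, M/m the colonization intensity over all
#' (resp. only colonized) fragments, a/A the arbuscule abundance in the
#' colonized parts (resp. whole root system). All indices are percentages in
#' \[0, 100\]; an entirely uncolonized replicate yields all zeros.
#'
#' @param counts an \code{am_class_counts} object from
#'   \code{\link{tally_classes}}.
#' @return Named numeric vector with elements F, M, m, a, A.
#' @examples
#' counts <- tally_classes(data.frame(myc_class = c(3, 5, 3),
#'                                    arb_class = c(3, 3, 3)))
#' compute_indices(counts)  # F = 100, M = 155/3, a = 100
#' @export
compute_indices <- function(counts) {
  stopifnot(inherits(counts, "am_class_counts"), counts$N >= 1L)
  N <- counts$N
  n <- counts$n           # classes 0..5
  nA <- counts$nA
  n0 <- n[[1L]]

  F_ <- 100 * (N - n0) / N
  M <- sum(MYC_WEIGHTS * n[2:6]) / N
  m <- if (n0 < N) M * N / (N - n0) else 0

  mA <- numeric(3L)       # arbuscule classes A1..A3
  if (m > 0) {
    for (j in 1:3) {
      mA[j] <- sum(MYC_WEIGHTS * nA[2:6, j + 1L]) / (N - n0) * 100 / m
    }
  }
  a <- (100 * mA[3L] + 50 * mA[2L] + 10 * mA[1L]) / 100
  A <- a * M / 100

  c(F = unname(F_), M = unname(M), m = unname(m), a = unname(a), A = unname(A))
}

#' Trouvelot indices per biological replicate
#'
#' Pools all rows sharing (sample, replicate) as fragments of that
#' biological replicate and computes F, M, m, a, A for each. Row order
#' follows the dataset's sample order, then replicate first-appearance
#' order within each sample.
#'
#' @param ds an \code{am_dataset} with trouvelot scoring.
#' @return Data frame with columns Samples, Replicates, F, M, m, a, A.
#' @export
indices_per_replicate <- function(ds) {
  stopifnot(inherits(ds, "am_dataset"))
  if (scoring_type(ds) != "trouvelot") {
    stop("indices_per_replicate() requires a trouvelot dataset", call. = FALSE)
  }
  if (nrow(ds) == 0L) stop("empty dataset", call. = FALSE)

  key <- paste(ds$Samples, ds$Replicates,
               if ("trt" %in% names(ds)) ds$trt else "", sep = "\r")
  groups <- split(seq_len(nrow(ds)), factor(key, levels = unique(key)))
  rows <- lapply(groups, function(idx) {
    counts <- tally_classes(parse_scores(ds$Scoring[idx]))
    ind <- compute_indices(counts)
    out <- data.frame(Samples = ds$Samples[idx[1L]],
                      Replicates = ds$Replicates[idx[1L]],
                      stringsAsFactors = FALSE)
    if ("trt" %in% names(ds)) out$trt <- ds$trt[idx[1L]]
    cbind(out, as.data.frame(as.list(ind), check.names = FALSE))
  })
  out <- do.call(rbind, rows)
  out <- out[order(match(out$Samples, sample_order(ds))), , drop = FALSE]
  rownames(out) <- NULL
  out
}
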