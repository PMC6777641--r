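# Seeded simulators for both scoring dialects. Defaults emulate the shape
# of typical dose-response colonization experiments: a well-colonized
# control, intermediately inhibited treatments, and a strongly inhibited
# sample, with a handful of biological replicates each.

with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  code
}

# inverse-CDF sampling from a normal truncated to [lo, hi]
rtruncnorm <- function(n, mean, sd, lo = 0, hi = 100) {
  if (sd == 0) return(rep(mean, n))
  u <- runif(n, pnorm(lo, mean, sd), pnorm(hi, mean, sd))
  pmin(hi, pmax(lo, qnorm(u, mean, sd)))
}

default_grid_means <- function() {
  list(
    "Low phosphate" = c(Total = 87, Hyphopodia = 4, IntrHyphae = 87,
                        Arbuscule = 73, Vesicle = 31),
    "Medium phosphate" = c(Total = 66, Hyphopodia = 3, IntrHyphae = 66,
                           Arbuscule = 52, Vesicle = 23),
    "High phosphate" = c(Total = 11, Hyphopodia = 1, IntrHyphae = 11,
                         Arbuscule = 10, Vesicle = 3)
  )
}

#' Simulate a gridline-intersect dataset
#'
#' Draws each replicate value from a normal distribution truncated to
#' \[0, 100\] around the sample's configured mean. Deterministic given the
#' seed; the global random state is left untouched.
#'
#' @param means named list: sample label -> named numeric vector of
#'   per-variable mean percentages. Defaults to a three-level phosphate
#'   dose-response (high, intermediate, strongly inhibited colonization).
#' @param n_replicates biological replicates per sample (default 7).
#' @param sd noise standard deviation on the percentage scale (default 8,
#'   a typical between-replicate spread for such experiments).
#' @param seed integer seed (mandatory; no hidden global state).
#' @return An \code{am_dataset} with grid scoring that passes
#'   \code{\link{am_validate}}.
#' @examples
#' ds <- simulate_grid(seed = 1)
#' am_summary(ds)
#' @export
simulate_grid <- function(means = default_grid_means(), n_replicates = 7,
                          sd = 8, seed) {
  stopifnot(is.list(means), length(means) >= 1L, n_replicates >= 1L, sd >= 0)
  vars <- names(means[[1L]])
  stopifnot(all(vars %in% GRID_VARIABLES))
  for (m in means) {
    stopifnot(identical(names(m), vars), all(m >= 0 & m <= 100))
  }
  with_seed(seed, {
    rows <- lapply(names(means), function(s) {
      df <- data.frame(Samples = s,
                       Replicates = as.character(seq_len(n_replicates)),
                       stringsAsFactors = FALSE)
      for (v in vars) {
        df[[v]] <- rtruncnorm(n_replicates, means[[s]][[v]], sd)
      }
      df
    })
    new_am_dataset(do.call(rbind, rows), "grid")
  })
}

default_trouvelot_params <- function() {
  list(
    class_probs = list(
      Control = c(0.05, 0.05, 0.30, 0.30, 0.15, 0.15),
      GR24 = c(0.02, 0.03, 0.10, 0.30, 0.20, 0.35),
      MP3 = c(0.02, 0.03, 0.05, 0.20, 0.35, 0.35),
      MP1 = c(0.10, 0.15, 0.30, 0.30, 0.10, 0.05)
    ),
    arb_probs = c(0.05, 0.10, 0.25, 0.60)
  )
}

#' Simulate a Trouvelot-scored dataset
#'
#' Each fragment draws a mycorrhization class from the sample's class
#' probability vector (classes 0--5); colonized fragments then draw an
#' arbuscule class A0--A3 from the conditional arbuscule probabilities.
#' All emitted codes are valid under \code{\link{parse_score}}.
#'
#' @param class_probs named list: sample label -> probability vector of
#'   length 6 over mycorrhization classes 0..5 (must sum to 1). Defaults to
#'   four samples emulating a strigolactone-analog experiment.
#' @param arb_probs probability vector of length 4 over arbuscule classes
#'   A0..A3, conditional on colonization; either one vector shared by all
#'   samples or a named list per sample.
#' @param n_fragments root fragments scored per biological replicate
#'   (default 30, the usual microscopy workload).
#' @param n_replicates biological replicates per sample (default 3).
#' @param seed integer seed (mandatory).
#' @return An \code{am_dataset} with trouvelot scoring.
#' @export
simulate_trouvelot <- function(class_probs = default_trouvelot_params()$class_probs,
                               arb_probs = default_trouvelot_params()$arb_probs,
                               n_fragments = 30, n_replicates = 3, seed) {
  stopifnot(is.list(class_probs), length(class_probs) >= 1L,
            n_fragments >= 1L, n_replicates >= 1L)
  check_probs <- function(p, len, what) {
    if (length(p) != len || any(p < 0) || abs(sum(p) - 1) > 1e-8) {
      stop(sprintf("%s must be a length-%d nonnegative vector summing to 1",
                   what, len), call. = FALSE)
    }
  }
  for (s in names(class_probs)) {
    check_probs(class_probs[[s]], 6L, sprintf("class_probs[['%s']]", s))
  }
  arb_for <- function(s) {
    p <- if (is.list(arb_probs)) arb_probs[[s]] else arb_probs
    check_probs(p, 4L, "arb_probs")
    p
  }
  with_seed(seed, {
    rows <- lapply(names(class_probs), function(s) {
      do.call(rbind, lapply(seq_len(n_replicates), function(r) {
        myc <- sample(0:5, n_fragments, replace = TRUE,
                      prob = class_probs[[s]])
        arb <- ifelse(myc == 0L, 0L,
                      sample(0:3, n_fragments, replace = TRUE,
                             prob = arb_for(s)))
        codes <- ifelse(myc == 0L, "0", sprintf("%dA%d", myc, arb))
        data.frame(Samples = s, Replicates = as.character(r),
                   Scoring = codes, stringsAsFactors = FALSE)
      }))
    })
    new_am_dataset(do.call(rbind, rows), "trouvelot")
  })
}

#' Write a dataset back to CSV
#'
#' Writes an \code{am_dataset} in its input dialect (canonical header
#' names, comma-delimited), so simulated data round-trips through
#' \code{\link{read_colonization_table}}.
#'
#' @param ds an \code{am_dataset}.
#' @param path output file path.
#' @return Invisibly, the path.
#' @export
write_dataset <- function(ds, path) {
  stopifnot(inherits(ds, "am_dataset"))
  write.csv(format_numeric_cols(as.data.frame(ds)), path, row.names = FALSE,
            fileEncoding = "UTF-8")
  invisible(path)
}
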