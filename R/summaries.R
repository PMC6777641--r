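# Summaries: collapse technical replicates, then per-replicate and
# per-sample (mean +/- SE) tables.

dataset_variables <- function(ds) {
  if (scoring_type(ds) == "grid") {
    intersect(GRID_VARIABLES, names(ds))
  } else {
    TROUVELOT_VARIABLES
  }
}

#' Collapse technical replicates of a grid dataset
#'
#' Rows sharing (sample, replicate) are repeated measurements of the same
#' biological replicate; they are averaged (unweighted arithmetic mean per
#' variable) into one row. For trouvelot datasets the analogous operation is
#' \code{\link{indices_per_replicate}}, which pools the fragments instead.
#'
#' @param ds an \code{am_dataset} with grid scoring.
#' @return Data frame with one row per biological replicate, variables in
#'   canonical order, row order following sample order then replicate
#'   first appearance.
#' @export
collapse_technical <- function(ds) {
  stopifnot(inherits(ds, "am_dataset"))
  if (scoring_type(ds) != "grid") {
    stop("collapse_technical() requires a grid dataset; ",
         "use indices_per_replicate() for trouvelot data", call. = FALSE)
  }
  vars <- dataset_variables(ds)
  # a trt column marks a combined multi-factor table: keep its levels apart
  key <- paste(ds$Samples, ds$Replicates,
               if ("trt" %in% names(ds)) ds$trt else "", sep = "\r")
  groups <- split(seq_len(nrow(ds)), factor(key, levels = unique(key)))
  rows <- lapply(groups, function(idx) {
    out <- data.frame(Samples = ds$Samples[idx[1L]],
                      Replicates = ds$Replicates[idx[1L]],
                      stringsAsFactors = FALSE)
    if ("trt" %in% names(ds)) out$trt <- ds$trt[idx[1L]]
    for (v in vars) out[[v]] <- mean(ds[[v]][idx])
    out
  })
  out <- do.call(rbind, rows)
  out <- out[order(match(out$Samples, sample_order(ds))), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Biological-replicate value table for any dataset: grid values averaged
# over technical replicates, or Trouvelot indices with fragments pooled.
replicate_values <- function(ds) {
  if (scoring_type(ds) == "grid") collapse_technical(ds) else
    indices_per_replicate(ds)
}

#' Summarize a colonization dataset
#'
#' Produces the two standard tables: per biological replicate (technical
#' replicates collapsed; for trouvelot data the F, M, m, a, A indices), and
#' per sample with the across-replicate mean and standard error
#' (\eqn{SE = s/\sqrt{n}} with \eqn{s} the n-1 sample standard deviation and
#' \eqn{n} the number of biological replicates). The SE of a sample with a
#' single biological replicate is reported as NA, not zero.
#'
#' @param ds an \code{am_dataset}.
#' @return An object of class \code{am_summary_tables}: list with
#'   \code{per_replicate} and \code{per_sample} data frames. The per-sample
#'   table has one row per sample in sample order; mean columns keep the
#'   variable names, SE columns are suffixed \code{"_se"}.
#' @examples
#' path <- system.file("extdata", "grid_phosphate.csv", package = "amquant")
#' am_summary(read_colonization_table(path, "grid"))
#' @export
am_summary <- function(ds) {
  stopifnot(inherits(ds, "am_dataset"))
  per_rep <- replicate_values(ds)
  vars <- setdiff(names(per_rep), c(ID_COLUMNS, "trt"))

  samples <- sample_order(ds)
  per_sample <- data.frame(Samples = samples, stringsAsFactors = FALSE)
  for (v in vars) {
    per_sample[[v]] <- vapply(samples, function(s)
      mean(per_rep[[v]][per_rep$Samples == s]), numeric(1))
  }
  for (v in vars) {
    per_sample[[paste0(v, "_se")]] <- vapply(samples, function(s) {
      x <- per_rep[[v]][per_rep$Samples == s]
      if (length(x) < 2L) NA_real_ else sd(x) / sqrt(length(x))
    }, numeric(1))
  }
  rownames(per_sample) <- NULL
  structure(list(per_replicate = per_rep, per_sample = per_sample),
            class = "am_summary_tables")
}

#' @export
print.am_summary_tables <- function(x, ...) {
  cat("Summary per Replicate\n")
  print.data.frame(x$per_replicate, ...)
  cat("\nSummary per Sample\n")
  print.data.frame(x$per_sample, ...)
  invisible(x)
}
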