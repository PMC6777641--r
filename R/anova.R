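# One-way (nonparametric, Kruskal-Wallis) and two-way (parametric) analyses.

#' One-way analysis per variable
#'
#' Nonparametric one-way analysis: the Kruskal-Wallis omnibus test per
#' variable plus the same pairwise rank-LSD table as \code{\link{am_stat}}.
#'
#' @param ds an \code{am_dataset}.
#' @param method p-value adjustment for the pairwise block.
#' @return List of class \code{am_anova1} with \code{omnibus} (data frame:
#'   variable, H, df, p) and \code{pairwise} (the \code{am_stat} result).
#' @export
anova_one_way <- function(ds, method = "none") {
  pairwise <- am_stat(ds, method = method)
  per_rep <- replicate_values(ds)
  samples <- sample_order(ds)
  vars <- attr(pairwise, "variables")
  omnibus <- do.call(rbind, lapply(vars, function(v) {
    kw <- kruskal_wallis(lapply(samples, function(s)
      per_rep[[v]][per_rep$Samples == s]))
    data.frame(variable = v, H = kw$H, df = kw$df, p = kw$p,
               stringsAsFactors = FALSE)
  }))
  rownames(omnibus) <- NULL
  structure(list(omnibus = omnibus, pairwise = pairwise),
            class = "am_anova1")
}

#' @export
print.am_anova1 <- function(x, ...) {
  cat("Kruskal-Wallis omnibus per variable\n")
  print.data.frame(x$omnibus, ...)
  cat("\n")
  print(x$pairwise, ...)
  invisible(x)
}

#' Two-way analysis of variance per variable
#'
#' Parametric two-way ANOVA with interaction on biological-replicate values,
#' for datasets carrying a second factor in a \code{trt} column (e.g. the
#' growth substrate when several experiments are combined). Sums of squares
#' are sequential (Type I) in the order sample, trt, sample:trt, matching
#' the classic ANOVA table. Diagnostics for the two standard assumption
#' checks are returned: (fitted, residual) pairs for homoscedasticity and
#' normal Q-Q coordinates for residual normality. When the residual sum of
#' squares is exactly zero the F ratios are undefined and reported as NA.
#'
#' @param ds an \code{am_dataset} whose table includes a \code{trt} column;
#'   both sample and trt must have at least 2 levels and the design must
#'   leave at least one residual degree of freedom.
#' @return List of class \code{am_anova2}, one element per variable, each
#'   with \code{table} (term, df, sum_sq, mean_sq, F, p), \code{diagnostics}
#'   (data frame fitted/residual) and \code{qq} (data frame theoretical/
#'   sample, sorted by sample quantile).
#' @export
anova_two_way <- function(ds) {
  stopifnot(inherits(ds, "am_dataset"))
  if (!"trt" %in% names(ds)) {
    stop("two-way analysis requires a 'trt' column with the second factor",
         call. = FALSE)
  }
  per_rep <- replicate_values(ds)
  if (length(unique(per_rep$Samples)) < 2L || length(unique(per_rep$trt)) < 2L) {
    stop("both factors need at least 2 levels", call. = FALSE)
  }
  vars <- setdiff(names(per_rep), c(ID_COLUMNS, "trt"))

  out <- lapply(vars, function(v) {
    d <- data.frame(value = per_rep[[v]],
                    sample = factor(per_rep$Samples,
                                    levels = unique(per_rep$Samples)),
                    trt = factor(per_rep$trt, levels = unique(per_rep$trt)))
    fit <- lm(value ~ sample * trt, data = d)
    if (fit$df.residual <= 0L) {
      stop("zero residual degrees of freedom: the design has no replication",
           call. = FALSE)
    }
    tab <- anova(fit)   # sequential (Type I) SS in model order
    terms <- data.frame(term = c("sample", "trt", "sample:trt", "residuals"),
                        df = tab$Df, sum_sq = tab$`Sum Sq`,
                        mean_sq = tab$`Mean Sq`,
                        F = c(tab$`F value`),
                        p = c(tab$`Pr(>F)`), stringsAsFactors = FALSE)
    total_ss <- sum(terms$sum_sq)
    if (terms$sum_sq[terms$term == "residuals"] <=
        max(1e-12, 1e-10 * total_ss)) {
      terms$sum_sq[terms$term == "residuals"] <- 0
      terms$mean_sq[terms$term == "residuals"] <- 0
      terms$F[] <- NA_real_
      terms$p[] <- NA_real_
    }
    res <- stats::residuals(fit)
    qq <- stats::qqnorm(res, plot.it = FALSE)
    ord <- order(qq$y)
    list(table = terms,
         diagnostics = data.frame(fitted = stats::fitted(fit), residual = res),
         qq = data.frame(theoretical = qq$x[ord], sample = qq$y[ord]))
  })
  names(out) <- vars
  structure(out, class = "am_anova2")
}

#' @export
print.am_anova2 <- function(x, ...) {
  for (v in names(x)) {
    cat(sprintf("Two-way ANOVA: %s\n", v))
    print.data.frame(x[[v]]$table, ...)
    cat("\n")
  }
  invisible(x)
}
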