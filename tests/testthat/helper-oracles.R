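# Independent oracles, written before (and kept independent of) the package
# implementations they check.

# Trouvelot indices by direct per-fragment application of the formulas:
# each fragment contributes its class-intensity weight; arbuscule shares are
# taken over colonized fragments only.
oracle_indices <- function(codes) {
  codes <- toupper(codes)
  myc <- ifelse(codes == "0", 0L, as.integer(substr(codes, 1, 1)))
  arb <- ifelse(codes == "0", 0L, as.integer(substr(codes, 3, 3)))
  w <- c(0, 1, 5, 30, 70, 95)[myc + 1]
  N <- length(codes)
  ncol <- sum(myc > 0)
  F_ <- 100 * ncol / N
  M <- sum(w) / N
  m <- if (ncol > 0) sum(w) / ncol else 0
  if (m > 0) {
    mA <- vapply(1:3, function(j) sum(w[arb == j]) / ncol * 100 / m, 0)
  } else {
    mA <- c(0, 0, 0)
  }
  a <- (100 * mA[3] + 50 * mA[2] + 10 * mA[1]) / 100
  c(F = F_, M = M, m = m, a = a, A = a * M / 100)
}

# Kruskal-Wallis via the reference implementation in stats.
oracle_kw <- function(groups) {
  x <- unlist(groups, use.names = FALSE)
  g <- rep(seq_along(groups), lengths(groups))
  kt <- stats::kruskal.test(x, factor(g))
  list(H = unname(kt$statistic), p = kt$p.value)
}

# spreadsheet-style mean / n-1 standard error from explicit sums
oracle_mean_se <- function(x) {
  n <- length(x)
  m <- sum(x) / n
  s2 <- sum((x - m)^2) / (n - 1)
  c(mean = m, se = sqrt(s2) / sqrt(n))
}

# exact permutation distribution of H for two small groups
oracle_kw_permutation_p <- function(g1, g2) {
  x <- c(g1, g2)
  n1 <- length(g1)
  idx <- utils::combn(length(x), n1)
  obs <- kruskal_wallis(list(g1, g2))$H
  hs <- apply(idx, 2, function(i) {
    kruskal_wallis(list(x[i], x[-i]))$H
  })
  mean(hs >= obs - 1e-12)
}
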