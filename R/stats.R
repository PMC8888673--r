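# Statistical toolkit: paired t-tests, Pearson correlation with a
# bootstrapped confidence interval, Bonferroni thresholds.

#' Paired-sample t-test
#'
#' Two-sided paired t on the differences `a - b` with `n - 1` degrees of
#' freedom. Zero-variance differences with a nonzero mean report an
#' infinite statistic with p = 0 and a `degenerate` flag.
#'
#' @param a,b numeric vectors of equal length (n >= 2).
#' @return List (`StatResult`): `t`, `df`, `p`, `meanDiff`, `n`,
#'   `degenerate`.
#' @export
pairedT <- function(a, b) {
  if (length(a) != length(b)) stop("a and b must have equal length")
  n <- length(a)
  if (n < 2L) stop("need n >= 2 pairs")
  d <- a - b
  if (stats::sd(d) < 1e-15) {
    if (abs(mean(d)) < 1e-15)
      return(list(t = 0, df = n - 1L, p = 1, meanDiff = 0, n = n,
                  degenerate = FALSE))
    return(list(t = sign(mean(d)) * Inf, df = n - 1L, p = 0,
                meanDiff = mean(d), n = n, degenerate = TRUE))
  }
  tt <- stats::t.test(a, b, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, meanDiff = unname(tt$estimate), n = n,
       degenerate = FALSE)
}

#' Pearson correlation with a bootstrapped confidence interval
#'
#' Pearson r with its two-sided p-value, plus a seeded percentile
#' confidence interval from `B` resamples of the participant pairs with
#' replacement.
#'
#' @param x,y numeric vectors (n >= 3, non-constant).
#' @param B number of bootstrap resamples.
#' @param seed integer seed.
#' @param level confidence level.
#' @return List (`StatResult`): `r`, `p`, `ciLow`, `ciHigh`, `n`, `B`.
#' @export
pearsonBootstrap <- function(x, y, B = 10000L, seed = 1L, level = 0.95) {
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length")
  if (n < 3L) stop("need n >= 3")
  if (stats::sd(x) < 1e-15 || stats::sd(y) < 1e-15)
    stop("constant input: correlation undefined")
  ct <- stats::cor.test(x, y)
  rs <- .withSeed(seed, {
    vapply(seq_len(B), function(b) {
      ii <- sample.int(n, n, replace = TRUE)
      if (stats::sd(x[ii]) < 1e-15 || stats::sd(y[ii]) < 1e-15)
        NA_real_ else stats::cor(x[ii], y[ii])
    }, numeric(1))
  })
  qs <- stats::quantile(rs, c((1 - level) / 2, 1 - (1 - level) / 2),
                        na.rm = TRUE, names = FALSE)
  list(r = unname(ct$estimate), p = ct$p.value, ciLow = qs[1],
       ciHigh = qs[2], n = n, B = B)
}

#' Bonferroni-corrected significance threshold
#'
#' @param alpha family-wise alpha.
#' @param m number of comparisons (>= 1).
#' @return `alpha / m`.
#' @export
bonferroni <- function(alpha, m) {
  if (m < 1) stop("m must be >= 1")
  alpha / m
}
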