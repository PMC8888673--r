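# Haemodynamic response, convolution and time-series preprocessing helpers.

#' Canonical double-gamma haemodynamic response function
#'
#' The HRF kernel used throughout the pipeline: a difference of two gamma
#' densities (response peak minus undershoot), sampled at the repetition
#' time, zero at t = 0, truncated at `durationS` and scaled to unit peak.
#' Any fixed kernel used consistently for simulation and fitting preserves
#' the recovery properties of the pipeline; these defaults (peak 6 s,
#' undershoot 16 s, unit dispersions, peak:undershoot ratio 6, 32 s support)
#' are the standard canonical shape.
#'
#' @param trS sampling interval (s).
#' @param peakDelayS,undershootDelayS gamma shape parameters (s, with unit
#'   dispersion these equal the modes + 1).
#' @param peakDispersion,undershootDispersion gamma scale parameters.
#' @param ratio peak-to-undershoot amplitude ratio.
#' @param durationS kernel support (s).
#' @return Numeric kernel sampled at `t = 0, trS, 2 trS, ...`, with the
#'   parameter list attached as attribute `"params"`.
#' @export
canonicalHRF <- function(trS = 1, peakDelayS = 6, undershootDelayS = 16,
                         peakDispersion = 1, undershootDispersion = 1,
                         ratio = 6, durationS = 32) {
  t <- seq(0, durationS, by = trS)
  h <- stats::dgamma(t, shape = peakDelayS / peakDispersion,
                     scale = peakDispersion) -
    stats::dgamma(t, shape = undershootDelayS / undershootDispersion,
                  scale = undershootDispersion) / ratio
  h <- h / max(h)
  attr(h, "params") <- list(trS = trS, peakDelayS = peakDelayS,
                            undershootDelayS = undershootDelayS,
                            peakDispersion = peakDispersion,
                            undershootDispersion = undershootDispersion,
                            ratio = ratio, durationS = durationS)
  h
}

#' Causal convolution with an HRF kernel
#'
#' Convolves each time series with the kernel and truncates to the input
#' length (causal; output at time t depends on inputs at times <= t).
#'
#' @param x numeric vector, or matrix with series in rows.
#' @param hrf kernel from [canonicalHRF()] (same sampling interval as `x`).
#' @return Object of the same shape as `x`.
#' @export
convolveHRF <- function(x, hrf) {
  h <- as.numeric(hrf)
  if (is.matrix(x)) {
    n <- ncol(x)
    nf <- stats::nextn(n + length(h) - 1L)
    H <- stats::fft(c(h, numeric(nf - length(h))))
    X <- t(x)
    X <- rbind(X, matrix(0, nf - n, ncol(X)))
    Y <- Re(stats::mvfft(stats::mvfft(X) * H, inverse = TRUE)) / nf
    t(Y[seq_len(n), , drop = FALSE])
  } else {
    n <- length(x)
    y <- stats::convolve(x, rev(h), type = "open")
    y[seq_len(n)]
  }
}

#' Resample frame-resolution values to TR resolution
#'
#' Averages frames within each TR bin (when frames are finer than the TR) or
#' repeats values (when coarser); the ratio must be an integer either way.
#'
#' @param x numeric vector (one value per frame) or matrix (frames in
#'   columns).
#' @param frameDurationS seconds per frame.
#' @param trS repetition time (s).
#' @return Vector/matrix at TR resolution.
#' @export
resampleToTR <- function(x, frameDurationS, trS = 1) {
  if (isTRUE(all.equal(frameDurationS, trS))) return(x)
  mat <- is.matrix(x)
  X <- if (mat) x else matrix(x, nrow = 1)
  if (frameDurationS < trS) {
    k <- trS / frameDurationS
    if (abs(k - round(k)) > 1e-8)
      stop("frame duration must divide the TR evenly")
    k <- as.integer(round(k))
    nTR <- ncol(X) %/% k
    G <- kronecker(diag(nTR), matrix(1 / k, k, 1))  # bin-averaging operator
    Y <- X[, seq_len(nTR * k), drop = FALSE] %*% G
  } else {
    k <- frameDurationS / trS
    if (abs(k - round(k)) > 1e-8)
      stop("TR must divide the frame duration evenly")
    Y <- X[, rep(seq_len(ncol(X)), each = as.integer(round(k))),
           drop = FALSE]
  }
  if (mat) Y else as.numeric(Y)
}

#' Linear detrend and z-score normalisation
#'
#' Removes a per-series linear trend and scales to unit variance, per run.
#' Constant (zero-variance) series are returned as all zeros rather than
#' NaN. With `scale = "vertex"` every series is scaled by its own SD (strict
#' per-vertex z-scoring, used for mapping runs, where pRF fitting is
#' invariant to per-vertex scale). With `scale = "run"` all series in a run
#' share one scale — the RMS of the per-vertex SDs — which preserves
#' relative response amplitudes across vertices; this is the convention for
#' simulated main-experiment runs, where downstream profile reconstruction
#' depends on amplitude ratios (the two conventions coincide when
#' homoscedastic noise dominates the series).
#'
#' @param x matrix with series in rows (vertices x volumes) or a vector.
#' @param runLengths integer vector of volumes per run partitioning the
#'   columns; detrending and scaling are applied within each run.
#' @param scale `"vertex"` (unit SD per series), `"run"` (one common scale
#'   per run) or `"none"` (detrend only; callers apply their own scale).
#' @return Same shape as `x`.
#' @export
detrendZScore <- function(x, runLengths = if (is.matrix(x)) ncol(x) else
                            length(x), scale = c("vertex", "run", "none")) {
  scale <- match.arg(scale)
  mat <- is.matrix(x)
  X <- if (mat) x else matrix(x, nrow = 1)
  if (sum(runLengths) != ncol(X))
    stop("runLengths must sum to the number of volumes")
  ends <- cumsum(runLengths)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  for (r in seq_along(runLengths)) {
    cols <- starts[r]:ends[r]
    n <- length(cols)
    tt <- seq_len(n)
    B <- cbind(1, tt - mean(tt))
    # residuals of the projection onto (intercept, linear trend)
    coefs <- solve(crossprod(B), crossprod(B, t(X[, cols, drop = FALSE])))
    R <- X[, cols, drop = FALSE] - t(B %*% coefs)
    s <- sqrt(rowSums(R^2) / (n - 1))
    if (scale == "run") s[] <- sqrt(mean(s^2))
    if (scale == "none") s[] <- 1
    s[s < 1e-12] <- Inf   # constant series -> zeros
    X[, cols] <- R / s
  }
  if (mat) X else as.numeric(X)
}

# run an expression under a fixed seed, restoring the caller's RNG state
.withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
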