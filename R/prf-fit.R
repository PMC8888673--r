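# Two-stage pRF estimation: coarse grid search by Pearson correlation
# against precomputed predictions, then fine Nelder-Mead optimisation of
# (x, y, sigma) with amplitude and intercept solved by least squares.

#' 2-D Gaussian pRF profile on a field grid
#'
#' Evaluates an isotropic 2-D Gaussian centred at `(x, y)` with SD `sigma`
#' at every pixel centre and normalises it to unit sum over the grid, so
#' that the overlap (inner product) with a full-field mask is 1.
#'
#' @param x,y pRF centre (deg).
#' @param sigma pRF size (deg, > 0).
#' @param grid a [FieldGrid-class].
#' @return `heightPx x widthPx` weight matrix summing to 1.
#' @export
prfProfile <- function(x, y, sigma, grid = FieldGrid()) {
  if (sigma <= 0) stop("sigma must be > 0")
  pc <- pixelCoords(grid)
  gx <- exp(-(pc$x - x)^2 / (2 * sigma^2))
  gy <- exp(-(pc$y - y)^2 / (2 * sigma^2))
  w <- outer(gy, gx)
  s <- sum(w)
  if (s <= 0) return(w)
  w / s
}

#' Predicted BOLD time series for a pRF
#'
#' The reference (full-grid) prediction path: per-frame overlap between the
#' unit-sum pRF profile and the stimulus masks, resampled to TR resolution,
#' then causally convolved with the HRF. Returned without z-scoring; callers
#' normalise as needed.
#'
#' @param x,y,sigma pRF parameters (deg).
#' @param apertures an [ApertureStack-class].
#' @param hrf kernel from [canonicalHRF()] sampled at `trS`.
#' @param trS repetition time (s).
#' @return Numeric vector, one value per retained volume.
#' @export
predictTimeseries <- function(x, y, sigma, apertures, hrf = canonicalHRF(trS),
                              trS = 1) {
  grid <- fieldGrid(apertures)
  w <- prfProfile(x, y, sigma, grid)
  fr <- frames(apertures)
  npix <- prod(dim(fr)[1:2])
  ov <- as.numeric(crossprod(as.numeric(w), matrix(fr, npix, dim(fr)[3])))
  ov <- resampleToTR(ov, frameDuration(apertures), trS)
  convolveHRF(ov, hrf)
}

#' Coarse-search parameter grid
#'
#' The standard grid: 15 x-values and 15 y-values evenly spaced over
#' -8.925..8.925 deg crossed with 34 sigma values log-spaced over
#' 0.18..17 deg — 7650 combinations, in deterministic x-major scan order
#' (x slowest, then y, then sigma).
#'
#' @param nXY number of x (and y) values.
#' @param xyMaxDeg extreme |x| and |y| (deg).
#' @param nSigma number of sigma values.
#' @param sigmaRangeDeg sigma range (deg), log-spaced.
#' @return List with `x`, `y`, `sigma` vectors and `params`, the full
#'   combination matrix (columns x, y, sigma).
#' @export
searchGrid <- function(nXY = 15L, xyMaxDeg = 8.925, nSigma = 34L,
                       sigmaRangeDeg = c(0.18, 17)) {
  xs <- seq(-xyMaxDeg, xyMaxDeg, length.out = nXY)
  sig <- exp(seq(log(sigmaRangeDeg[1]), log(sigmaRangeDeg[2]),
                 length.out = nSigma))
  params <- cbind(x = rep(xs, each = nXY * nSigma),
                  y = rep(rep(xs, each = nSigma), times = nXY),
                  sigma = rep(sig, times = nXY * nXY))
  list(x = xs, y = xs, sigma = sig, params = params)
}

# Flattened aperture pixel matrix at TR resolution plus pixel coordinates;
# shared by the coarse predictions and the C++ fine-fit objective.
.maskMatrixTR <- function(apertures, trS = 1) {
  fr <- frames(apertures)
  grid <- fieldGrid(apertures)
  npix <- prod(dim(fr)[1:2])
  M <- resampleToTR(matrix(fr, npix, dim(fr)[3]), frameDuration(apertures),
                    trS)
  pc <- pixelCoords(grid)
  # Mt: time-by-pixel transpose consumed by the C++ kernels (contiguous
  # per-pixel time courses)
  list(M = M, Mt = t(M), xs = pc$x, ys = pc$y, grid = grid)
}

# cache of coarse prediction matrices keyed by grid/aperture fingerprint
.predCache <- new.env(parent = emptyenv())

#' Precomputed coarse-search prediction matrix
#'
#' Builds (and caches per session) the HRF-convolved predicted time series
#' for every parameter combination of the coarse [searchGrid()]. The
#' separable structure of the Gaussian is exploited so the build stays fast.
#'
#' @param apertures an [ApertureStack-class].
#' @param hrf HRF kernel at `trS`.
#' @param trS repetition time (s).
#' @param grid search grid from [searchGrid()].
#' @param cache reuse a previous build for identical inputs?
#' @return List with `params` (n x 3) and `pred` (n x volumes), plus `predZ`
#'   (row-standardised predictions for correlation).
#' @export
coarsePredictions <- function(apertures, hrf = canonicalHRF(trS), trS = 1,
                              grid = searchGrid(), cache = TRUE) {
  mm <- .maskMatrixTR(apertures, trS)
  key <- paste(format(c(dim(mm$M), sum(mm$M), sum(mm$M^2),
                        range(grid$sigma), length(grid$x), sum(hrf)),
                      digits = 15), collapse = "|")
  if (cache && !is.null(.predCache[[key]])) return(.predCache[[key]])
  nT <- ncol(mm$M)
  params <- grid$params
  pred <- matrix(0, nrow(params), nT)
  h <- length(mm$ys); w <- length(mm$xs)
  # row index blocks follow x-major order used in searchGrid()
  for (si in seq_along(grid$sigma)) {
    s <- grid$sigma[si]
    Gx <- sapply(grid$x, function(xc) exp(-(mm$xs - xc)^2 / (2 * s^2)))
    Gy <- sapply(grid$y, function(yc) exp(-(mm$ys - yc)^2 / (2 * s^2)))
    # overlap for all centres at this sigma, frame by frame
    O <- array(0, c(length(grid$y), length(grid$x), nT))
    for (t in seq_len(nT)) {
      Ft <- matrix(mm$M[, t], h, w)
      O[, , t] <- crossprod(Gy, Ft %*% Gx)       # ny x nx
    }
    norm <- outer(colSums(Gy), colSums(Gx))       # in-grid profile sums
    for (xi in seq_along(grid$x)) for (yi in seq_along(grid$y)) {
      r <- ((xi - 1L) * length(grid$y) + (yi - 1L)) * length(grid$sigma) + si
      pred[r, ] <- O[yi, xi, ] / norm[yi, xi]
    }
  }
  pred <- convolveHRF(pred, hrf)
  predSd <- sqrt(pmax(0, rowMeans(pred^2) - rowMeans(pred)^2))
  predZ <- (pred - rowMeans(pred)) / ifelse(predSd < 1e-12, Inf, predSd)
  out <- list(params = params, pred = pred, predZ = predZ)
  if (cache) .predCache[[key]] <- out
  out
}

#' Coarse pRF fit by maximal correlation
#'
#' Correlates each observed series with every precomputed prediction and
#' returns the argmax grid parameters and correlation. Candidates whose
#' squared correlation does not exceed the goodness-of-fit threshold, and
#' constant observed series (correlation undefined), are returned as
#' not-fit (`NA` parameters). Ties resolve to the first candidate in the
#' deterministic x-major scan order.
#'
#' @param observed numeric vector or vertices-by-volumes matrix.
#' @param predictions from [coarsePredictions()].
#' @param r2Threshold minimum squared correlation to count as fit.
#' @return data.frame with columns `x`, `y`, `sigma`, `r` and `fit`.
#' @export
coarseFit <- function(observed, predictions, r2Threshold = 0.05) {
  obs <- if (is.matrix(observed)) observed else matrix(observed, nrow = 1)
  nT <- ncol(obs)
  obsSd <- sqrt(pmax(0, rowMeans(obs^2) - rowMeans(obs)^2))
  constant <- obsSd < 1e-12
  obsZ <- (obs - rowMeans(obs)) / ifelse(constant, Inf, obsSd)
  out <- data.frame(x = rep(NA_real_, nrow(obs)), y = NA_real_,
                    sigma = NA_real_, r = NA_real_, fit = FALSE)
  chunk <- 1024L
  for (i0 in seq(1L, nrow(obs), by = chunk)) {
    ii <- i0:min(i0 + chunk - 1L, nrow(obs))
    R <- tcrossprod(obsZ[ii, , drop = FALSE], predictions$predZ) / nT
    best <- max.col(R, ties.method = "first")
    rbest <- R[cbind(seq_along(ii), best)]
    out$x[ii] <- predictions$params[best, "x"]
    out$y[ii] <- predictions$params[best, "y"]
    out$sigma[ii] <- predictions$params[best, "sigma"]
    out$r[ii] <- rbest
    out$fit[ii] <- rbest^2 > r2Threshold
  }
  out$fit[constant] <- FALSE
  out[constant, c("x", "y", "sigma", "r")] <- NA_real_
  out
}

#' Fine pRF fit by SSE minimisation
#'
#' Refines the coarse seed by derivative-free (Nelder-Mead) minimisation of
#' the sum of squared errors between the predicted and observed series over
#' `(x, y, sigma)`; the response amplitude `beta` and an intercept are
#' solved in closed form per candidate. Bounds (x, y in [-10, 10], sigma in
#' [0.05, 17]) are enforced through a quadratic penalty; sigma is optimised
#' on the log scale.
#'
#' @param observed numeric vector (one vertex).
#' @param seedPar numeric `c(x, y, sigma)` from the coarse fit.
#' @param maskEnv precomputed mask environment from an internal call; pass
#'   `apertures` instead for one-off fits.
#' @param apertures an [ApertureStack-class] (ignored if `maskEnv` given).
#' @param hrf HRF kernel at `trS`.
#' @param trS repetition time (s).
#' @param maxit iteration cap for the optimiser.
#' @param reltol relative SSE convergence tolerance.
#' @return List with `x`, `y`, `sigma`, `beta`, `intercept`, `r2`, `sse`
#'   and `converged`.
#' @export
fineFit <- function(observed, seedPar, maskEnv = NULL, apertures = NULL,
                    hrf = canonicalHRF(trS), trS = 1, maxit = 500L,
                    reltol = 1e-6) {
  if (is.null(maskEnv)) {
    if (is.null(apertures)) stop("supply maskEnv or apertures")
    maskEnv <- .maskMatrixTR(apertures, trS)
  }
  obs <- as.numeric(observed)
  bounds <- list(xy = 10, sigma = c(0.05, 17))
  obj <- function(p) {
    x <- p[1]; y <- p[2]; s <- exp(p[3])
    pen <- 0
    if (abs(x) > bounds$xy) pen <- pen + (abs(x) - bounds$xy)^2
    if (abs(y) > bounds$xy) pen <- pen + (abs(y) - bounds$xy)^2
    if (s < bounds$sigma[1]) pen <- pen + (bounds$sigma[1] - s)^2
    if (s > bounds$sigma[2]) pen <- pen + (s - bounds$sigma[2])^2
    xc <- min(max(x, -bounds$xy), bounds$xy)
    yc <- min(max(y, -bounds$xy), bounds$xy)
    sc <- min(max(s, bounds$sigma[1]), bounds$sigma[2])
    .cppPrfSSE(maskEnv$Mt, maskEnv$xs, maskEnv$ys, xc, yc, sc, hrf, obs) +
      1e6 * pen
  }
  p0 <- c(seedPar[1], seedPar[2], log(seedPar[3]))
  opt <- stats::optim(p0, obj, method = "Nelder-Mead",
                      control = list(maxit = maxit, reltol = reltol))
  best <- if (opt$value <= obj(p0)) opt$par else p0
  x <- min(max(best[1], -bounds$xy), bounds$xy)
  y <- min(max(best[2], -bounds$xy), bounds$xy)
  s <- min(max(exp(best[3]), bounds$sigma[1]), bounds$sigma[2])
  pred <- .cppPrfPredict(maskEnv$Mt, maskEnv$xs, maskEnv$ys, x, y, s, hrf)
  fit <- stats::lm.fit(cbind(1, pred), obs)
  sse <- sum(fit$residuals^2)
  sst <- sum((obs - mean(obs))^2)
  list(x = x, y = y, sigma = s, beta = unname(fit$coefficients[2]),
       intercept = unname(fit$coefficients[1]),
       r2 = 1 - sse / sst, sse = sse, converged = opt$convergence == 0L)
}

#' Fit pRFs for a whole observer
#'
#' Runs the two-stage procedure (coarse correlation search, then fine SSE
#' optimisation) on every vertex of a mapping-run [BoldSeries-class] and
#' attaches the fitted table to the ensemble. Vertices failing the coarse
#' goodness-of-fit gate keep `NA` parameters. A `smoother` hook may be
#' supplied to smooth the series across vertex neighbourhoods before the
#' coarse stage (cortical-surface smoothing has no synthetic counterpart, so
#' the default is the identity).
#'
#' @param ensemble an [ObserverEnsemble-class].
#' @param bold mapping-run [BoldSeries-class] (vertex order must match the
#'   ensemble).
#' @param apertures the mapping [ApertureStack-class].
#' @param hrf HRF kernel at the series TR.
#' @param grid coarse [searchGrid()].
#' @param r2Threshold coarse goodness-of-fit gate.
#' @param smoother optional function `matrix -> matrix` applied before the
#'   coarse stage only (the fine stage always sees the unsmoothed series).
#' @param verbose print progress?
#' @return The ensemble with `fittedPRF(ensemble)` filled (columns
#'   `vertex`, `x`, `y`, `sigma`, `beta`, `r2`, `converged`).
#' @export
fitPRF <- function(ensemble, bold, apertures, hrf = canonicalHRF(trS),
                   grid = searchGrid(), r2Threshold = 0.05,
                   smoother = identity, verbose = FALSE) {
  trS <- trSeconds(bold)
  Y <- boldData(bold)
  stopifnot(nrow(Y) == nrow(truthPRF(ensemble)))
  preds <- coarsePredictions(apertures, hrf, trS, grid)
  coarse <- coarseFit(smoother(Y), preds, r2Threshold)
  maskEnv <- .maskMatrixTR(apertures, trS)
  n <- nrow(Y)
  fitted <- data.frame(vertex = truthPRF(ensemble)$vertex,
                       x = NA_real_, y = NA_real_, sigma = NA_real_,
                       beta = NA_real_, r2 = coarse$r^2, converged = FALSE)
  for (i in seq_len(n)) {
    if (!coarse$fit[i]) next
    ff <- fineFit(Y[i, ], c(coarse$x[i], coarse$y[i], coarse$sigma[i]),
                  maskEnv = maskEnv, hrf = hrf, trS = trS)
    fitted$x[i] <- ff$x; fitted$y[i] <- ff$y; fitted$sigma[i] <- ff$sigma
    fitted$beta[i] <- ff$beta; fitted$r2[i] <- ff$r2
    fitted$converged[i] <- ff$converged
    if (verbose && i %% 500L == 0L)
      message(sprintf("  fine fit %d/%d", i, n))
  }
  fittedPRF(ensemble) <- fitted
  ensemble
}
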