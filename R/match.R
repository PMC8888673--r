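# Encoding-model matching: predict sliding-window profiles for banks of
# simulated-stimulus masks from the fitted pRFs, correlate with observed
# profiles, and return the best-matching physical parameter with the full
# correlation map.

# Overlaps of fitted pRF profiles with mask columns, chunked. Same
# unit-amplitude Gaussian convention as the generative model, so predicted
# and observed responses share their dependence on pRF size; callers
# normalise by mask mass (a per-mask constant that cancels in profile
# shapes and correlations).
.fittedOverlaps <- function(fitted, masks, grid, chunk = 256L) {
  pc <- pixelCoords(grid)
  n <- nrow(fitted)
  out <- matrix(NA_real_, n, ncol(masks))
  ok <- which(!is.na(fitted$x) & !is.na(fitted$sigma))
  for (i0 in seq(1L, length(ok), by = chunk)) {
    ii <- ok[i0:min(i0 + chunk - 1L, length(ok))]
    W <- matrix(0, length(ii), nrow(masks))
    for (j in seq_along(ii)) {
      v <- fitted[ii[j], ]
      gx <- exp(-(pc$x - v$x)^2 / (2 * v$sigma^2))
      gy <- exp(-(pc$y - v$y)^2 / (2 * v$sigma^2))
      W[j, ] <- as.numeric(outer(gy, gx))
    }
    out[ii, ] <- W %*% masks
  }
  out
}

#' Predicted sliding-window profile for a stimulus mask
#'
#' Per vertex, the predicted response to a hypothetical stimulus is the
#' overlap of its fitted pRF profile with the binary (or rectified
#' grey-level) mask; the predictions are then pooled with exactly the same
#' sliding-window specification as the observed data.
#'
#' @param mask matrix on `grid` (or an [ApertureStack-class] frame).
#' @param vertices data.frame of fitted pRFs (`x`, `y`, `sigma`, `r2`).
#' @param spec a [WindowSpec-class].
#' @param grid the analysis [FieldGrid-class] the mask lives on.
#' @param ... passed to [slidingSample()].
#' @return A window-profile data.frame (see [slidingSample()]).
#' @export
predictProfile <- function(mask, vertices, spec = WindowSpec(),
                           grid = FieldGrid(), ...) {
  if (!all(dim(mask) == c(grid@heightPx, grid@widthPx)))
    stop("mask dimensions do not match the grid")
  vertices$response <-
    as.numeric(.fittedOverlaps(vertices, cbind(as.numeric(mask)), grid)) /
    max(sum(mask), 1e-12)
  slidingSample(vertices, spec, ...)
}

#' Predicted profiles for a whole mask bank
#'
#' Equivalent to calling [predictProfile()] on every bank mask, but the
#' per-vertex pRF overlaps are computed in one pass over the bank, which is
#' much faster for the 81- and 130-entry banks. With several window specs
#' (e.g. central and peripheral sweeps) each profile is the row-bound
#' concatenation across specs, in the order given.
#'
#' @param masks list of mask matrices (e.g. `simulatedMaskBank()$masks`).
#' @param vertices data.frame of fitted pRFs.
#' @param specs a [WindowSpec-class] or list of them.
#' @param grid the analysis [FieldGrid-class].
#' @param ... passed to [slidingSample()].
#' @return List of window-profile data.frames, one per mask.
#' @export
predictProfileBank <- function(masks, vertices, specs = WindowSpec(),
                               grid = FieldGrid(), ...) {
  if (is(specs, "WindowSpec")) specs <- list(specs)
  maskMat <- vapply(masks, as.numeric,
                    numeric(grid@heightPx * grid@widthPx))
  ov <- .fittedOverlaps(vertices, maskMat, grid)
  ov <- sweep(ov, 2, pmax(colSums(maskMat), 1e-12), "/")
  lapply(seq_along(masks), function(k) {
    v <- vertices
    v$response <- ov[, k]
    do.call(rbind, lapply(specs, function(sp)
      slidingSample(v, sp, ...)))
  })
}

#' Best-matching simulated stimulus for an observed profile
#'
#' Pearson-correlates the observed window profile with the predicted
#' profile of every bank entry over windows non-missing in both, and
#' returns the full correlation vector and the argmax parameter (first
#' index on ties). Bank entries with a constant predicted profile get
#' correlation 0 and are flagged.
#'
#' @param observed window-profile data.frame (from [slidingSample()]); when
#'   profiles were sampled at several locations, pass the row-bound
#'   concatenation used for the predictions too.
#' @param bankProfiles list of predicted window profiles, one per bank
#'   entry (e.g. from [predictProfile()] over a [simulatedMaskBank()]).
#' @param axis numeric parameter per bank entry.
#' @param minOverlap minimum number of jointly non-missing windows.
#' @return List (`MatchResult`): `axis`, `r` (correlations), `argmax`
#'   (index), `bestParameter`, `bestR`, `constant` (flags).
#' @export
bestMatch <- function(observed, bankProfiles, axis,
                      minOverlap = 3L) {
  stopifnot(length(bankProfiles) == length(axis))
  r <- numeric(length(axis))
  constant <- logical(length(axis))
  for (k in seq_along(bankProfiles)) {
    p <- bankProfiles[[k]]
    ok <- !is.na(observed$response) & !is.na(p$response)
    if (sum(ok) < minOverlap)
      stop("insufficient overlapping windows between observed and ",
           "predicted profiles")
    if (stats::sd(p$response[ok]) < 1e-12 ||
        stats::sd(observed$response[ok]) < 1e-12) {
      r[k] <- 0; constant[k] <- TRUE
    } else {
      r[k] <- stats::cor(observed$response[ok], p$response[ok])
    }
  }
  argmax <- which.max(r)
  list(axis = axis, r = r, argmax = argmax,
       bestParameter = axis[argmax], bestR = r[argmax],
       constant = constant)
}
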