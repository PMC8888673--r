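# Scoring of the psychophysical adjustment tasks and the eye-tracking
# pipeline (local-median detrend, 2-D histogram, dispersion).

#' Perceptual effect of the two-dot illusion
#'
#' Per context, the effect is the mean binary-log ratio of adjusted over
#' reference distance; the total effect sums the outward- and inward-fins
#' effects (outward minus inward, the inward effect being negative when the
#' illusion compresses apparent distance).
#'
#' @param trials data.frame with `condition` (`outward`, `inward`,
#'   optionally `none`), `reference`, `adjusted` (both > 0).
#' @return List with `perContext` (named mean log2 ratios) and `total`
#'   (outward effect minus inward effect).
#' @export
mlEffect <- function(trials) {
  need <- c("outward", "inward")
  have <- intersect(unique(trials$condition), c(need, "none"))
  if (!all(need %in% have))
    stop("trials must include both 'outward' and 'inward' contexts")
  perContext <- vapply(split(trials, trials$condition), function(d)
    mean(log2(d$adjusted / d$reference)), numeric(1))
  list(perContext = perContext,
       total = perContext[["outward"]] - perContext[["inward"]])
}

#' Illusion magnitude as a percentage
#'
#' `100 * (outward / inward - 1)`: by how many percent the outward-fins
#' distance is overestimated relative to the inward-fins distance.
#'
#' @param outwardMeanDeg,inwardMeanDeg mean adjusted distances (deg, > 0).
#' @return Percentage.
#' @export
mlIllusionPercent <- function(outwardMeanDeg, inwardMeanDeg) {
  if (outwardMeanDeg <= 0 || inwardMeanDeg <= 0)
    stop("mean distances must be positive")
  100 * (outwardMeanDeg / inwardMeanDeg - 1)
}

#' Perceptual effect of the moving-stimulus illusion
#'
#' Mean adjusted position of the control trials minus mean adjusted
#' position of the illusory trials (deg).
#'
#' @param trials data.frame with `condition` (`illusory`, `control`) and
#'   `adjusted`.
#' @return Effect in degrees.
#' @export
cbEffect <- function(trials) {
  need <- c("illusory", "control")
  if (!all(need %in% trials$condition))
    stop("trials must include both 'illusory' and 'control' conditions")
  mean(trials$adjusted[trials$condition == "control"]) -
    mean(trials$adjusted[trials$condition == "illusory"])
}

#' Detrend a gaze record with stepping local medians
#'
#' Slides a `windowS`-wide window across the record at `stepS` steps,
#' computes the median position per window and axis, assigns each sample
#' the median of the window whose centre is nearest (edge samples use the
#' nearest existing window), and subtracts it. Robust to brief spikes such
#' as blinks; slow drift is removed.
#'
#' @param gaze data.frame with `time` (s, strictly increasing), `x`, `y`.
#' @param windowS window width (s).
#' @param stepS step size (s).
#' @return The data.frame with detrended `x`, `y`.
#' @export
detrendGaze <- function(gaze, windowS = 10, stepS = 1) {
  dur <- max(gaze$time) - min(gaze$time)
  if (dur < windowS) stop("record shorter than the detrending window")
  t0 <- min(gaze$time)
  centres <- seq(t0 + windowS / 2, max(gaze$time) - windowS / 2,
                 by = stepS)
  medx <- medy <- numeric(length(centres))
  for (i in seq_along(centres)) {
    inW <- gaze$time >= centres[i] - windowS / 2 &
      gaze$time <= centres[i] + windowS / 2
    medx[i] <- stats::median(gaze$x[inW])
    medy[i] <- stats::median(gaze$y[inW])
  }
  nearest <- vapply(gaze$time, function(t) which.min(abs(centres - t)),
                    integer(1))
  gaze$x <- gaze$x - medx[nearest]
  gaze$y <- gaze$y - medy[nearest]
  gaze
}

#' Summarise a detrended gaze record
#'
#' A 2-D position histogram (bin width `binDeg`) normalised to a maximum of
#' 1, plus the per-axis dispersion as the raw median absolute deviation (no
#' normal-consistency factor).
#'
#' @param gaze data.frame with `x`, `y` (detrended, deg).
#' @param binDeg histogram bin size (deg).
#' @return List with `histogram` (matrix, max 1; dimnames give bin
#'   centres), `madX`, `madY`, `n`.
#' @export
gazeSummary <- function(gaze, binDeg = 0.05) {
  if (!nrow(gaze)) stop("empty gaze record")
  bx <- floor(gaze$x / binDeg)
  by <- floor(gaze$y / binDeg)
  xb <- seq(min(bx), max(bx)); yb <- seq(min(by), max(by))
  h <- table(factor(by, levels = yb), factor(bx, levels = xb))
  h <- matrix(as.numeric(h), length(yb), length(xb),
              dimnames = list((yb + 0.5) * binDeg, (xb + 0.5) * binDeg))
  list(histogram = h / max(h),
       madX = stats::mad(gaze$x, constant = 1),
       madY = stats::mad(gaze$y, constant = 1),
       n = nrow(gaze))
}
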