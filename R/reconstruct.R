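# Sliding-window reconstruction: collapse pRF coordinates across hemifields
# or quadrants, sample responses in stepping windows with pRF-size criteria,
# summarise profiles with a 1-D Gaussian, and apply participant-level
# exclusion rules.

#' Collapse pRF coordinates across hemifields or quadrants
#'
#' Hemifield collapse maps x to |x| (pooling mirror-symmetric stimulus
#' locations across the vertical meridian); quadrant collapse additionally
#' maps y to |y|. Responses are untouched and the operation is idempotent.
#'
#' @param vertices data.frame with at least `x`, `y`.
#' @param mode `"hemifields"` or `"quadrants"`.
#' @return The data.frame with transformed coordinates.
#' @export
collapseField <- function(vertices, mode = c("hemifields", "quadrants")) {
  mode <- match.arg(mode)
  vertices$x <- abs(vertices$x)
  if (mode == "quadrants") vertices$y <- abs(vertices$y)
  vertices
}

# active pRF-size criterion; stringent keeps pRFs whose centre +/- 1 sigma
# stays within the window height
.sizeKeep <- function(vertices, criterion, heightDeg) {
  switch(criterion,
         none = rep(TRUE, nrow(vertices)),
         lenient = vertices$sigma <= 1,
         stringent = abs(vertices$y) + vertices$sigma < heightDeg / 2)
}

#' Sample responses in sliding windows
#'
#' Steps a `width x height` window along x and averages the responses of
#' vertices whose (collapsed) pRF centre falls inside the half-open box
#' `[xc - w/2, xc + w/2) x [yc - h/2, yc + h/2)` and that pass the active
#' size criterion. Vertices with pRF eccentricity > `maxEccDeg` or pRF-model
#' `r2 <= r2Threshold` are excluded globally. Empty windows are flagged
#' missing, not fatal.
#'
#' @param vertices data.frame with `x`, `y`, `sigma`, `r2` (fitted pRFs) and
#'   `response`; coordinates are collapsed internally according to the spec.
#' @param spec a [WindowSpec-class].
#' @param maxEccDeg global eccentricity cutoff (deg) applied to the fitted
#'   pRF position before collapsing.
#' @param r2Threshold pRF goodness-of-fit gate.
#' @return data.frame (`WindowProfile`): `centre`, `response`, `n`,
#'   `missing`, with the spec attached as attribute `"spec"`.
#' @export
slidingSample <- function(vertices, spec = WindowSpec(), maxEccDeg = 8.5,
                          r2Threshold = 0.05) {
  validObject(spec)
  keep <- !is.na(vertices$x) & !is.na(vertices$sigma) &
    sqrt(vertices$x^2 + vertices$y^2) <= maxEccDeg &
    !is.na(vertices$r2) & vertices$r2 > r2Threshold
  v <- collapseField(vertices[keep, , drop = FALSE], spec@collapse)
  v <- v[.sizeKeep(v, spec@sizeCriterion, spec@heightDeg), , drop = FALSE]
  centres <- seq(spec@sweepFrom, spec@sweepTo, by = spec@stepDeg)
  inY <- v$y >= spec@yCentreDeg - spec@heightDeg / 2 &
    v$y < spec@yCentreDeg + spec@heightDeg / 2
  resp <- numeric(length(centres)); n <- integer(length(centres))
  for (i in seq_along(centres)) {
    inW <- inY & v$x >= centres[i] - spec@widthDeg / 2 &
      v$x < centres[i] + spec@widthDeg / 2
    n[i] <- sum(inW)
    resp[i] <- if (n[i]) mean(v$response[inW]) else NA_real_
  }
  out <- data.frame(centre = centres, response = resp, n = n,
                    missing = n == 0L)
  attr(out, "spec") <- spec
  out
}

#' Fit a 1-D Gaussian to a window profile
#'
#' Least-squares fit of `alpha + beta * exp(-(c - mu)^2 / (2 sigma^2))` over
#' the window centres, with missing windows omitted from the objective
#' (never interpolated). When the profile carries per-window vertex counts
#' (column `n`), windows are weighted by their count: a window mean over n
#' vertices has sampling variance proportional to 1/n, so sparse outer
#' windows no longer dominate the tails of the fit. Initialised at the
#' argmax window (`mu`), 1 deg (`sigma`), the profile minimum (`alpha`) and
#' range (`beta`); Levenberg-Marquardt with bounds `sigma` in (0.05, 10],
#' `mu` within the sweep range +/- 1 deg. The reported `r2` is unweighted.
#'
#' @param profile data.frame from [slidingSample()] (columns `centre`,
#'   `response` and optionally `n`).
#' @param minPoints minimum number of non-missing windows.
#' @param countWeights weight windows by vertex count when available?
#' @return List (`GaussFit1D`): `alpha`, `beta`, `mu`, `sigma`, `r2`,
#'   `ok` (FALSE marks a fit failure, with the other fields NA).
#' @export
fitProfile <- function(profile, minPoints = 5L, countWeights = TRUE) {
  ok <- !is.na(profile$response)
  cc <- profile$centre[ok]; yy <- profile$response[ok]
  w <- if (countWeights && !is.null(profile$n)) profile$n[ok] else
    rep(1, sum(ok))
  fail <- list(alpha = NA_real_, beta = NA_real_, mu = NA_real_,
               sigma = NA_real_, r2 = NA_real_, ok = FALSE)
  if (sum(ok) < minPoints) return(fail)
  start <- c(alpha = min(yy), beta = max(yy) - min(yy),
             mu = cc[which.max(yy)], sigma = 1)
  lower <- c(-Inf, -Inf, min(profile$centre) - 1, 0.05)
  upper <- c(Inf, Inf, max(profile$centre) + 1, 10)
  resid <- function(p) yy - (p[1] + p[2] * exp(-(cc - p[3])^2 /
                                                 (2 * p[4]^2)))
  fit <- try(minpack.lm::nls.lm(start, lower, upper,
                                fn = function(p) sqrt(w) * resid(p),
                                control = minpack.lm::nls.lm.control(
                                  maxiter = 500)), silent = TRUE)
  if (inherits(fit, "try-error")) return(fail)
  p <- fit$par
  sse <- sum(resid(p)^2)
  sst <- sum((yy - mean(yy))^2)
  list(alpha = unname(p[1]), beta = unname(p[2]), mu = unname(p[3]),
       sigma = unname(p[4]), r2 = if (sst > 0) 1 - sse / sst else NA_real_,
       ok = TRUE)
}

#' Participant-level exclusion rules for profile fits
#'
#' Drops a participant when any condition's profile fit quality is an
#' outlier — `r2` below the other participants' mean minus 2.5 of their SD,
#' per condition/location cell (leave-one-out moments, so a gross outlier
#' cannot mask itself by inflating the group SD) — when two conditions' fit
#' qualities are highly dissimilar (absolute `r2` difference above
#' `maxR2Diff` within a location), or when any sampled window was empty
#' under the active criterion.
#'
#' @param fits data.frame with columns `participant`, `condition`,
#'   optionally `location`, `r2` and optionally `anyEmpty` (logical).
#' @param sdRule SD multiplier for the poor-fit rule.
#' @param maxR2Diff maximum tolerated between-condition `r2` difference.
#' @return data.frame per participant: `participant`, `keep`, `reason`.
#' @export
exclusionRules <- function(fits, sdRule = 2.5, maxR2Diff = 0.3) {
  if (!"location" %in% names(fits)) fits$location <- "all"
  participants <- unique(fits$participant)
  if (length(participants) < 3L)
    stop("need >= 3 participants for the SD rule")
  reason <- stats::setNames(rep("", length(participants)),
                            as.character(participants))
  for (cell in split(fits, list(fits$condition, fits$location),
                     drop = TRUE)) {
    for (i in seq_len(nrow(cell))) {
      if (is.na(cell$r2[i])) next
      others <- cell$r2[-i]
      thr <- mean(others) - sdRule * stats::sd(others)
      if (!is.na(thr) && cell$r2[i] < thr) {
        p <- as.character(cell$participant[i])
        reason[p] <- paste0(reason[p], "poor_fit;")
      }
    }
  }
  for (loc in split(fits, list(fits$participant, fits$location),
                    drop = TRUE)) {
    if (nrow(loc) >= 2L && diff(range(loc$r2)) > maxR2Diff)
      reason[as.character(loc$participant[1])] <-
        paste0(reason[as.character(loc$participant[1])], "dissimilar_fit;")
  }
  if ("anyEmpty" %in% names(fits)) {
    bad <- unique(fits$participant[fits$anyEmpty])
    for (p in bad) reason[as.character(p)] <-
        paste0(reason[as.character(p)], "empty_window;")
  }
  data.frame(participant = participants,
             keep = reason[as.character(participants)] == "",
             reason = sub(";$", "", reason[as.character(participants)]),
             row.names = NULL)
}
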