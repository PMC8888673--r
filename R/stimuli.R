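# Stimulus apertures and masks: rotating wedge / expanding ring mapping
# apertures, the two-dot illusion displays with contextual fins, drifting
# Gabor movies, and the simulated-stimulus mask banks used by the
# encoding-model matching stage.

# pixel-centre coordinate matrices for a grid (columns = x, rows = y)
.gridXY <- function(grid) {
  pc <- pixelCoords(grid)
  list(x = matrix(pc$x, grid@heightPx, grid@widthPx, byrow = TRUE),
       y = matrix(pc$y, grid@heightPx, grid@widthPx))
}

# rasterise filled discs: a pixel belongs to a disc iff its centre lies
# within the radius (no anti-aliasing, deterministic binary masks)
.discMask <- function(grid, cx, cy, radius) {
  xy <- .gridXY(grid)
  m <- matrix(0, grid@heightPx, grid@widthPx)
  for (i in seq_along(cx))
    m[(xy$x - cx[i])^2 + (xy$y - cy[i])^2 <= radius^2] <- 1
  m
}

#' Rotating-wedge mapping aperture
#'
#' One frame of the retinotopic mapping wedge: a 12-degree polar-angle wedge
#' of maximal eccentricity 8.5 deg that rotates around fixation in 60
#' discrete steps of 6 deg (50\% overlap between consecutive wedges). Step 0
#' is centred on the upper vertical meridian; clockwise steps advance toward
#' positive x.
#'
#' @param stepIndex integer in `[0, 60)`.
#' @param direction `"cw"` or `"ccw"`.
#' @param grid a [FieldGrid-class].
#' @param wedgeWidthDeg wedge polar-angle width (deg).
#' @param maxEccDeg maximal eccentricity (deg).
#' @param nSteps steps per full rotation.
#' @return A binary `heightPx x widthPx` matrix.
#' @export
wedgeAperture <- function(stepIndex, direction = c("cw", "ccw"),
                          grid = FieldGrid(), wedgeWidthDeg = 12,
                          maxEccDeg = 8.5, nSteps = 60L) {
  direction <- match.arg(direction)
  if (length(stepIndex) != 1L || stepIndex < 0 || stepIndex >= nSteps)
    stop("stepIndex must lie in [0, ", nSteps, ")")
  stepDeg <- 360 / nSteps
  centreDeg <- 90 + (if (direction == "cw") -1 else 1) * stepDeg * stepIndex
  xy <- .gridXY(grid)
  ecc <- sqrt(xy$x^2 + xy$y^2)
  ang <- atan2(xy$y, xy$x) * 180 / pi
  d <- abs(((ang - centreDeg + 180) %% 360) - 180)  # angular distance
  (ecc <= maxEccDeg & d <= wedgeWidthDeg / 2) * 1
}

# log-spaced outer diameters for the ring aperture; the smallest outer
# diameter puts the inner circle at its floor
.ringOuterDiams <- function(nSteps = 36L, maxDiamDeg = 17, innerRatio = 0.57,
                            minInnerDeg = 0.48) {
  exp(seq(log(minInnerDeg / innerRatio), log(maxDiamDeg), length.out = nSteps))
}

#' Expanding/contracting ring mapping aperture
#'
#' One frame of the mapping ring: an annulus whose outer diameter steps
#' logarithmically up to 17 deg (maximal eccentricity 8.5 deg) across 36
#' steps, keeping the inner diameter a fixed 57\% of the outer (within the
#' 56--58\% band) and never below 0.48 deg. `"expand"` orders steps from
#' smallest to largest outer diameter; `"contract"` reverses the order.
#'
#' @param stepIndex integer in `[0, 36)`.
#' @param phase `"expand"` or `"contract"`.
#' @param grid a [FieldGrid-class].
#' @param nSteps number of logarithmic steps.
#' @param maxDiamDeg largest outer diameter (deg).
#' @param innerRatio inner/outer diameter ratio.
#' @param minInnerDeg floor on the inner diameter (deg).
#' @return A binary matrix frame.
#' @export
ringAperture <- function(stepIndex, phase = c("expand", "contract"),
                         grid = FieldGrid(), nSteps = 36L, maxDiamDeg = 17,
                         innerRatio = 0.57, minInnerDeg = 0.48) {
  phase <- match.arg(phase)
  if (length(stepIndex) != 1L || stepIndex < 0 || stepIndex >= nSteps)
    stop("stepIndex must lie in [0, ", nSteps, ")")
  outer <- .ringOuterDiams(nSteps, maxDiamDeg, innerRatio, minInnerDeg)
  if (phase == "contract") outer <- rev(outer)
  od <- outer[stepIndex + 1L]
  id <- max(minInnerDeg, innerRatio * od)
  xy <- .gridXY(grid)
  ecc <- sqrt(xy$x^2 + xy$y^2)
  (ecc >= id / 2 & ecc <= od / 2 & ecc <= maxDiamDeg / 2) * 1
}

#' Standard synthetic mapping protocol
#'
#' The aperture sequence used for synthetic mapping runs: one clockwise wedge
#' cycle (60 steps), one expanding ring cycle (36), one counter-clockwise
#' wedge cycle (60) and one contracting ring cycle (36), at one step per
#' second — 192 frames in total.
#'
#' @param grid a [FieldGrid-class].
#' @return An [ApertureStack-class] with `frameDurationS = 1`.
#' @export
mappingApertures <- function(grid = FieldGrid()) {
  fr <- array(0, c(grid@heightPx, grid@widthPx, 192L))
  k <- 0L
  for (s in 0:59) fr[, , k <- k + 1L] <- wedgeAperture(s, "cw", grid)
  for (s in 0:35) fr[, , k <- k + 1L] <- ringAperture(s, "expand", grid)
  for (s in 0:59) fr[, , k <- k + 1L] <- wedgeAperture(s, "ccw", grid)
  for (s in 0:35) fr[, , k <- k + 1L] <- ringAperture(s, "contract", grid)
  ApertureStack(fr, frameDurationS = 1, grid = grid)
}

#' Two-dot illusion display masks
#'
#' Binary masks for the dot-variant geometric illusion: two target dots on
#' the horizontal meridian mirrored across fixation, plus eight contextual
#' (fin) dots at a 45-degree polar angle from each target. Consecutive dots
#' along a fin are `finSpacingDeg` apart centre-to-centre; `"outward"` fins
#' point away from fixation, `"inward"` toward it, `"none"` draws no context.
#'
#' @param condition `"outward"`, `"inward"` or `"none"`.
#' @param grid a [FieldGrid-class].
#' @param targetEccDeg target-dot eccentricity (deg).
#' @param dotDiameterDeg dot diameter (deg).
#' @param finAngleDeg fin angle from the horizontal (deg).
#' @param finSpacingDeg centre-to-centre dot spacing along a fin (deg).
#' @return List with binary matrices `target` and `context` (disjoint).
#' @export
muellerLyerMasks <- function(condition = c("outward", "inward", "none"),
                             grid = FieldGrid(), targetEccDeg = 4,
                             dotDiameterDeg = 0.64, finAngleDeg = 45,
                             finSpacingDeg = 1.36) {
  condition <- match.arg(condition)
  r <- dotDiameterDeg / 2
  tx <- c(-targetEccDeg, targetEccDeg)
  ty <- c(0, 0)
  cx <- cy <- numeric(0)
  if (condition != "none") {
    a <- finAngleDeg * pi / 180
    s <- if (condition == "outward") 1 else -1
    for (side in c(-1, 1)) {        # left / right target
      for (vert in c(-1, 1)) {      # lower / upper fin
        for (k in 1:2) {            # two dots per fin
          cx <- c(cx, side * targetEccDeg + side * s * k * finSpacingDeg *
                    cos(a))
          cy <- c(cy, vert * k * finSpacingDeg * sin(a))
        }
      }
    }
  }
  allx <- c(tx, cx); ally <- c(ty, cy)
  if (any(abs(allx) + r > grid@extentDeg | abs(ally) + r > grid@extentDeg))
    stop("dot geometry exceeds the FieldGrid extent")
  list(target = .discMask(grid, tx, ty, r),
       context = if (length(cx)) .discMask(grid, cx, cy, r) else
         matrix(0, grid@heightPx, grid@widthPx))
}

# Gabor patch added onto a background frame within a truncation window.
# Carrier: cos(2*pi*(freq * proj - tf * t)), where proj projects the pixel
# offset onto the drift direction.
.addGabor <- function(frame, grid, cx, cy, driftDir, tSec,
                      wavelengthDeg = 0.4, envSigmaDeg = 0.192, tfHz = 10,
                      truncSigmas = 4) {
  pc <- pixelCoords(grid)
  lim <- truncSigmas * envSigmaDeg
  cols <- which(pc$x >= cx - lim & pc$x <= cx + lim)
  rows <- which(pc$y >= cy - lim & pc$y <= cy + lim)
  if (!length(cols) || !length(rows)) return(frame)
  dx <- matrix(pc$x[cols] - cx, length(rows), length(cols), byrow = TRUE)
  dy <- matrix(pc$y[rows] - cy, length(rows), length(cols))
  env <- exp(-(dx^2 + dy^2) / (2 * envSigmaDeg^2))
  proj <- dx * driftDir[1] + dy * driftDir[2]
  carrier <- cos(2 * pi * (proj / wavelengthDeg - tfHz * tSec))
  frame[rows, cols] <- frame[rows, cols] + 0.5 * env * carrier
  frame
}

#' Drifting-Gabor movie frames
#'
#' Grey-level frames (background 0.5) of four Gabor patches, one per visual
#' quadrant, mirrored across both meridians at a horizontal offset of
#' `xOffsetDeg`. Each patch travels toward the horizontal meridian at
#' `speedDegPerS` for `tripDurationS` seconds (7.2 deg path with the
#' defaults, no reversal), starting at the vertical screen edge
#' (`|y| = yStartDeg`). The internal carrier drifts at `internalTfHz`:
#' orthogonal to the path and outward in the `"illusory"` condition,
#' anti-parallel to the path in the `"control"` condition — the envelope
#' trajectories are identical in both. `pathAngleDeg` tilts the motion path
#' about its start point, positive = outward.
#'
#' @param condition `"illusory"` or `"control"`.
#' @param nFrames number of frames spanning one trip (>= 2); default 150
#'   (60 Hz over 2.5 s).
#' @param grid a [FieldGrid-class].
#' @param pathAngleDeg path tilt about the start point (deg, outward > 0).
#' @param xOffsetDeg horizontal patch offset (deg).
#' @param speedDegPerS external speed (deg/s).
#' @param tripDurationS trip duration (s).
#' @param yStartDeg |y| of the path start (deg); default half the 17.1-deg
#'   screen height.
#' @param wavelengthDeg,envSigmaDeg,internalTfHz carrier wavelength, envelope
#'   SD (deg) and internal temporal frequency (Hz).
#' @return An [ApertureStack-class] of grey-level frames.
#' @export
curveballFrames <- function(condition = c("illusory", "control"),
                            nFrames = 150L, grid = FieldGrid(),
                            pathAngleDeg = 0, xOffsetDeg = 4,
                            speedDegPerS = 2.88, tripDurationS = 2.5,
                            yStartDeg = 8.55, wavelengthDeg = 0.4,
                            envSigmaDeg = 0.192, internalTfHz = 10) {
  condition <- match.arg(condition)
  if (nFrames < 2L) stop("nFrames must be >= 2")
  th <- pathAngleDeg * pi / 180
  pathLen <- speedDegPerS * tripDurationS
  tt <- seq(0, tripDurationS, length.out = nFrames)
  fr <- array(0.5, c(grid@heightPx, grid@widthPx, nFrames))
  for (i in seq_len(nFrames)) {
    frame <- fr[, , i]
    dist <- speedDegPerS * tt[i]
    for (sx in c(-1, 1)) for (sy in c(-1, 1)) {
      # path direction: toward the meridian, tilted outward by pathAngleDeg
      dir <- c(sx * sin(th), -sy * cos(th))
      cx <- sx * xOffsetDeg + dist * dir[1]
      cy <- sy * yStartDeg + dist * dir[2]
      drift <- if (condition == "illusory") c(sx, 0) else -dir
      frame <- .addGabor(frame, grid, cx, cy, drift, tt[i],
                         wavelengthDeg, envSigmaDeg, internalTfHz)
    }
    fr[, , i] <- frame
  }
  fr[fr < 0] <- 0; fr[fr > 1] <- 1
  ApertureStack(fr, frameDurationS = tripDurationS / nFrames, grid = grid)
}

#' Rectify and average a stimulus stack into a single mask
#'
#' Applies `|v - 0.5| * 2` to every frame — sending the grey background to 0,
#' folding dark troughs onto bright peaks and normalising the maximum to 1 —
#' then averages across frames. Note both extremes map to 1 (black and white
#' pixels alike), so the transform is meant for grey-level stacks on a 0.5
#' background.
#'
#' @param stack an [ApertureStack-class] with values in `[0, 1]`.
#' @return A single matrix in `[0, 1]`.
#' @export
rectifyAverage <- function(stack) {
  fr <- frames(stack)
  if (dim(fr)[3] < 1L) stop("empty stack")
  rect <- abs(fr - 0.5) * 2
  apply(rect, c(1, 2), mean)
}

#' Simulated-stimulus mask banks
#'
#' Banks of hypothetical-stimulus masks for encoding-model matching.
#' `"mueller_lyer"`: 130 two-dot masks whose inter-dot distance grows by
#' 0.128 deg per mask (0.064 deg per side), symmetric about fixation.
#' `"curveball"`: 81 rectified-averaged trajectory masks for straight paths
#' pivoting at the path start, tilt angles -40..40 deg in 1-degree steps
#' (outward positive), each averaged over 150 frames.
#'
#' @param experiment `"mueller_lyer"` or `"curveball"`.
#' @param grid a [FieldGrid-class].
#' @param nMasks number of bank entries.
#' @param distStepDeg (two-dot bank) inter-dot distance increment per mask.
#' @param dotDiameterDeg (two-dot bank) dot diameter.
#' @param tiltRangeDeg (trajectory bank) symmetric tilt range.
#' @param nFrames (trajectory bank) frames averaged per mask.
#' @return List with `masks` (list of matrices), `axis` (numeric parameter
#'   per mask: inter-dot distance deg, or path tilt deg) and `axisName`.
#' @export
simulatedMaskBank <- function(experiment = c("mueller_lyer", "curveball"),
                              grid = FieldGrid(), nMasks = NULL,
                              distStepDeg = 0.128, dotDiameterDeg = 0.64,
                              tiltRangeDeg = 40, nFrames = 150L) {
  experiment <- match.arg(experiment)
  if (experiment == "mueller_lyer") {
    if (is.null(nMasks)) nMasks <- 130L
    axis <- distStepDeg * seq_len(nMasks)
    masks <- lapply(axis, function(d)
      .discMask(grid, c(-d / 2, d / 2), c(0, 0), dotDiameterDeg / 2))
    list(masks = masks, axis = axis, axisName = "interDotDistanceDeg")
  } else {
    if (is.null(nMasks)) nMasks <- 81L
    axis <- seq(-tiltRangeDeg, tiltRangeDeg, length.out = nMasks)
    masks <- lapply(axis, function(a)
      rectifyAverage(curveballFrames("illusory", nFrames = nFrames,
                                     grid = grid, pathAngleDeg = a)))
    list(masks = masks, axis = axis, axisName = "pathTiltDeg")
  }
}
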