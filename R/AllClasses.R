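#' @import methods
NULL

#' FieldGrid: pixel raster over the visual field
#'
#' A square pixel grid representing the visual field around fixation, used to
#' rasterise stimulus apertures and pRF profiles. The grid spans
#' `[-extentDeg, extentDeg]` in both x (positive rightward) and y (positive
#' upward), in degrees of visual angle, with fixation at the centre. Pixel
#' `(row, col)` has its centre at
#' `x = -extentDeg + (col - 0.5) * degPerPix` and
#' `y =  extentDeg - (row - 0.5) * degPerPix`, so degree/pixel conversion is
#' exact and invertible at pixel centres.
#'
#' @slot widthPx,heightPx integer pixel dimensions (square pixels required).
#' @slot extentDeg half-width of the represented field in degrees.
#'
#' @examples
#' g <- FieldGrid()
#' degPerPix(g)
#' @export
setClass("FieldGrid",
  representation(widthPx = "integer", heightPx = "integer",
                 extentDeg = "numeric"),
  prototype(widthPx = 100L, heightPx = 100L, extentDeg = 8.925))

setValidity("FieldGrid", function(object) {
  msg <- character()
  if (length(object@widthPx) != 1L || object@widthPx < 1L)
    msg <- c(msg, "widthPx must be a single positive integer")
  if (length(object@heightPx) != 1L || object@heightPx < 1L)
    msg <- c(msg, "heightPx must be a single positive integer")
  if (object@widthPx != object@heightPx)
    msg <- c(msg, "pixels must be square: widthPx == heightPx")
  if (length(object@extentDeg) != 1L || object@extentDeg <= 0)
    msg <- c(msg, "extentDeg must be a single positive number")
  if (length(msg)) msg else TRUE
})

#' Construct a FieldGrid
#'
#' @param widthPx,heightPx pixel dimensions; must be equal.
#' @param extentDeg half-width of the visual field spanned, in degrees. The
#'   default (8.925 deg over 100 px) matches the coarse-search extent so that
#'   every grid-search pRF centre is representable on the mask.
#' @return A [FieldGrid-class] object.
#' @export
FieldGrid <- function(widthPx = 100L, heightPx = widthPx, extentDeg = 8.925) {
  new("FieldGrid", widthPx = as.integer(widthPx),
      heightPx = as.integer(heightPx), extentDeg = as.numeric(extentDeg))
}

setMethod("show", "FieldGrid", function(object) {
  cat(sprintf("FieldGrid: %d x %d px spanning +/-%g deg (%.4f deg/px)\n",
              object@widthPx, object@heightPx, object@extentDeg,
              degPerPix(object)))
})

#' ApertureStack: time-ordered stimulus frames in visual-field coordinates
#'
#' A sequence of frames on a common [FieldGrid-class], values in `[0, 1]`
#' (binary masks or grey-level images on a 0.5 background), together with the
#' duration of each frame in seconds. Stored as a `height x width x frame`
#' array.
#'
#' @slot frames numeric array `[heightPx, widthPx, nFrames]`, values in [0, 1].
#' @slot frameDurationS seconds per frame.
#' @slot grid the [FieldGrid-class] the frames live on.
#' @export
setClass("ApertureStack",
  representation(frames = "array", frameDurationS = "numeric",
                 grid = "FieldGrid"))

setValidity("ApertureStack", function(object) {
  msg <- character()
  d <- dim(object@frames)
  if (length(d) != 3L)
    msg <- c(msg, "frames must be a 3-D array [height, width, frame]")
  else {
    if (d[3] < 1L) msg <- c(msg, "frame count must be >= 1")
    if (d[1] != object@grid@heightPx || d[2] != object@grid@widthPx)
      msg <- c(msg, "frame dimensions must match the FieldGrid")
  }
  rng <- range(object@frames)
  if (is.na(rng[1]) || rng[1] < 0 || rng[2] > 1)
    msg <- c(msg, "frame values must lie in [0, 1] and be non-missing")
  if (length(object@frameDurationS) != 1L || object@frameDurationS <= 0)
    msg <- c(msg, "frameDurationS must be a single positive number")
  if (length(msg)) msg else TRUE
})

#' Construct an ApertureStack
#'
#' @param frames 3-D array `[height, width, frame]` or a single matrix.
#' @param frameDurationS seconds per frame.
#' @param grid a [FieldGrid-class].
#' @return An [ApertureStack-class].
#' @export
ApertureStack <- function(frames, frameDurationS = 1, grid = FieldGrid()) {
  if (is.matrix(frames)) frames <- array(frames, c(dim(frames), 1L))
  new("ApertureStack", frames = frames,
      frameDurationS = as.numeric(frameDurationS), grid = grid)
}

setMethod("show", "ApertureStack", function(object) {
  cat(sprintf("ApertureStack: %d frame(s) of %d x %d px, %.3g s/frame\n",
              dim(object@frames)[3], dim(object@frames)[1],
              dim(object@frames)[2], object@frameDurationS))
  cat("  on "); show(object@grid)
})

#' ObserverSpec: generative description of a synthetic participant
#'
#' Holds everything needed to draw a ground-truth pRF ensemble and simulate
#' its BOLD responses: vertex counts per visual area, the linear
#' size-eccentricity law per area (`sigma = intercept + slope * ecc`), the
#' sparse-coverage band around the horizontal meridian for the quarter-field
#' maps (V2/V3), response-amplitude and noise parameters, and the injected
#' apparent-position shift `deltaShiftDeg` used by the illusory generative
#' regime.
#'
#' @slot nVertices named integer vector (V1, V2, V3): vertices per hemisphere.
#' @slot sigmaIntercept,sigmaSlope named numeric (per region) size law.
#' @slot meridianGapDeg polar-angle band (deg) around the horizontal meridian
#'   with depleted V2/V3 coverage; 0 disables the gap.
#' @slot betaMean,betaSd response amplitude distribution (z-units per unit
#'   overlap).
#' @slot noiseSd white-noise SD in z-score units.
#' @slot deltaShiftDeg injected apparent outward shift (deg, >= 0).
#' @slot eccRange eccentricity range sampled (log-uniform), degrees.
#' @slot seed integer seed fixing every stochastic draw.
#' @export
setClass("ObserverSpec",
  representation(nVertices = "integer", sigmaIntercept = "numeric",
                 sigmaSlope = "numeric", meridianGapDeg = "numeric",
                 betaMean = "numeric", betaSd = "numeric",
                 noiseSd = "numeric", deltaShiftDeg = "numeric",
                 eccRange = "numeric", seed = "integer"))

setValidity("ObserverSpec", function(object) {
  msg <- character()
  regs <- c("V1", "V2", "V3")
  if (!identical(names(object@nVertices), regs))
    msg <- c(msg, "nVertices must be named c(V1=, V2=, V3=)")
  if (any(object@nVertices < 0L) || sum(object@nVertices) < 1L)
    msg <- c(msg, "vertex counts must be non-negative with a positive total")
  if (!identical(names(object@sigmaIntercept), regs) ||
      !identical(names(object@sigmaSlope), regs))
    msg <- c(msg, "sigma law must be named per region (V1, V2, V3)")
  if (any(object@sigmaIntercept <= 0) || any(object@sigmaSlope < 0))
    msg <- c(msg, "sigma intercepts must be > 0 and slopes >= 0")
  if (object@meridianGapDeg < 0) msg <- c(msg, "meridianGapDeg must be >= 0")
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
  if (object@deltaShiftDeg < 0) msg <- c(msg, "deltaShiftDeg must be >= 0")
  if (length(object@eccRange) != 2L || object@eccRange[1] <= 0 ||
      diff(object@eccRange) <= 0)
    msg <- c(msg, "eccRange must be increasing and positive")
  if (length(msg)) msg else TRUE
})

#' Construct an ObserverSpec
#'
#' Defaults describe a desk-scale observer: 2000 V1 vertices per hemisphere
#' (dense enough for 0.1-degree sliding windows), pRF size growing linearly
#' with eccentricity (V1 `0.1 + 0.1 * ecc` degrees, steeper in V2/V3),
#' response amplitude around 3 z-units at the overlap peak, and unit white
#' noise when noise is enabled.
#'
#' @param nVertices vertices per hemisphere per region, named (V1, V2, V3).
#' @param sigmaIntercept,sigmaSlope per-region linear size-eccentricity law.
#' @param meridianGapDeg depleted polar-angle band around the horizontal
#'   meridian for V2/V3 (deg of polar angle, total width).
#' @param betaMean,betaSd amplitude distribution.
#' @param noiseSd white-noise SD (z-units).
#' @param deltaShiftDeg injected apparent outward shift (deg).
#' @param eccRange sampled eccentricity range (deg), log-uniform.
#' @param seed integer seed.
#' @return An [ObserverSpec-class].
#' @export
ObserverSpec <- function(nVertices = c(V1 = 2000L, V2 = 0L, V3 = 0L),
                         sigmaIntercept = c(V1 = 0.1, V2 = 0.15, V3 = 0.2),
                         sigmaSlope = c(V1 = 0.1, V2 = 0.15, V3 = 0.2),
                         meridianGapDeg = 20,
                         betaMean = 3, betaSd = 0.5,
                         noiseSd = 1, deltaShiftDeg = 0,
                         eccRange = c(0.1, 8.5), seed = 1L) {
  nv <- c(V1 = 0L, V2 = 0L, V3 = 0L)
  nVertices <- as.integer(round(nVertices))
  if (is.null(names(nVertices)) && length(nVertices) <= 3L)
    names(nVertices) <- c("V1", "V2", "V3")[seq_along(nVertices)]
  nv[names(nVertices)] <- nVertices
  new("ObserverSpec", nVertices = nv,
      sigmaIntercept = sigmaIntercept[c("V1", "V2", "V3")],
      sigmaSlope = sigmaSlope[c("V1", "V2", "V3")],
      meridianGapDeg = as.numeric(meridianGapDeg),
      betaMean = as.numeric(betaMean), betaSd = as.numeric(betaSd),
      noiseSd = as.numeric(noiseSd),
      deltaShiftDeg = as.numeric(deltaShiftDeg),
      eccRange = as.numeric(eccRange), seed = as.integer(seed))
}

setMethod("show", "ObserverSpec", function(object) {
  cat("ObserverSpec\n")
  cat("  vertices/hemisphere:",
      paste(sprintf("%s=%d", names(object@nVertices), object@nVertices),
            collapse = ", "), "\n")
  cat(sprintf("  noiseSd=%g  delta=%g deg  seed=%d\n",
              object@noiseSd, object@deltaShiftDeg, object@seed))
})

#' ObserverEnsemble: ground-truth and fitted pRFs of a synthetic observer
#'
#' The vertex table of one synthetic participant. `truth` holds the
#' generative pRFs (never mutated by fitting); `fitted` is filled by
#' [fitPRF()] and is `NULL` until then.
#'
#' @slot truth data.frame with columns `vertex`, `region`, `hemisphere`,
#'   `x`, `y`, `sigma`, `beta` (ground truth, degrees / z-units).
#' @slot fitted `NULL` or a data.frame keyed by `vertex` with columns `x`,
#'   `y`, `sigma`, `beta`, `r2`, `converged`.
#' @slot spec the generating [ObserverSpec-class].
#' @export
setClass("ObserverEnsemble",
  representation(truth = "data.frame", fitted = "ANY", spec = "ObserverSpec"),
  prototype(fitted = NULL))

setValidity("ObserverEnsemble", function(object) {
  need <- c("vertex", "region", "hemisphere", "x", "y", "sigma", "beta")
  msg <- character()
  if (!all(need %in% names(object@truth)))
    msg <- c(msg, paste("truth must contain columns:",
                        paste(need, collapse = ", ")))
  else if (any(object@truth$sigma <= 0))
    msg <- c(msg, "all ground-truth sigma must be > 0")
  if (!is.null(object@fitted)) {
    needf <- c("vertex", "x", "y", "sigma", "beta", "r2")
    if (!all(needf %in% names(object@fitted)))
      msg <- c(msg, paste("fitted must contain columns:",
                          paste(needf, collapse = ", ")))
    else if (nrow(object@fitted) != nrow(object@truth))
      msg <- c(msg, "fitted must have one row per truth vertex")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "ObserverEnsemble", function(object) {
  cat(sprintf("ObserverEnsemble: %d vertices (%s)\n", nrow(object@truth),
              paste(sprintf("%s=%d", names(table(object@truth$region)),
                            as.integer(table(object@truth$region))),
                    collapse = ", ")))
  cat(sprintf("  fitted pRFs: %s\n",
              if (is.null(object@fitted)) "none" else
                sprintf("%d (%d converged)", nrow(object@fitted),
                        sum(object@fitted$converged, na.rm = TRUE))))
})

#' BoldSeries: per-vertex z-scored BOLD time courses
#'
#' A `vertices x volumes` matrix of (detrended, z-scored) responses at TR
#' resolution, with vertex identifiers as rownames.
#'
#' @slot data numeric matrix, vertices in rows, volumes in columns.
#' @slot trS repetition time in seconds.
#' @export
setClass("BoldSeries",
  representation(data = "matrix", trS = "numeric"))

setValidity("BoldSeries", function(object) {
  msg <- character()
  if (!is.numeric(object@data)) msg <- c(msg, "data must be numeric")
  if (length(object@trS) != 1L || object@trS <= 0)
    msg <- c(msg, "trS must be a single positive number")
  if (length(msg)) msg else TRUE
})

#' Construct a BoldSeries
#' @param data vertices-by-volumes numeric matrix.
#' @param trS repetition time (s).
#' @return A [BoldSeries-class].
#' @export
BoldSeries <- function(data, trS = 1) {
  new("BoldSeries", data = as.matrix(data), trS = as.numeric(trS))
}

setMethod("show", "BoldSeries", function(object) {
  cat(sprintf("BoldSeries: %d vertices x %d volumes, TR = %g s\n",
              nrow(object@data), ncol(object@data), object@trS))
})

#' WindowSpec: sliding-window sampling specification
#'
#' Describes how per-vertex responses are pooled into a response-versus-
#' position profile: a `widthDeg x heightDeg` window centred at `yCentreDeg`
#' steps along x at `stepDeg` between `sweepFrom` and `sweepTo` (window
#' centres). Vertices enter a window when their (collapsed) pRF centre falls
#' in the half-open box `[xc - w/2, xc + w/2) x [yc - h/2, yc + h/2)` and
#' they pass the active pRF-size criterion.
#'
#' @slot widthDeg,heightDeg window dimensions (deg).
#' @slot stepDeg step between window centres (deg, > 0).
#' @slot sweepFrom,sweepTo first and last window centre (deg).
#' @slot yCentreDeg vertical window centre (deg, post-collapse coordinates).
#' @slot collapse `"hemifields"` (x -> |x|) or `"quadrants"`
#'   ((x, y) -> (|x|, |y|)).
#' @slot sizeCriterion `"none"`, `"lenient"` (drop sigma > 1 deg) or
#'   `"stringent"` (keep |y| + sigma < height/2).
#' @export
setClass("WindowSpec",
  representation(widthDeg = "numeric", heightDeg = "numeric",
                 stepDeg = "numeric", sweepFrom = "numeric",
                 sweepTo = "numeric", yCentreDeg = "numeric",
                 collapse = "character", sizeCriterion = "character"))

setValidity("WindowSpec", function(object) {
  msg <- character()
  if (object@stepDeg <= 0) msg <- c(msg, "stepDeg must be > 0")
  if (object@widthDeg <= 0 || object@heightDeg <= 0)
    msg <- c(msg, "window dimensions must be > 0")
  if (object@sweepTo < object@sweepFrom)
    msg <- c(msg, "sweepTo must be >= sweepFrom")
  if (!object@collapse %in% c("hemifields", "quadrants"))
    msg <- c(msg, "collapse must be 'hemifields' or 'quadrants'")
  if (!object@sizeCriterion %in% c("none", "lenient", "stringent"))
    msg <- c(msg, "sizeCriterion must be none, lenient or stringent")
  if (length(msg)) msg else TRUE
})

#' Construct a WindowSpec
#'
#' Defaults give the horizontal-meridian sweep used for the two-dot
#' experiment: a 1 x 1 deg window stepping 0.1 deg with centres from 1.5 to
#' 6.5 deg, hemifield collapse. Use [curveballWindowSpec()] for the tall
#' windows of the moving-stimulus experiment.
#'
#' @param widthDeg,heightDeg window size (deg).
#' @param stepDeg step size (deg).
#' @param sweepFrom,sweepTo window-centre range (deg).
#' @param yCentreDeg vertical centre (deg).
#' @param collapse `"hemifields"` or `"quadrants"`.
#' @param sizeCriterion `"none"`, `"lenient"` or `"stringent"`.
#' @return A [WindowSpec-class].
#' @export
WindowSpec <- function(widthDeg = 1, heightDeg = 1, stepDeg = 0.1,
                       sweepFrom = 1.5, sweepTo = 6.5, yCentreDeg = 0,
                       collapse = "hemifields", sizeCriterion = "none") {
  new("WindowSpec", widthDeg = as.numeric(widthDeg),
      heightDeg = as.numeric(heightDeg), stepDeg = as.numeric(stepDeg),
      sweepFrom = as.numeric(sweepFrom), sweepTo = as.numeric(sweepTo),
      yCentreDeg = as.numeric(yCentreDeg), collapse = collapse,
      sizeCriterion = sizeCriterion)
}

#' Tall-window specs for the moving-stimulus experiment
#'
#' The motion path runs vertically toward the horizontal meridian; responses
#' are sampled in two horizontal sweeps with tall windows: a peripheral
#' 1 x 4.5 deg window over the initial part of the path (|y| in
#' [4.05, 8.55]) and a central 1 x 2 deg window over its final part (|y| in
#' [1.35, 3.35]), both stepping from 1 to 7 deg with quadrant collapse.
#'
#' @param location `"central"` or `"peripheral"`.
#' @param sizeCriterion passed through.
#' @return A [WindowSpec-class].
#' @export
curveballWindowSpec <- function(location = c("central", "peripheral"),
                                sizeCriterion = "none") {
  location <- match.arg(location)
  if (location == "central")
    WindowSpec(widthDeg = 1, heightDeg = 2, stepDeg = 0.1,
               sweepFrom = 1, sweepTo = 7, yCentreDeg = 2.35,
               collapse = "quadrants", sizeCriterion = sizeCriterion)
  else
    WindowSpec(widthDeg = 1, heightDeg = 4.5, stepDeg = 0.1,
               sweepFrom = 1, sweepTo = 7, yCentreDeg = 6.3,
               collapse = "quadrants", sizeCriterion = sizeCriterion)
}

setMethod("show", "WindowSpec", function(object) {
  cat(sprintf(
    "WindowSpec: %g x %g deg window, centres %g..%g step %g, y = %g\n",
    object@widthDeg, object@heightDeg, object@sweepFrom, object@sweepTo,
    object@stepDeg, object@yCentreDeg))
  cat(sprintf("  collapse = %s, size criterion = %s\n", object@collapse,
              object@sizeCriterion))
})
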