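#' @rdname FieldGrid-class
#' @param object a FieldGrid (or object carrying one).
#' @export
setGeneric("degPerPix", function(object) standardGeneric("degPerPix"))

#' @rdname FieldGrid-class
#' @export
setGeneric("pixelCoords", function(object) standardGeneric("pixelCoords"))

#' @rdname FieldGrid-class
#' @export
setGeneric("fieldGrid", function(object) standardGeneric("fieldGrid"))

#' @rdname ApertureStack-class
#' @param object an ApertureStack.
#' @export
setGeneric("frames", function(object) standardGeneric("frames"))

#' @rdname ApertureStack-class
#' @export
setGeneric("nFrames", function(object) standardGeneric("nFrames"))

#' @rdname ApertureStack-class
#' @export
setGeneric("frameDuration", function(object) standardGeneric("frameDuration"))

#' @rdname ObserverEnsemble-class
#' @param object an ObserverEnsemble.
#' @export
setGeneric("truthPRF", function(object) standardGeneric("truthPRF"))

#' @rdname ObserverEnsemble-class
#' @export
setGeneric("fittedPRF", function(object) standardGeneric("fittedPRF"))

#' @rdname ObserverEnsemble-class
#' @param value replacement fitted-pRF data.frame.
#' @export
setGeneric("fittedPRF<-", function(object, value)
  standardGeneric("fittedPRF<-"))

#' @rdname ObserverEnsemble-class
#' @export
setGeneric("observerSpec", function(object) standardGeneric("observerSpec"))

#' @rdname BoldSeries-class
#' @param object a BoldSeries.
#' @export
setGeneric("boldData", function(object) standardGeneric("boldData"))

#' @rdname BoldSeries-class
#' @export
setGeneric("trSeconds", function(object) standardGeneric("trSeconds"))

# -- methods ------------------------------------------------------------------

#' @rdname FieldGrid-class
#' @export
setMethod("degPerPix", "FieldGrid", function(object)
  2 * object@extentDeg / object@widthPx)

#' @describeIn FieldGrid-class x/y degree coordinates of pixel centres; a
#'   list with `x` (by column, rightward) and `y` (by row, downward in the
#'   matrix, upward in the field).
#' @export
setMethod("pixelCoords", "FieldGrid", function(object) {
  dpp <- degPerPix(object)
  list(x = -object@extentDeg + (seq_len(object@widthPx) - 0.5) * dpp,
       y = object@extentDeg - (seq_len(object@heightPx) - 0.5) * dpp)
})

#' @rdname ApertureStack-class
#' @export
setMethod("fieldGrid", "ApertureStack", function(object) object@grid)

#' @rdname ApertureStack-class
#' @export
setMethod("frames", "ApertureStack", function(object) object@frames)

#' @rdname ApertureStack-class
#' @export
setMethod("nFrames", "ApertureStack", function(object) dim(object@frames)[3])

#' @rdname ApertureStack-class
#' @export
setMethod("frameDuration", "ApertureStack", function(object)
  object@frameDurationS)

#' @rdname ObserverEnsemble-class
#' @export
setMethod("truthPRF", "ObserverEnsemble", function(object) object@truth)

#' @rdname ObserverEnsemble-class
#' @export
setMethod("fittedPRF", "ObserverEnsemble", function(object) object@fitted)

#' @rdname ObserverEnsemble-class
#' @export
setReplaceMethod("fittedPRF", "ObserverEnsemble", function(object, value) {
  object@fitted <- value
  validObject(object)
  object
})

#' @rdname ObserverEnsemble-class
#' @export
setMethod("observerSpec", "ObserverEnsemble", function(object) object@spec)

#' @rdname BoldSeries-class
#' @export
setMethod("boldData", "BoldSeries", function(object) object@data)

#' @rdname BoldSeries-class
#' @export
setMethod("trSeconds", "BoldSeries", function(object) object@trS)

#' Convert degrees to (fractional) pixel indices and back
#'
#' `degToPix` maps field coordinates (deg) to fractional matrix indices
#' (`col` for x, `row` for y); `pixToDeg` inverts it. The mapping is exact at
#' pixel centres: `pixToDeg(degToPix(x))` returns `x` for any `x`.
#'
#' @param grid a [FieldGrid-class].
#' @param x,y field coordinates in degrees.
#' @param col,row fractional pixel indices.
#' @return `degToPix`: list with `col`, `row`; `pixToDeg`: list with `x`, `y`.
#' @export
degToPix <- function(grid, x, y) {
  dpp <- degPerPix(grid)
  list(col = (x + grid@extentDeg) / dpp + 0.5,
       row = (grid@extentDeg - y) / dpp + 0.5)
}

#' @rdname degToPix
#' @export
pixToDeg <- function(grid, col, row) {
  dpp <- degPerPix(grid)
  list(x = -grid@extentDeg + (col - 0.5) * dpp,
       y = grid@extentDeg - (row - 0.5) * dpp)
}
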