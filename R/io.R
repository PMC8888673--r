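# Plain-text array container for aperture stacks and delimited tables for
# fitted pRFs. The container is a JSON header line followed by one
# full-precision ("%.17g") row of pixel values per frame, so round trips
# are bit-exact.

#' Write an ApertureStack to a text container
#'
#' @param stack an [ApertureStack-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeApertureStack <- function(stack, path) {
  grid <- fieldGrid(stack)
  header <- jsonlite::toJSON(list(
    format = "prfRecon-aperture-stack", version = 1L,
    heightPx = grid@heightPx, widthPx = grid@widthPx,
    extentDeg = grid@extentDeg, frameDurationS = frameDuration(stack),
    nFrames = nFrames(stack)), auto_unbox = TRUE, digits = NA)
  fr <- frames(stack)
  npix <- prod(dim(fr)[1:2])
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(as.character(header), con)
  M <- matrix(fr, npix, dim(fr)[3])
  for (f in seq_len(ncol(M)))
    writeLines(paste(sprintf("%.17g", M[, f]), collapse = ","), con)
  invisible(path)
}

#' Read an ApertureStack from a text container
#'
#' @param path file written by [writeApertureStack()].
#' @return An [ApertureStack-class].
#' @export
readApertureStack <- function(path) {
  lines <- readLines(path)
  hdr <- jsonlite::fromJSON(lines[1])
  if (!identical(hdr$format, "prfRecon-aperture-stack"))
    stop("not an aperture-stack container: ", path)
  grid <- FieldGrid(hdr$widthPx, hdr$heightPx, hdr$extentDeg)
  vals <- lapply(lines[-1], function(l)
    as.numeric(strsplit(l, ",", fixed = TRUE)[[1]]))
  fr <- array(unlist(vals), c(hdr$heightPx, hdr$widthPx, hdr$nFrames))
  ApertureStack(fr, hdr$frameDurationS, grid)
}

#' Write / read a fitted-pRF table
#'
#' Delimited (tab-separated) tables with one row per vertex.
#'
#' @param prf data.frame of pRF parameters.
#' @param path file path.
#' @return `writePRFTable`: `path` invisibly; `readPRFTable`: data.frame.
#' @export
writePRFTable <- function(prf, path) {
  data.table::fwrite(prf, path, sep = "\t")
  invisible(path)
}

#' @rdname writePRFTable
#' @export
readPRFTable <- function(path) {
  as.data.frame(data.table::fread(path, sep = "\t"))
}

#' Export a mask or map frame as PNG
#'
#' Greyscale export for visual inspection (requires the `png` package).
#' Values are clipped to `[0, 1]`; `NA` renders as 0.
#'
#' @param mask numeric matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeMaskPNG <- function(mask, path) {
  if (!requireNamespace("png", quietly = TRUE))
    stop("the 'png' package is required for PNG export")
  m <- pmin(pmax(mask, 0), 1)
  m[is.na(m)] <- 0
  png::writePNG(m, path)
  invisible(path)
}
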