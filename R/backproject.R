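# Searchlight backprojection of per-vertex responses into visual-field
# space, for visualisation and peak localisation.

#' Backproject vertex responses with a searchlight
#'
#' Lays a grid over the visual field (`spacingDeg` between grid points) and,
#' at each point, averages the responses of all vertices whose pRF centres
#' fall within a `radiusDeg` searchlight, weighting each vertex by inverse
#' distance `1 / (d + eps)` (the `eps` guard bounds the degenerate d = 0
#' case). The companion weight map — vertex count scaled by the mean
#' inverse distance — expresses how saturated each point's estimate is;
#' points with no in-radius vertex are masked (`NA`).
#'
#' @param vertices data.frame with fitted `x`, `y` and `response`.
#' @param extentDeg half-width of the mapped field (deg).
#' @param spacingDeg grid spacing (deg).
#' @param radiusDeg searchlight radius (deg).
#' @param eps distance guard (deg).
#' @return List (`FieldMap`): `xGrid`, `yGrid`, `value` (matrix, rows = y
#'   descending), `weight`, `extentDeg`, `spacingDeg`.
#' @export
searchlightMap <- function(vertices, extentDeg = 8.5, spacingDeg = 0.1,
                           radiusDeg = 1.0, eps = 0.05) {
  v <- vertices[!is.na(vertices$x) & !is.na(vertices$response), ,
                drop = FALSE]
  xg <- seq(-extentDeg, extentDeg, by = spacingDeg)
  yg <- rev(xg)
  val <- wt <- matrix(NA_real_, length(yg), length(xg))
  for (i in seq_along(yg)) {
    dy2 <- (v$y - yg[i])^2
    near <- dy2 <= radiusDeg^2
    if (!any(near)) next
    vx <- v$x[near]; vr <- v$response[near]; dy2n <- dy2[near]
    for (j in seq_along(xg)) {
      d2 <- (vx - xg[j])^2 + dy2n
      inR <- d2 <= radiusDeg^2
      if (!any(inR)) next
      w <- 1 / (sqrt(d2[inR]) + eps)
      val[i, j] <- sum(w * vr[inR]) / sum(w)
      wt[i, j] <- sum(inR) * mean(w)
    }
  }
  list(xGrid = xg, yGrid = yg, value = val, weight = wt,
       extentDeg = extentDeg, spacingDeg = spacingDeg)
}

#' Average searchlight maps across observers
#'
#' Pointwise mean of the map values over observers with an unmasked
#' estimate at each grid point; the weight map is the sum of the individual
#' weights. All maps must share the same grid.
#'
#' @param maps list of field maps from [searchlightMap()].
#' @return A field map of the same shape.
#' @export
groupAverage <- function(maps) {
  stopifnot(length(maps) >= 1L)
  ref <- maps[[1]]
  for (m in maps[-1])
    if (!isTRUE(all.equal(m$xGrid, ref$xGrid)) ||
        !isTRUE(all.equal(m$yGrid, ref$yGrid)))
      stop("maps must share an identical grid")
  vals <- simplify2array(lapply(maps, `[[`, "value"))
  wts <- simplify2array(lapply(maps, `[[`, "weight"))
  n <- apply(!is.na(vals), c(1, 2), sum)
  value <- apply(vals, c(1, 2), function(z)
    if (all(is.na(z))) NA_real_ else mean(z, na.rm = TRUE))
  weight <- apply(wts, c(1, 2), function(z)
    if (all(is.na(z))) NA_real_ else sum(z, na.rm = TRUE))
  out <- ref
  out$value <- value; out$weight <- weight; out$n <- n
  out
}
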