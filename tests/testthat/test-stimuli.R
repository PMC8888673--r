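test_that("wedge apertures rotate 6 degrees per step and close the cycle", {
  g <- fixGrid()
  # closure: a clockwise step k equals the counter-clockwise step (60-k)
  for (k in c(0L, 7L, 30L)) {
    kc <- (60L - k) %% 60L
    expect_identical(wedgeAperture(k, "cw", g), wedgeAperture(kc, "ccw", g))
  }
  # consecutive steps: centroid polar angle advances by 360/60 = 6 degrees
  a1 <- maskCentroid(wedgeAperture(10, "cw", g), g)
  a2 <- maskCentroid(wedgeAperture(11, "cw", g), g)
  ang <- function(p) atan2(p$y, p$x) * 180 / pi
  expect_equal(((ang(a1) - ang(a2)) + 360) %% 360, 6, tolerance = 0.05)
  expect_error(wedgeAperture(60, "cw", g), "stepIndex")
  expect_error(wedgeAperture(-1, "cw", g), "stepIndex")
})

test_that("wedge area matches the 12/360 disc fraction and tiles the disc", {
  g <- fixGrid()
  xy <- prfRecon:::.gridXY(g)
  discPx <- sum(xy$x^2 + xy$y^2 <= 8.5^2)  # rasterised full-disc oracle
  w <- wedgeAperture(23, "cw", g)
  expect_lt(abs(sum(w) / ((12 / 360) * discPx) - 1), 0.05)
  # 50% overlap: every interior location is covered by >= 1 wedge per cycle
  cover <- Reduce(`+`, lapply(seq(0, 59, by = 1), wedgeAperture,
                              direction = "cw", grid = g))
  interior <- xy$x^2 + xy$y^2 <= 8^2 & xy$x^2 + xy$y^2 >= 0.5^2
  expect_true(all(cover[interior] >= 1))
})

test_that("ring apertures keep the annulus proportional and log-spaced", {
  g <- fixGrid()
  xy <- prfRecon:::.gridXY(g)
  ecc <- sqrt(xy$x^2 + xy$y^2)
  outerPrev <- 0
  for (k in c(0L, 5L, 17L, 35L)) {
    m <- ringAperture(k, "expand", g)
    inR <- min(ecc[m > 0]); outR <- max(ecc[m > 0])
    expect_gte(2 * inR, 0.48 - degPerPix(g))       # inner diameter floor
    # inner/outer ratio within the 56-58% band (one pixel of slack)
    expect_gt(inR / outR, 0.56 - 2 * degPerPix(g) / (2 * outR))
    expect_lt(inR / outR, 0.58 + 2 * degPerPix(g) / (2 * outR))
    expect_gt(outR, outerPrev)                      # expanding: increasing
    outerPrev <- outR
  }
  expect_lte(max(ecc[ringAperture(35, "expand", g) > 0]), 8.5)
  expect_error(ringAperture(36, "expand", g), "stepIndex")
  # exact parameterisation: inner = 0.57 * outer, never below 0.48 deg,
  # outer diameters strictly log-spaced up to 17 deg
  outer <- prfRecon:::.ringOuterDiams()
  expect_length(outer, 36L)
  expect_equal(max(outer), 17)
  expect_true(all(pmax(0.48, 0.57 * outer) >= 0.48))
  expect_true(all(0.57 * outer / outer >= 0.56 & 0.57 * outer / outer <= 0.58))
  expect_equal(sd(diff(log(outer))), 0, tolerance = 1e-12)
})

test_that("two-dot displays place targets and fins by the stated geometry", {
  g <- fixGrid()
  out <- muellerLyerMasks("outward", g)
  # right target centred at (4, 0): rasterised-centroid oracle
  right <- out$target
  right[, pixelCoords(g)$x < 0] <- 0
  cen <- maskCentroid(right, g)
  expect_lt(abs(cen$x - 4), degPerPix(g))
  expect_lt(abs(cen$y - 0), degPerPix(g))
  # outward first fin dot at (4 + 1.36 cos45, 1.36 sin45) = (4.962, 0.962)
  pc <- pixelCoords(g)
  quad <- out$context
  quad[pc$y < 0, ] <- 0; quad[, pc$x < 4.5] <- 0
  quad[, pc$x > 5.6] <- 0                            # isolate the first dot
  cenF <- maskCentroid(quad, g)
  expect_lt(abs(cenF$x - 4.962), degPerPix(g))
  expect_lt(abs(cenF$y - 0.962), degPerPix(g))
  # masks disjoint; eight context dots worth of pixels
  expect_true(all(out$target * out$context == 0))
  expect_identical(sum(muellerLyerMasks("none", g)$context), 0)
  # inward is the mirror of outward about the vertical through each target:
  # equivalently, reflecting the whole context about x = 0 swaps nothing
  # (both are left-right symmetric), but reflecting fin offsets does
  inw <- muellerLyerMasks("inward", g)
  cenI <- maskCentroid({m <- inw$context; m[pc$y < 0, ] <- 0
                        m[, pc$x < 2.4] <- 0; m[, pc$x > 3.5] <- 0; m}, g)
  expect_lt(abs(cenI$x - (4 - 0.962)), degPerPix(g))
  expect_error(muellerLyerMasks("outward", g, targetEccDeg = 8.8),
               "extent")
})

test_that("drifting-patch movies travel 7.2 deg with zero-mean carriers", {
  g <- fixGrid()
  ill <- curveballFrames("illusory", nFrames = 20L, grid = g)
  ctl <- curveballFrames("control", nFrames = 20L, grid = g)
  # envelope centroid (upper-right patch) displaces by 7.2 deg vertically
  pc <- pixelCoords(g)
  quadrant <- function(fr) { fr[pc$y < 0, ] <- 0; fr[, pc$x < 0] <- 0; fr }
  env1 <- quadrant(abs(frames(ill)[, , 1] - 0.5))
  env2 <- quadrant(abs(frames(ill)[, , 20] - 0.5))
  y1 <- maskCentroid(env1, g)$y
  y2 <- maskCentroid(env2, g)$y
  expect_equal(y1 - y2, 7.2, tolerance = 0.1)
  # frames average to the 0.5 background
  expect_lt(max(abs(apply(frames(ill), 3, mean) - 0.5)), 0.01)
  # identical envelope trajectories in the two conditions
  for (f in c(1L, 10L, 20L)) {
    ei <- maskCentroid(abs(quadrant(frames(ill)[, , f]) - 0.5) *
                         (quadrant(frames(ill)[, , f]) > 0), g)
    ec <- maskCentroid(abs(quadrant(frames(ctl)[, , f]) - 0.5) *
                         (quadrant(frames(ctl)[, , f]) > 0), g)
    expect_lt(abs(ei$x - ec$x), 0.15)
    expect_lt(abs(ei$y - ec$y), 0.15)
  }
  expect_error(curveballFrames("illusory", nFrames = 1L), "nFrames")
})

test_that("rectify-average maps the background to 0 and extremes to 1", {
  g <- FieldGrid(20L, 20L, 2)
  half <- array(0.5, c(20, 20, 3))
  expect_true(all(rectifyAverage(ApertureStack(half, 1, g)) == 0))
  blink <- array(0, c(20, 20, 2)); blink[, , 2] <- 1
  expect_true(all(rectifyAverage(ApertureStack(blink, 1, g)) == 1))
  # trajectory mask: column of maximal mass at |x| = 4 deg within one pixel
  gg <- fixGrid()
  m <- rectifyAverage(curveballFrames("illusory", nFrames = 150L,
                                      grid = gg))
  xs <- pixelCoords(gg)$x
  right <- m[, xs > 0]
  peakX <- xs[xs > 0][which.max(colSums(right))]
  expect_lt(abs(peakX - 4), degPerPix(gg) + 1e-9)
})

test_that("simulated mask banks follow the stated parameter axes", {
  g <- fixGrid()
  ml <- simulatedMaskBank("mueller_lyer", g)
  expect_length(ml$masks, 130L)
  expect_equal(unique(round(diff(ml$axis), 10)), 0.128)
  # every mask is left-right mirror symmetric
  for (k in c(1L, 65L, 130L))
    expect_identical(ml$masks[[k]], ml$masks[[k]][, ncol(ml$masks[[k]]):1])
  cb <- simulatedMaskBank("curveball", g, nFrames = 25L)
  expect_length(cb$masks, 81L)
  expect_equal(range(cb$axis), c(-40, 40))
  expect_true(all(vapply(cb$masks, function(m) all(m >= 0 & m <= 1),
                         logical(1))))
})

test_that("aperture stacks round-trip bit-exactly through the container", {
  g <- FieldGrid(16L, 16L, 2)
  set.seed(5)
  fr <- array(runif(16 * 16 * 4), c(16, 16, 4))
  st <- ApertureStack(fr, frameDurationS = 0.25, grid = g)
  path <- tempfile(fileext = ".txt")
  writeApertureStack(st, path)
  st2 <- readApertureStack(path)
  expect_identical(frames(st2), frames(st))
  expect_identical(frameDuration(st2), frameDuration(st))
  expect_identical(fieldGrid(st2)@extentDeg, g@extentDeg)
  unlink(path)
})

test_that("degree/pixel conversion is exact and invertible at pixel centres", {
  g <- fixGrid()
  pc <- pixelCoords(g)
  p <- degToPix(g, pc$x[37], pc$y[81])
  expect_equal(p$col, 37)
  expect_equal(p$row, 81)
  d <- pixToDeg(g, 37, 81)
  expect_equal(d$x, pc$x[37])
  expect_equal(d$y, pc$y[81])
})
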