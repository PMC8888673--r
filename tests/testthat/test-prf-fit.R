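test_that("pRF profiles are unit-sum Gaussians peaking at the centre", {
  g <- fixGrid()
  w <- prfProfile(2.3, -1.1, 0.8, g)
  expect_equal(sum(w), 1, tolerance = 1e-9)
  peak <- which(w == max(w), arr.ind = TRUE)
  d <- pixToDeg(g, peak[2], peak[1])
  expect_lt(abs(d$x - 2.3), degPerPix(g))
  expect_lt(abs(d$y + 1.1), degPerPix(g))
  # completeness: overlap with a full-field mask is 1
  expect_equal(sum(w * 1), 1, tolerance = 1e-9)
  expect_error(prfProfile(0, 0, 0, g), "sigma")
})

test_that("predicted series follow the boxcar-convolution oracle", {
  g <- fixGrid(); hrf <- fixHRF()
  # constant full-field stimulus: series proportional to boxcar (*) HRF
  D <- 12L; total <- 40L
  fr <- array(0, c(g@heightPx, g@widthPx, total))
  fr[, , seq_len(D)] <- 1
  st <- ApertureStack(fr, 1, g)
  pred <- predictTimeseries(0.5, 0.5, 1, st, hrf)
  box <- c(rep(1, D), rep(0, total - D))
  oracle <- vapply(seq_len(total), function(t)         # direct convolution
    sum(hrf[seq_len(min(t, length(hrf)))] *
          box[t - seq_len(min(t, length(hrf))) + 1]), numeric(1))
  expect_gt(cor(pred, oracle), 1 - 1e-12)
  expect_equal(pred / max(pred), oracle / max(oracle), tolerance = 1e-9)
  # time invariance: shifting the stimulus shifts the output
  fr2 <- array(0, c(g@heightPx, g@widthPx, total))
  fr2[, , 5L + seq_len(D)] <- 1
  pred2 <- predictTimeseries(0.5, 0.5, 1, ApertureStack(fr2, 1, g), hrf)
  expect_equal(pred2[(5 + 1):total], pred[1:(total - 5)], tolerance = 1e-9)
  # zero overlap at every frame: all-zero series
  none <- ApertureStack(array(0, c(g@heightPx, g@widthPx, 8L)), 1, g)
  expect_true(all(predictTimeseries(0, 0, 1, none, hrf) == 0))
})

test_that("the coarse grid has the stated structure", {
  sg <- searchGrid()
  expect_equal(nrow(sg$params), 15 * 15 * 34)
  expect_equal(range(sg$x), c(-8.925, 8.925))
  expect_equal(range(sg$sigma), c(0.18, 17), tolerance = 1e-12)
  expect_equal(sd(diff(log(sg$sigma))), 0, tolerance = 1e-12)
  # x-major scan order: x constant over inner blocks
  expect_equal(sg$params[1:34, "x"], rep(sg$x[1], 34))
})

test_that("coarse fit recovers grid points exactly and rejects noise", {
  ap <- fixMapApertures(); hrf <- fixHRF()
  preds <- coarsePredictions(ap, hrf, 1)
  sg <- searchGrid()
  idx <- c(2000L, 4303L, 7000L)
  cf <- coarseFit(preds$pred[idx, ], preds)
  expect_equal(cf$x, unname(preds$params[idx, "x"]))
  expect_equal(cf$y, unname(preds$params[idx, "y"]))
  expect_equal(cf$sigma, unname(preds$params[idx, "sigma"]))
  # affine invariance of the correlation objective
  cf2 <- coarseFit(3 * preds$pred[idx, ] + 7, preds)
  expect_equal(cf2[, c("x", "y", "sigma")], cf[, c("x", "y", "sigma")])
  # constant series: not-fit marker
  cf3 <- coarseFit(rep(1, ncol(preds$pred)), preds)
  expect_false(cf3$fit)
  expect_true(is.na(cf3$x))
  # seeded pure-noise series stay below the goodness-of-fit gate >= 95/100
  set.seed(12)
  noise <- matrix(rnorm(100 * ncol(preds$pred)), 100)
  expect_gte(mean(!coarseFit(noise, preds)$fit), 0.95)
})

test_that("fine fit recovers off-grid truth and never worsens the seed", {
  ap <- fixMapApertures(); hrf <- fixHRF()
  truth <- c(x = 2.1, y = -0.7, sigma = 0.55)
  obs <- 3 * predictTimeseries(truth[1], truth[2], truth[3], ap, hrf) + 0.4
  preds <- coarsePredictions(ap, hrf, 1)
  cf <- coarseFit(obs, preds)
  maskEnv <- prfRecon:::.maskMatrixTR(ap, 1)
  ff <- fineFit(obs, c(cf$x, cf$y, cf$sigma), maskEnv = maskEnv, hrf = hrf)
  expect_lt(abs(ff$x - truth[1]), 0.05)
  expect_lt(abs(ff$y - truth[2]), 0.05)
  expect_lt(abs(ff$sigma / truth[3] - 1), 0.10)
  expect_gte(ff$r2, 0.999)
  # SSE never worse than the coarse seed
  seedSSE <- prfRecon:::.cppPrfSSE(maskEnv$Mt, maskEnv$xs, maskEnv$ys,
                                   cf$x, cf$y, cf$sigma, hrf, obs)
  expect_lte(ff$sse, seedSSE + 1e-9)
  # a constant offset is absorbed by the intercept
  ff2 <- fineFit(obs + 5, c(cf$x, cf$y, cf$sigma), maskEnv = maskEnv,
                 hrf = hrf)
  expect_equal(c(ff2$x, ff2$y, ff2$sigma), c(ff$x, ff$y, ff$sigma),
               tolerance = 1e-4)
  expect_equal(ff2$intercept - ff$intercept, 5, tolerance = 1e-3)
})

test_that("whole-observer fitting meets the recovery tolerances", {
  ens <- fixFittedEnsemble()
  tr <- truthPRF(ens); ft <- fittedPRF(ens)
  expect_lt(median(abs(ft$x - tr$x), na.rm = TRUE), 0.05)
  expect_lt(median(abs(ft$y - tr$y), na.rm = TRUE), 0.05)
  expect_lt(median(abs(ft$sigma - tr$sigma) / tr$sigma, na.rm = TRUE), 0.1)
  expect_gt(mean(ft$converged), 0.95)
})
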