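test_that("two-dot adjustment scoring sums binary-log size ratios", {
  # independent arithmetic oracle on representative adjusted means
  trials <- data.frame(condition = c("outward", "inward", "none"),
                       reference = 3.99,
                       adjusted = c(4.18, 3.77, 3.99))
  eff <- mlEffect(trials)
  oracle <- log2(4.18 / 3.99) - log2(3.77 / 3.99)
  expect_equal(eff$total, oracle, tolerance = 1e-12)
  expect_lt(abs(eff$total - 0.1492), 5e-4)
  expect_equal(unname(eff$perContext["none"]), 0, tolerance = 1e-12)
  # antisymmetry: swapping adjusted and reference negates the effect
  swapped <- transform(trials, reference = adjusted, adjusted = reference)
  expect_equal(mlEffect(swapped)$total, -eff$total, tolerance = 1e-12)
  # ratio-scale invariance
  doubled <- transform(trials, reference = 2 * reference,
                       adjusted = 2 * adjusted)
  expect_equal(mlEffect(doubled)$total, eff$total, tolerance = 1e-12)
  expect_error(mlEffect(trials[trials$condition != "inward", ]),
               "inward")
})

test_that("illusion percentage follows the outward/inward ratio", {
  expect_equal(mlIllusionPercent(4.18, 3.77), 10.876, tolerance = 1e-3)
  expect_equal(mlIllusionPercent(2, 2), 0)
  expect_equal(mlIllusionPercent(4, 2), 100)
  expect_error(mlIllusionPercent(-1, 2), "positive")
})

test_that("moving-stimulus effect subtracts illusory from control means", {
  trials <- data.frame(condition = rep(c("control", "illusory"), each = 2),
                       adjusted = c(4.0, 4.0, 4.6, 4.6))
  expect_equal(cbEffect(trials), -0.6)
  swapped <- transform(trials,
                       condition = ifelse(condition == "control",
                                          "illusory", "control"))
  expect_equal(cbEffect(swapped), 0.6)
  same <- data.frame(condition = c("control", "illusory"), adjusted = 4)
  expect_equal(cbEffect(same), 0)
  expect_error(cbEffect(same[1, ]), "illusory")
})

test_that("a known perceptual gain is recovered from jittered trials", {
  gain <- 1.08
  tr <- simulateAdjustmentTrials("mueller_lyer", nPerCondition = 500L,
                                 gain = c(outward = gain, inward = 1 / gain,
                                          none = 1), jitterSdLog2 = 0.1,
                                 seed = 77L)
  eff <- mlEffect(tr)
  expect_lt(abs(eff$perContext[["outward"]] - log2(gain)), 0.01)
  expect_lt(abs(eff$total - 2 * log2(gain)), 0.02)
})

test_that("local-median detrending removes drift but resists spikes", {
  # constant gaze detrends to zero
  gz <- data.frame(time = seq(0, 30, by = 1 / 60), x = 0.3, y = -0.2)
  d0 <- detrendGaze(gz)
  expect_true(all(abs(d0$x) < 1e-12) && all(abs(d0$y) < 1e-12))
  # slow linear drift: interior residual mean below 0.01 deg
  t <- seq(0, 60, by = 1 / 60)
  gz2 <- data.frame(time = t, x = 0.01 * t, y = 0)
  d2 <- detrendGaze(gz2)
  interior <- t > 5 & t < 55
  expect_lt(mean(abs(d2$x[interior])), 0.01)
  # a 0.5 s blink spike leaves interior medians untouched
  gz3 <- gz2
  spike <- t >= 30 & t < 30.5
  gz3$x[spike] <- gz3$x[spike] + 10
  d3 <- detrendGaze(gz3)
  away <- t > 5 & t < 55 & !(t >= 24.5 & t <= 36)
  expect_equal(d3$x[away], d2$x[away], tolerance = 1e-12)
  expect_error(detrendGaze(gz2[t < 8, ]), "shorter")
})

test_that("gaze summaries give max-normalised histograms and raw MAD", {
  g1 <- data.frame(x = rep(0.1, 50), y = rep(-0.3, 50))
  s1 <- gazeSummary(g1)
  expect_equal(sum(s1$histogram == 1), 1L)
  expect_equal(dim(s1$histogram), c(1L, 1L))
  expect_equal(s1$madX, 0)
  g2 <- data.frame(x = c(-1, 0, 1), y = c(0, 0, 0))
  expect_equal(gazeSummary(g2)$madX, 1)   # definition of the unscaled MAD
  set.seed(55)
  g3 <- data.frame(x = rnorm(4000, 0, 0.2), y = rnorm(4000, 0, 0.2))
  s3 <- gazeSummary(g3)
  expect_equal(max(s3$histogram), 1)
  expect_equal(s3$madX, median(abs(g3$x - median(g3$x))))
  expect_error(gazeSummary(g3[0, ]), "empty")
})
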