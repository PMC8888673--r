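test_that("observer ensembles are deterministic and follow the size law", {
  spec <- ObserverSpec(nVertices = c(V1 = 400L), seed = 3L)
  e1 <- makeObserver(spec)
  e2 <- makeObserver(spec)
  expect_identical(truthPRF(e1), truthPRF(e2))
  # sigma = 0.1 + 0.1 * ecc: mean sigma near 4 deg eccentricity is ~0.5
  spec2 <- ObserverSpec(nVertices = c(V1 = 4000L), seed = 4L)
  tr <- truthPRF(makeObserver(spec2))
  ecc <- sqrt(tr$x^2 + tr$y^2)
  mid <- ecc >= 3.5 & ecc <= 4.5
  expect_lt(abs(mean(tr$sigma[mid]) / 0.5 - 1), 0.1)
  expect_true(all(tr$sigma > 0))
})

test_that("quarter-field maps avoid the horizontal meridian band", {
  spec <- ObserverSpec(nVertices = c(V1 = 200L, V2 = 200L, V3 = 200L),
                       meridianGapDeg = 20, seed = 5L)
  tr <- truthPRF(makeObserver(spec))
  polar <- abs(atan2(tr$y, abs(tr$x))) * 180 / pi  # angle from meridian
  expect_true(all(polar[tr$region != "V1"] >= 10))
  expect_lt(min(polar[tr$region == "V1"]), 10)
  # gap 0 restores meridian coverage in V2
  spec0 <- ObserverSpec(nVertices = c(V1 = 200L, V2 = 200L),
                        meridianGapDeg = 0, seed = 5L)
  tr0 <- truthPRF(makeObserver(spec0))
  p0 <- abs(atan2(tr0$y, abs(tr0$x))) * 180 / pi
  expect_lt(min(p0[tr0$region == "V2"]), 10)
  expect_error(ObserverSpec(nVertices = c(V1 = -1L)), "non-negative")
  expect_error(ObserverSpec(nVertices = c(V1 = 0L, V2 = 0L, V3 = 0L)),
               "positive total")
})

test_that("mapping runs are z-scored, scale-invariant and silent off-screen", {
  # small bespoke ensemble: one vertex far outside the apertures
  spec <- ObserverSpec(nVertices = c(V1 = 10L), noiseSd = 0, seed = 6L)
  ens <- makeObserver(spec)
  ens@truth$x[1] <- 12; ens@truth$y[1] <- 12   # beyond the 8.5 deg apertures
  bold <- simulateMappingRun(ens, fixMapApertures(), fixHRF())
  Y <- boldData(bold)
  expect_true(all(abs(Y[1, ]) < 1e-10))        # constant -> zero after guard
  driven <- rowSums(abs(Y)) > 0
  expect_lt(max(abs(rowMeans(Y[driven, ]))), 1e-6)
  expect_lt(max(abs(apply(Y[driven, ], 1, sd) - 1)), 1e-6)
  # doubling beta leaves the z-scored series untouched
  ens2 <- ens; ens2@truth$beta <- 2 * ens@truth$beta
  bold2 <- simulateMappingRun(ens2, fixMapApertures(), fixHRF())
  expect_equal(boldData(bold2), Y, tolerance = 1e-12)
})

test_that("experiment runs reproduce the block protocols", {
  spec <- ObserverSpec(nVertices = c(V1 = 20L), noiseSd = 0, seed = 8L)
  ens <- makeObserver(spec)
  ml <- simulateExperimentRun(ens, "mueller_lyer", deltaShiftDeg = 0,
                              nRuns = 2L)
  ev1 <- ml$events[ml$events$run == 1 & ml$events$period == "background", ]
  expect_equal(nrow(ev1), 8L)                    # eight blocks per run
  expect_equal(sort(unique(diff(sort(ev1$onset_s)))), 32)  # 32 s period
  expect_equal(sum(ev1$condition == "outward"), 4L)
  expect_equal(ncol(boldData(ml$bold)), 2L * 256L)
  cb <- simulateExperimentRun(ens, "curveball", deltaShiftDeg = 0,
                              nRuns = 1L)
  expect_equal(ncol(boldData(cb$bold)), 291L)    # 15 + 6 x 46 retained
  expect_equal(nrow(cb$events), 12L)             # 2 stimulus blocks x 6
  expect_setequal(unique(cb$events$condition), c("illusory", "control"))
  # determinism under the seed
  cb2 <- simulateExperimentRun(ens, "curveball", deltaShiftDeg = 0,
                               nRuns = 1L)
  expect_identical(boldData(cb2$bold), boldData(cb$bold))
})

test_that("a zero shift makes the two conditions generatively identical", {
  spec <- ObserverSpec(nVertices = c(V1 = 60L), noiseSd = 0, seed = 9L)
  ens <- makeObserver(spec)
  sim <- simulateExperimentRun(ens, "mueller_lyer", deltaShiftDeg = 0,
                               nRuns = 4L)
  design <- buildDesign(sim$events, runVolumes("mueller_lyer"), 1, fixHRF())
  co <- fitAndContrast(sim$bold, design,
                       c(outward_target = 1, outward_background = -1))
  ci <- fitAndContrast(sim$bold, design,
                       c(inward_target = 1, inward_background = -1))
  expect_equal(co$contrast, ci$contrast, tolerance = 1e-9)
})

test_that("simulated gaze and adjustment records have the stated structure", {
  gz <- simulateGaze(durationS = 30, rateHz = 60, seed = 2L)
  expect_true(all(diff(gz$time) > 0))
  expect_equal(1 / median(diff(gz$time)), 60, tolerance = 1e-6)
  tr <- simulateAdjustmentTrials("mueller_lyer", nPerCondition = 5L,
                                 seed = 2L)
  expect_setequal(unique(tr$condition), c("outward", "inward", "none"))
  expect_true(all(tr$adjusted > 0))
  expect_identical(tr, simulateAdjustmentTrials("mueller_lyer",
                                                nPerCondition = 5L,
                                                seed = 2L))
})
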