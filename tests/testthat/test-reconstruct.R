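test_that("hemifield and quadrant collapse fold coordinates idempotently", {
  v <- data.frame(x = c(-4, 3, 0), y = c(0, -6.2, 2))
  h <- collapseField(v, "hemifields")
  expect_equal(h$x, c(4, 3, 0))
  expect_equal(h$y, v$y)
  q <- collapseField(v, "quadrants")
  expect_equal(q$x, c(4, 3, 0))
  expect_equal(q$y, c(0, 6.2, 2))
  expect_identical(collapseField(q, "quadrants"), q)
})

test_that("sliding windows are half-open and honour the size criteria", {
  v <- data.frame(x = 4.0, y = 0, sigma = 0.3, r2 = 1, response = 1)
  prof <- slidingSample(v, WindowSpec())
  hit <- prof$centre[!prof$missing]
  expect_equal(range(hit), c(3.6, 4.5))   # centres in (3.5, 4.5]
  expect_true(all(prof$response[!prof$missing] == 1))
  # stringent: |y| + sigma < height/2
  vs <- data.frame(x = c(4, 4), y = c(0.2, 0.1), sigma = c(0.4, 0.3),
                   r2 = 1, response = 1)
  ps <- slidingSample(vs, WindowSpec(sizeCriterion = "stringent"))
  expect_equal(max(ps$n), 1L)             # (0.2, 0.4) excluded: 0.6 >= 0.5
  # lenient boundary at sigma = 1 (strictly greater is excluded)
  vl <- data.frame(x = 4, y = 0, sigma = c(1.01, 1.0, 0.99), r2 = 1,
                   response = 1)
  pl <- slidingSample(vl, WindowSpec(sizeCriterion = "lenient"))
  expect_equal(max(pl$n), 2L)
  # global gates: eccentricity and pRF goodness of fit
  vg <- data.frame(x = c(4, 8.6, 4), y = 0, sigma = 0.5,
                   r2 = c(1, 1, 0.05), response = 1)
  pg <- slidingSample(vg, WindowSpec())
  expect_equal(max(pg$n), 1L)
})

test_that("window sets nest across criteria and ignore vertex order", {
  set.seed(31)
  v <- data.frame(x = runif(400, -7, 7), y = runif(400, -1, 1),
                  sigma = runif(400, 0.2, 1.4), r2 = 1,
                  response = rnorm(400))
  pn <- slidingSample(v, WindowSpec())
  pl <- slidingSample(v, WindowSpec(sizeCriterion = "lenient"))
  ps <- slidingSample(v, WindowSpec(sizeCriterion = "stringent"))
  expect_true(all(ps$n <= pl$n))
  expect_true(all(pl$n <= pn$n))
  perm <- slidingSample(v[sample(400), ], WindowSpec())
  expect_equal(perm$response, pn$response)
})

test_that("1-D Gaussian profile fits recover noiseless parameters", {
  cc <- seq(1.5, 6.5, by = 0.1)
  p0 <- c(alpha = 0, beta = 1, mu = 4.49, sigma = 0.8)
  y <- p0["alpha"] + p0["beta"] * exp(-(cc - p0["mu"])^2 /
                                        (2 * p0["sigma"]^2))
  prof <- data.frame(centre = cc, response = y)
  f <- fitProfile(prof)
  expect_equal(c(f$alpha, f$beta, f$mu, f$sigma), unname(p0),
               tolerance = 1e-3)
  expect_gt(f$r2, 0.999999)
  # adding a constant only moves the baseline
  f2 <- fitProfile(transform(prof, response = response + 3))
  expect_equal(f2$alpha - f$alpha, 3, tolerance = 1e-3)
  expect_equal(c(f2$beta, f2$mu, f2$sigma), c(f$beta, f$mu, f$sigma),
               tolerance = 1e-3)
  # too few points: failure marker, not an error
  short <- data.frame(centre = cc[1:4], response = y[1:4])
  expect_false(fitProfile(short)$ok)
})

test_that("participant exclusion rules apply the SD and dissimilarity gates", {
  fits <- data.frame(participant = c(1, 2, 3, 4),
                     condition = "a", location = "all",
                     r2 = c(0.9, 0.9, 0.9, 0.2))
  res <- exclusionRules(fits)
  expect_false(res$keep[res$participant == 4])   # 0.2 < mean - 2.5 SD
  expect_true(all(res$keep[res$participant != 4]))
  # between-condition dissimilarity above 0.3
  fits2 <- data.frame(participant = rep(1:3, each = 2),
                      condition = rep(c("a", "b"), 3), location = "all",
                      r2 = c(0.95, 0.60, 0.9, 0.88, 0.91, 0.9))
  res2 <- exclusionRules(fits2)
  expect_false(res2$keep[res2$participant == 1])  # |0.95 - 0.60| > 0.3
  expect_true(all(res2$keep[res2$participant != 1]))
  # identical quality: nobody dropped
  fits3 <- data.frame(participant = 1:4, condition = "a", r2 = 0.8)
  expect_true(all(exclusionRules(fits3)$keep))
  expect_error(exclusionRules(fits3[1:2, ]), ">= 3 participants")
  # empty windows are a recorded drop reason
  fits4 <- data.frame(participant = 1:3, condition = "a", r2 = 0.8,
                      anyEmpty = c(FALSE, TRUE, FALSE))
  res4 <- exclusionRules(fits4)
  expect_equal(res4$reason[res4$participant == 2], "empty_window")
})
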