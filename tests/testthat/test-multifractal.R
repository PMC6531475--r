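test_that("the multiscale measure matches brute-force convolution", {
  set.seed(21)
  x <- matrix(runif(16 * 16), 16, 16)
  cfg <- measureConfig(scales = c(1, 2), gammas = c(1, 3),
                       densityMode = "intensity")
  stack <- waveletMeasure(x, cfg)
  for (s in 1:2) {
    expected <- matrix(0, 16, 16)
    for (g in c(1, 3)) {
      k <- MFdenoise:::psiKernel(c(1, 2)[s], g, 3)
      expected <- expected + bruteConvolveMirror(x, k)
    }
    expected <- pmax(expected / 2, 1e-12)
    expect_lt(max(abs(measureValues(stack)[, , s] - expected)), 1e-10)
  }
})

test_that("a central impulse reproduces the kernels' central weight", {
  x <- matrix(0, 33, 33)
  x[17, 17] <- 1
  cfg <- measureConfig(scales = c(1, 2, 3), densityMode = "intensity")
  stack <- waveletMeasure(x, cfg)
  # Psi(0) = 1 for every gamma, so the gamma-average at the impulse is 1
  for (s in 1:3) expect_equal(measureValues(stack)[17, 17, s], 1)
})

test_that("a constant image has zero gradient density at the floor", {
  stack <- waveletMeasure(matrix(0.7, 40, 40),
                          measureConfig(scales = 1:3))
  expect_true(all(measureValues(stack) == 1e-12))
})

test_that("noiseless power-law stacks are recovered to machine precision", {
  scales <- 1:5
  vals <- array(rep(2.5 * scales^1.3, each = 64), c(8, 8, 5))
  em <- estimateExponents(new("ScaleStack", values = vals, scales = scales))
  expect_lt(max(abs(exponentValues(em) - 1.3)), 1e-10)
  expect_lt(max(abs(exponentIntercepts(em) - log(2.5))), 1e-10)
  expect_true(all(exponentFitR2(em) >= 1 - 1e-12))

  flat <- estimateExponents(new("ScaleStack",
                                values = array(3, c(4, 4, 5)),
                                scales = scales))
  expect_lt(max(abs(exponentValues(flat))), 1e-12)
})

test_that("jittered power-law slopes are recovered with small bias", {
  set.seed(77)
  scales <- 1:5
  npix <- 100 * 100
  logmu <- outer(rep(2, npix), log(scales)) +
    matrix(rnorm(npix * 5, sd = 0.2), npix, 5)
  vals <- array(exp(logmu), c(100, 100, 5))
  em <- estimateExponents(new("ScaleStack", values = vals, scales = scales))
  expect_lt(abs(mean(exponentValues(em)) - 2), 0.05)
  expect_true(all(exponentFitR2(em) >= 0 & exponentFitR2(em) <= 1))
})

test_that("non-positive stacks are rejected", {
  vals <- array(1, c(4, 4, 2))
  vals[1, 1, 1] <- 0
  expect_error(new("ScaleStack", values = vals, scales = 1:2), "positive")
})

test_that("level sets select exactly the requested exponent band", {
  em <- new("ExponentMap", d = matrix(rep(c(1, 2, 3), length.out = 36), 6, 6),
            logAlpha = matrix(0, 6, 6), r2 = matrix(1, 6, 6))
  expect_true(all(maskMatrix(levelSet(em, 0, tol = Inf))))
  exact <- levelSet(em, 2, tol = 0)
  expect_identical(maskMatrix(exact), exponentValues(em) == 2)

  set.seed(5)
  d <- matrix(rnorm(400, 2, 0.3), 20, 20)
  emr <- new("ExponentMap", d = d, logAlpha = d * 0, r2 = d * 0 + 1)
  target <- median(d)
  got <- sum(maskMatrix(levelSet(emr, target, tol = 0.1)))
  expect_equal(got, sum(abs(d - target) <= 0.1))
})

test_that("MSM extraction selects the lower-quantile exponents with ties", {
  em <- new("ExponentMap", d = matrix(sample(1:16), 4, 4),
            logAlpha = matrix(0, 4, 4), r2 = matrix(1, 4, 4))
  msm <- extractMSM(em, 0.25)
  expect_equal(sum(maskMatrix(msm)), 4)
  expect_true(all(exponentValues(em)[maskMatrix(msm)] <= 4.75))

  expect_true(all(maskMatrix(extractMSM(em, 1.0))))

  const <- new("ExponentMap", d = matrix(1.5, 4, 4),
               logAlpha = matrix(0, 4, 4), r2 = matrix(1, 4, 4))
  expect_true(all(maskMatrix(extractMSM(const, 0.1))))

  expect_error(extractMSM(em, 0), "quantile")
  expect_error(extractMSM(em, 1.2), "quantile")
})

test_that("MSM masks nest monotonically in the quantile", {
  set.seed(13)
  for (trial in 1:3) {
    d <- matrix(rnorm(900), 30, 30)
    em <- new("ExponentMap", d = d, logAlpha = d * 0, r2 = d * 0 + 1)
    qs <- sort(runif(4, 0.05, 1))
    masks <- lapply(qs, function(q) maskMatrix(extractMSM(em, q)))
    for (i in 1:3)
      expect_false(any(masks[[i]] & !masks[[i + 1]]))
  }
})

test_that("the MSM of a noiseless disk concentrates near the disk edge", {
  img <- diskPhantom(96, radius = 24)
  em <- estimateExponents(waveletMeasure(img))
  msm <- maskMatrix(extractMSM(em, 0.25))

  n <- 96
  y <- matrix(seq_len(n), n, n)
  x <- t(y)
  r <- sqrt((y - n / 2)^2 + (x - n / 2)^2)
  ring <- abs(r - 24) <= 2
  fracMSM <- sum(msm & ring) / sum(msm)
  fracRandom <- sum(ring) / n^2  # expected under a uniform mask
  expect_gt(fracMSM, fracRandom)
})

test_that("the MSM is more stable under noise than a random mask", {
  img <- diskPhantom(96, radius = 24)
  msmClean <- maskMatrix(extractMSM(estimateExponents(waveletMeasure(img)),
                                    0.25))
  noisy <- addMixedPGNoise(img, noiseParams(1e-2, 1e-2, seed = 31))
  msmNoisy <- maskMatrix(extractMSM(estimateExponents(waveletMeasure(noisy)),
                                    0.25))
  jaccard <- sum(msmNoisy & msmClean) / sum(msmNoisy | msmClean)
  # random masks of fraction p overlap with expected Jaccard p / (2 - p)
  p <- mean(msmClean)
  expect_gt(jaccard, p / (2 - p))
})

test_that("undersized images and bad configs are rejected", {
  expect_error(waveletMeasure(matrix(1, 8, 8),
                              measureConfig(scales = c(4, 8))), "support")
  expect_error(measureConfig(scales = 3), "scales")
  expect_error(measureConfig(scales = c(2, 1)), "scales")
  expect_error(measureConfig(gammas = 0.5), "gammas")
})
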