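test_that("zero intensity with zero sigma stays exactly zero", {
  b <- addMixedPGNoise(matrix(0, 32, 32), noiseParams(0.05, 0, seed = 1))
  expect_true(all(b == 0))
})

test_that("empirical moments match the mixed Poisson-Gaussian law", {
  n <- 316L  # ~1e5 pixels
  v <- matrix(0.5, n, n)
  g0 <- 0.1; sigma <- 0.05
  b <- addMixedPGNoise(v, noiseParams(g0, sigma, seed = 4))
  x <- as.vector(b)
  trueVar <- g0 * 0.5 + sigma^2
  seMean <- sd(x) / sqrt(length(x))
  expect_lt(abs(mean(x) - 0.5), 4 * seMean)
  m4 <- mean((x - mean(x))^4)
  seVar <- sqrt(max(m4 - var(x)^2, 0) / length(x))
  expect_lt(abs(var(x) - trueVar), 4 * seVar)
})

test_that("noise draws are deterministic in the seed and unclipped", {
  v <- matrix(0.2, 64, 64)
  p <- noiseParams(0.01, 0.2, seed = 9)
  b1 <- addMixedPGNoise(v, p)
  b2 <- addMixedPGNoise(v, p)
  expect_identical(b1, b2)
  expect_true(any(b1 < 0))  # Gaussian tail must not be clipped
  b3 <- addMixedPGNoise(v, noiseParams(0.01, 0.2, seed = 10))
  expect_false(identical(b1, b3))
})

test_that("invalid inputs are rejected", {
  expect_error(addMixedPGNoise(matrix(-0.1, 4, 4), noiseParams(0.1, 0.1)),
               "non-negative")
  expect_error(noiseParams(0, 0.1), "g0")
  expect_error(noiseParams(0.1, -1), "sigma")
})

test_that("the five-level schedule is the half-decade grid, low to high", {
  sched <- noiseLevelSchedule()
  expect_length(sched, 5L)
  g0s <- vapply(sched, function(p) p@g0, numeric(1))
  sigmas <- vapply(sched, function(p) p@sigma, numeric(1))
  expect_equal(g0s, 10^seq(-3, -1, 0.5))
  expect_equal(sigmas, g0s)
  expect_equal(g0s[1], 1e-3)
  expect_equal(g0s[5], 1e-1)
  expect_true(all(diff(g0s) > 0))
})

test_that("PSNR degrades monotonically from the low- to high-noise setting", {
  ph <- smallPhantom(seed = 3)
  v <- getChannel(phantomImage(ph), 1)
  bLow <- addMixedPGNoise(v, noiseParams(1e-3, 1e-3, seed = 5))
  bHigh <- addMixedPGNoise(v, noiseParams(1e-1, 1e-1, seed = 5))
  expect_gt(imagePSNR(v, bLow), imagePSNR(v, bHigh))
})

test_that("multichannel corruption uses independent per-channel substreams", {
  ph <- smallPhantom(seed = 3)
  img <- phantomImage(ph)
  noisy <- addMixedPGNoise(img, noiseParams(0.01, 0.01, seed = 8))
  expect_identical(channelNames(noisy), channelNames(img))
  # channel c reproduces the matrix method seeded at seed + c - 1
  for (c in 1:3) {
    direct <- addMixedPGNoise(getChannel(img, c),
                              noiseParams(0.01, 0.01, seed = 8L + c - 1L))
    expect_identical(getChannel(noisy, c), direct)
  }
})

test_that("empirical MSE grows with the gain on a fixed constant image", {
  v <- matrix(0.5, 128, 128)
  mses <- vapply(c(1e-3, 1e-2, 1e-1), function(g0)
    imageMSE(v, addMixedPGNoise(v, noiseParams(g0, 0, seed = 2))),
    numeric(1))
  expect_true(all(diff(mses) > 0))
})
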