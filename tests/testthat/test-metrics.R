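test_that("MSE matches its definition", {
  expect_equal(imageMSE(matrix(c(0, 2), 1), matrix(c(1, 1), 1)), 1.0)
  v <- matrix(runif(64), 8, 8)
  expect_equal(imageMSE(v, v), 0)

  set.seed(14)
  vhat <- matrix(runif(64), 8, 8)
  acc <- 0
  for (i in 1:8) for (j in 1:8) acc <- acc + (v[i, j] - vhat[i, j])^2
  expect_lt(abs(imageMSE(v, vhat) - acc / 64), 1e-12)
  expect_error(imageMSE(v, matrix(1, 4, 4)), "shape")
})

test_that("PSNR follows the peak-over-root-MSE formula", {
  # max(v) = 1, MSE = 0.01 -> 20 dB
  v <- matrix(c(1, 1), 1)
  vhat <- matrix(c(1 - 0.1 * sqrt(2), 1), 1)
  expect_equal(imagePSNR(v, vhat), 20, tolerance = 1e-12)

  # max(v) = 255, MSE = 1 -> 20 log10(255) ~ 48.13 dB
  v255 <- matrix(c(255, 255), 1)
  vhat255 <- matrix(c(255 - sqrt(2), 255), 1)
  expect_equal(imagePSNR(v255, vhat255), 20 * log10(255), tolerance = 1e-9)
  expect_equal(20 * log10(255), 48.1308, tolerance = 1e-4)

  # halving the MSE at fixed peak adds exactly 10 log10(2) dB
  set.seed(15)
  v <- matrix(runif(100, 0.5, 1), 10, 10)
  e <- matrix(rnorm(100, sd = 0.05), 10, 10)
  p1 <- imagePSNR(v, v + e)
  p2 <- imagePSNR(v, v + e / sqrt(2))
  expect_equal(p2 - p1, 10 * log10(2), tolerance = 1e-10)

  expect_identical(imagePSNR(v, v), Inf)
  expect_error(imagePSNR(matrix(0, 2, 2), matrix(1, 2, 2)), "peak")
})

test_that("PSNR and MSE are mutually consistent", {
  set.seed(16)
  v <- matrix(runif(256), 16, 16)
  vhat <- v + matrix(rnorm(256, sd = 0.1), 16, 16)
  expect_lt(abs(imagePSNR(v, vhat) -
                20 * log10(max(v) / sqrt(imageMSE(v, vhat)))), 1e-12)
})

test_that("residual PSD localizes a pure tone and obeys Parseval", {
  n <- 64
  v <- matrix(0, n, n)
  kx <- 8  # cycles across the image -> frequency kx/n cycles/pixel
  tone <- cos(2 * pi * kx * (col(v) - 1) / n)
  curve <- residualPSD(v, -tone, nBins = 16)
  expect_true(all(curve$psd >= 0))
  # FFT roundoff leaves ~1e-26 in other bins; energetic = within 1e-10 of peak
  inBin <- which(curve$psd > max(curve$psd) * 1e-10)
  expect_length(inBin, 1L)
  f <- kx / n
  # the only energetic bin must be the one holding the tone frequency:
  # its geometric centre lies within half a (log-spaced) bin of f
  halfBinWidth <- diff(log(range(curve$freq))) / (2 * 15)
  expect_lt(abs(log(curve$freq[inBin]) - log(f)), halfBinWidth * 2.01)

  # zero residual -> identically zero curve
  expect_true(all(residualPSD(tone, tone, 8)$psd == 0))

  # Parseval: total spectral energy = npixels * sum(dv^2)
  set.seed(17)
  a <- matrix(runif(n * n), n, n)
  b <- matrix(runif(n * n), n, n)
  dv <- a - b
  total <- sum(Mod(stats::fft(dv))^2)
  expect_lt(abs(total - n * n * sum(dv^2)) / total, 1e-10)
  curve <- residualPSD(a, b, 16)
  binned <- sum(curve$psd * curve$n)
  dc <- Mod(stats::fft(dv))[1, 1]^2
  expect_lt(abs((binned + dc) - total) / total, 1e-10)

  expect_error(residualPSD(a, matrix(0, 2, 2)), "shape")
})

test_that("multichannel quality reports include a channel average", {
  ph <- smallPhantom(seed = 4, size = 64L)
  img <- phantomImage(ph)
  noisy <- addMixedPGNoise(img, noiseParams(0.05, 0.05, seed = 2))
  rep <- qualityReport(img, noisy)
  expect_identical(rep$channel,
                   c("cytoplasm", "nucleus", "particles", "average"))
  expect_equal(rep$mse[4], mean(rep$mse[1:3]))
  expect_equal(rep$psnr_db[4], mean(rep$psnr_db[1:3]))
  expect_true(all(rep$mse >= 0))
})
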