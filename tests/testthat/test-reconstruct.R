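test_that("forward-difference gradients match the stencil definition", {
  g <- imageGradients(matrix(0.3, 6, 6))
  expect_true(all(gradientComponents(g)$gx == 0))
  expect_true(all(gradientComponents(g)$gy == 0))

  ramp <- outer(rep(1, 5), 1:5)  # b(x, y) = x (column index)
  g <- gradientComponents(imageGradients(ramp))
  expect_true(all(g$gx[, 1:4] == 1))
  expect_true(all(g$gx[, 5] == 0))  # replicated boundary: zero across it
  expect_true(all(g$gy == 0))

  set.seed(8)
  b <- matrix(runif(25), 5, 5)
  g <- gradientComponents(imageGradients(b))
  for (i in 1:5) for (j in 1:5) {
    expect_identical(g$gx[i, j], if (j < 5) b[i, j + 1] - b[i, j] else 0)
    expect_identical(g$gy[i, j], if (i < 5) b[i + 1, j] - b[i, j] else 0)
  }
  expect_error(imageGradients(matrix(1, 1, 4)), "2x2")
})

test_that("gradient restriction is the componentwise mask product", {
  set.seed(9)
  g <- imageGradients(matrix(runif(64), 8, 8))
  full <- restrictGradients(g, matrix(TRUE, 8, 8))
  expect_identical(gradientComponents(full), gradientComponents(g))

  none <- restrictGradients(g, matrix(FALSE, 8, 8))
  expect_true(all(gradientComponents(none)$gx == 0))
  expect_true(all(gradientComponents(none)$gy == 0))

  checker <- outer(1:8, 1:8, function(i, j) (i + j) %% 2 == 0)
  res <- restrictGradients(g, checker)
  expect_equal(gradientComponents(res)$gx,
               gradientComponents(g)$gx * checker)
  expect_equal(gradientComponents(res)$gy,
               gradientComponents(g)$gy * checker)
  expect_error(restrictGradients(g, matrix(TRUE, 4, 4)), "shape")
})

test_that("the diffusion tensor is identity without structure and SPD always", {
  J <- tensorElements(buildDiffusionTensor(matrix(0.5, 16, 16)))
  expect_equal(J$j11, matrix(1, 16, 16))
  expect_equal(J$j12, matrix(0, 16, 16))
  expect_equal(J$j22, matrix(1, 16, 16))

  set.seed(4)
  for (trial in 1:3) {
    J <- tensorElements(buildDiffusionTensor(matrix(runif(900), 30, 30)))
    expect_true(all(J$j11 > 0))
    expect_true(all(J$j11 * J$j22 - J$j12^2 > 0))
  }
})

test_that("on a vertical step edge the strong diffusion axis is vertical", {
  b <- cbind(matrix(0, 32, 16), matrix(1, 32, 16))
  J <- tensorElements(buildDiffusionTensor(b, smoothingSigma = 1.5))
  i <- 16L
  for (j in 16:17) {  # columns flanking the step
    M <- matrix(c(J$j11[i, j], J$j12[i, j], J$j12[i, j], J$j22[i, j]), 2)
    e <- eigen(M, symmetric = TRUE)
    expect_gt(e$values[1] - e$values[2], 1e-6)  # anisotropic on the edge
    v <- e$vectors[, 1]  # (x, y) components of the dominant axis
    expect_lt(abs(v[1]), 1e-6)  # x-component ~ 0: axis parallel to the edge
    expect_gt(abs(v[2]), 1 - 1e-6)
  }
})

test_that("a zero source reconstructs the zero image", {
  z <- matrix(0, 10, 10)
  g <- new("GradientField", gx = z, gy = z)
  v <- solveWeightedPoisson(g, identityTensor(10, 10),
                            solverConfig(meanFix = "zero_mean"))
  expect_true(all(v == 0))
})

test_that("full gradients with identity tensor reproduce the image exactly", {
  set.seed(10)
  b <- matrix(runif(32 * 32), 32, 32)  # direct sparse path
  v <- solveWeightedPoisson(imageGradients(b), identityTensor(32, 32),
                            solverConfig(), targetMean = mean(b))
  expect_lt(max(abs(v - b)), 1e-6)

  b <- matrix(runif(80 * 80), 80, 80)  # conjugate-gradient path
  v <- solveWeightedPoisson(imageGradients(b), identityTensor(80, 80),
                            solverConfig(), targetMean = mean(b))
  expect_lt(max(abs(v - b)), 1e-6)
})

test_that("the iterative solution matches a dense direct oracle", {
  set.seed(11)
  for (trial in 1:5) {
    gx <- matrix(rnorm(144), 12, 12)
    gy <- matrix(rnorm(144), 12, 12)
    J <- randomSPDTensor(12, 12)
    got <- solveWeightedPoisson(new("GradientField", gx = gx, gy = gy), J,
                                solverConfig(meanFix = "zero_mean"))
    want <- denseWeightedPoissonOracle(gx, gy, J@j11, J@j12, J@j22)
    expect_lt(max(abs(got - want)), 1e-8)
  }
})

test_that("the assembled weighted Laplacian is symmetric with constant nullspace", {
  set.seed(12)
  J <- randomSPDTensor(9, 9)
  z <- matrix(0, 9, 9)
  sys <- MFdenoise:::assembleWeightedSystem(
    new("GradientField", gx = z, gy = z), J)
  A <- sys$A
  for (trial in 1:5) {
    u <- rnorm(81); w <- rnorm(81)
    lhs <- sum(w * as.vector(A %*% u))
    rhs <- sum(u * as.vector(A %*% w))
    expect_lt(abs(lhs - rhs), 1e-10 * max(1, abs(lhs)))
  }
  expect_lt(max(abs(A %*% rep(1, 81))), 1e-10)
})

test_that("non-SPD tensors are rejected by the solver", {
  z <- matrix(0, 6, 6)
  g <- new("GradientField", gx = z, gy = z)
  bad <- identityTensor(6, 6)
  bad@j12 <- matrix(2, 6, 6)  # det = 1 - 4 < 0
  expect_error(solveWeightedPoisson(g, bad, solverConfig()),
               "positive definite")
})

test_that("denoising is shift-equivariant and deterministic", {
  ph <- smallPhantom(seed = 2, size = 64L)
  noisy <- addMixedPGNoise(getChannel(phantomImage(ph), 1),
                           noiseParams(0.05, 0.05, seed = 3))
  d1 <- denoise(noisy)
  d2 <- denoise(noisy)
  expect_identical(d1, d2)

  shifted <- denoise(noisy + 0.37)
  expect_lt(max(abs((shifted - d1) - 0.37)), 1e-7)
})

test_that("noise-free input with full mask and identity tensor is preserved", {
  ph <- smallPhantom(seed = 6, size = 64L)
  img <- phantomImage(ph)
  out <- denoise(img, msmQuantile = 1.0, tensor = "identity")
  for (c in 1:3)
    expect_lt(max(abs(getChannel(out, c) - getChannel(img, c))), 1e-6)
})

test_that("denoising improves PSNR at the high-noise setting", {
  wins <- 0L
  for (s in 1:3) {
    ph <- smallPhantom(seed = s)
    img <- phantomImage(ph)
    noisy <- addMixedPGNoise(img, noiseParams(0.1, 0.1, seed = 50 + s))
    den <- denoise(noisy)
    qn <- qualityReport(img, noisy)
    qd <- qualityReport(img, den)
    wins <- wins + (qd$psnr_db[qd$channel == "average"] >
                      qn$psnr_db[qn$channel == "average"])
  }
  expect_gte(wins, 2L)
})

test_that("pipeline failures identify the failing stage", {
  expect_error(denoise(matrix(0.5, 8, 8)), "stage")
})
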