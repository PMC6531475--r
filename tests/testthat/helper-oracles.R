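# Independent oracles and fixture builders shared across test files.
# Everything here is deliberately written from scratch (nested loops, dense
# linear algebra) so it never reuses the code paths it checks.

# Mirror (half-sample symmetric) index into 1..n, by explicit reflection.
reflectIndex <- function(i, n) {
  while (i < 1L || i > n) {
    if (i < 1L) i <- 1L - i
    if (i > n) i <- 2L * n + 1L - i
  }
  i
}

# Brute-force cross-correlation with mirror boundary: O(N^2 K^2).
bruteConvolveMirror <- function(x, kernel) {
  h <- (nrow(kernel) - 1L) %/% 2L
  out <- matrix(0, nrow(x), ncol(x))
  for (i in seq_len(nrow(x))) {
    for (j in seq_len(ncol(x))) {
      acc <- 0
      for (a in -h:h) {
        for (b in -h:h) {
          ii <- reflectIndex(i + a, nrow(x))
          jj <- reflectIndex(j + b, ncol(x))
          acc <- acc + kernel[a + h + 1L, b + h + 1L] * x[ii, jj]
        }
      }
      out[i, j] <- acc
    }
  }
  out
}

# Dense assembly of the forward-difference gradient operators as explicit
# matrices (column-major pixel ordering), by looping over pixels.
denseGradientOps <- function(nr, nc) {
  npix <- nr * nc
  Gx <- matrix(0, npix, npix)
  Gy <- matrix(0, npix, npix)
  id <- function(i, j) (j - 1L) * nr + i
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      p <- id(i, j)
      if (j < nc) {
        Gx[p, id(i, j + 1L)] <- 1
        Gx[p, p] <- -1
      }
      if (i < nr) {
        Gy[p, id(i + 1L, j)] <- 1
        Gy[p, p] <- -1
      }
    }
  }
  list(Gx = Gx, Gy = Gy)
}

# Dense direct solve of div(J grad v) = div(J g) with the mean pinned to
# zero via a dense saddle-point system.
denseWeightedPoissonOracle <- function(gx, gy, j11, j12, j22) {
  nr <- nrow(gx); nc <- ncol(gx)
  npix <- nr * nc
  ops <- denseGradientOps(nr, nc)
  W11 <- diag(as.vector(j11)); W12 <- diag(as.vector(j12))
  W22 <- diag(as.vector(j22))
  A <- t(ops$Gx) %*% (W11 %*% ops$Gx + W12 %*% ops$Gy) +
    t(ops$Gy) %*% (W12 %*% ops$Gx + W22 %*% ops$Gy)
  rhs <- t(ops$Gx) %*% (as.vector(j11) * as.vector(gx) +
                        as.vector(j12) * as.vector(gy)) +
    t(ops$Gy) %*% (as.vector(j12) * as.vector(gx) +
                   as.vector(j22) * as.vector(gy))
  b <- rhs - mean(rhs)
  K <- rbind(cbind(A, rep(1, npix)), c(rep(1, npix), 0))
  sol <- solve(K, c(b, 0))
  v <- sol[seq_len(npix)]
  matrix(v - mean(v), nr, nc)
}

# Random per-pixel SPD tensor field: positive diagonals and a bounded
# correlation so j11*j22 - j12^2 > 0 everywhere.
randomSPDTensor <- function(nr, nc) {
  j11 <- matrix(exp(rnorm(nr * nc, 0, 0.5)), nr, nc)
  j22 <- matrix(exp(rnorm(nr * nc, 0, 0.5)), nr, nc)
  rho <- matrix(runif(nr * nc, -0.8, 0.8), nr, nc)
  j12 <- rho * sqrt(j11 * j22)
  new("TensorField", j11 = j11, j12 = j12, j22 = j22)
}

# Small phantom used by several pipeline tests.
smallPhantom <- function(seed = 1L, size = 128L) {
  generatePhantom(phantomSpec(size, size, nCells = 5L, nClusters = 2L,
                              cellRadiusRange = c(10, 18), seed = seed))
}

# Single centred bright disk (blurred), for edge-affinity checks.
diskPhantom <- function(n = 96L, radius = 24L, blur = 1) {
  y <- matrix(seq_len(n), n, n)
  x <- t(y)
  img <- 0.8 * ((y - n / 2)^2 + (x - n / 2)^2 <= radius^2)
  pmax(MFdenoise:::gaussianBlur(img, blur), 0)  # clamp FFT roundoff
}
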