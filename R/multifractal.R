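# Stage 1: microcanonical multifractal decomposition.
#
# A positive multiscale measure mu(x, r) is built by convolving a
# non-negative density of the image with kernels from the family
# Psi(x) = (1 + |x|^2)^(-gamma) dilated to each scale r, averaging over
# gamma. The singularity exponent d(x) is the slope of log mu vs log r per
# pixel; the most singular manifold (MSM) is the lower tail of d(x).

# Psi((x)/r) sampled on a square support of half-width ceil(truncation * r),
# deliberately NOT normalized to unit sum: mu must scale like the measure of
# a ball of radius r, and unit-sum kernels would flatten the power law.
psiKernel <- function(r, gamma, truncation) {
  h <- as.integer(ceiling(truncation * r))
  g <- seq(-h, h)
  d2 <- outer(g^2, g^2, "+")
  1 / (1 + d2 / r^2)^gamma
}

#' Multiscale wavelet measure of an image
#'
#' For each scale r, convolves the chosen non-negative density of `b` (its
#' gradient magnitude by default, or the intensity itself) with the kernel
#' `Psi(x / r) = (1 + |x / r|^2)^(-gamma)` for every configured gamma, then
#' averages the coefficient planes over gamma. Kernels are truncated to a
#' square support of half-width `kernelTruncation * r` and left
#' unnormalized, so the result behaves like the density's mass in a ball
#' that grows with r. Boundaries are handled by mirror reflection; the
#' output is floored at `floorEpsilon` so logarithms are always defined.
#'
#' @param b numeric matrix (one image channel), finite values.
#' @param cfg a [MeasureConfig-class]; see [measureConfig()].
#' @return a [ScaleStack-class].
#' @examples
#' stack <- waveletMeasure(matrix(runif(256), 16, 16),
#'                         measureConfig(scales = 1:3))
#' stack
#' @export
waveletMeasure <- function(b, cfg = measureConfig()) {
  stopifnot(is(cfg, "MeasureConfig"))
  validObject(cfg)
  assertMatrix(b)
  hmax <- as.integer(ceiling(cfg@kernelTruncation * max(cfg@scales)))
  if (min(dim(b)) < 2L)
    stop("image must be at least 2x2", call. = FALSE)
  if (min(dim(b)) < 2L * hmax + 1L)
    stop("image smaller than the largest kernel support (",
         2L * hmax + 1L, " pixels)", call. = FALSE)

  density <- switch(cfg@densityMode,
    gradient_magnitude = sqrt(forwardDiffX(b)^2 + forwardDiffY(b)^2),
    intensity = b)

  vals <- array(0, c(nrow(b), ncol(b), length(cfg@scales)))
  for (s in seq_along(cfg@scales)) {
    acc <- matrix(0, nrow(b), ncol(b))
    for (g in cfg@gammas) {
      acc <- acc + convolveMirror(density,
                                  psiKernel(cfg@scales[s], g,
                                            cfg@kernelTruncation))
    }
    vals[, , s] <- pmax(acc / length(cfg@gammas), cfg@floorEpsilon)
  }
  new("ScaleStack", values = vals, scales = cfg@scales,
      floor = cfg@floorEpsilon)
}

#' Estimate singularity exponents by log-log regression
#'
#' Fits, independently at every pixel, the ordinary least-squares line
#' `log mu(x, r) = log alpha(x) + d(x) log r` across the stack's scales.
#' The slope is the singularity exponent d(x); the intercept is stored as
#' `logAlpha`; the per-pixel coefficient of determination quantifies how
#' well the power law holds locally.
#'
#' Pixels whose measure sat at the stack's positivity floor at every scale
#' (possible only for stacks built by [waveletMeasure()], which records its
#' floor) contain no signal at any scale: an identically vanishing measure
#' decays faster than any power of r, so such pixels are maximally regular.
#' They are assigned the largest exponent observed among informative pixels
#' rather than the floor-artifact slope of zero, which would otherwise rank
#' empty background as more singular than real edges. Stacks constructed
#' directly (floor = 0) are fit verbatim.
#'
#' @param stack a [ScaleStack-class] with at least two scales and strictly
#'   positive values.
#' @return an [ExponentMap-class].
#' @examples
#' vals <- array(rep(2.5 * (1:4)^1.3, each = 64), c(8, 8, 4))
#' em <- estimateExponents(new("ScaleStack", values = vals, scales = 1:4))
#' range(exponentValues(em))  # 1.3 everywhere
#' @export
estimateExponents <- function(stack) {
  stopifnot(is(stack, "ScaleStack"))
  validObject(stack)
  if (any(stack@values <= 0))
    stop("measure values must be strictly positive", call. = FALSE)
  d3 <- dim(stack@values)
  npix <- d3[1] * d3[2]
  logmu <- matrix(log(stack@values), npix, d3[3])
  logr <- log(stack@scales)

  lrc <- logr - mean(logr)
  sxx <- sum(lrc^2)
  ybar <- rowMeans(logmu)
  sxy <- logmu %*% lrc
  slope <- as.vector(sxy) / sxx
  intercept <- ybar - slope * mean(logr)

  fitted <- outer(slope, logr) + intercept
  ssRes <- rowSums((logmu - fitted)^2)
  ssTot <- rowSums((logmu - ybar)^2)
  r2 <- ifelse(ssTot > 0, pmax(pmin(1 - ssRes / ssTot, 1), 0), 1)

  if (stack@floor > 0) {
    floored <- rowSums(logmu <= log(stack@floor) * (1 - 1e-12)) == d3[3]
    if (any(floored) && !all(floored))
      slope[floored] <- max(slope[!floored])
  }

  new("ExponentMap",
      d = matrix(slope, d3[1], d3[2]),
      logAlpha = matrix(intercept, d3[1], d3[2]),
      r2 = matrix(r2, d3[1], d3[2]))
}

#' Level set of the exponent field
#'
#' The fractal component at exponent value d: the set of pixels whose
#' exponent lies within `tol` of `dValue`.
#'
#' @param em an [ExponentMap-class].
#' @param dValue target exponent.
#' @param tol non-negative half-width of the band (`Inf` selects all).
#' @return a [FeatureMask-class] with `dThreshold = dValue`.
#' @export
levelSet <- function(em, dValue, tol = 0) {
  stopifnot(is(em, "ExponentMap"), tol >= 0)
  new("FeatureMask", mask = abs(em@d - dValue) <= tol,
      dThreshold = as.numeric(dValue))
}

#' Extract the most singular manifold
#'
#' The most informative pixel set: pixels whose singularity exponent lies at
#' or below the given lower quantile of the exponent distribution. The
#' literal argmin of d(x) is generically a single pixel; a lower-quantile
#' band yields the dense, edge-map-like set the decomposition is meant to
#' produce. Ties at the threshold are all included, so a constant exponent
#' map selects every pixel at any quantile.
#'
#' @param em an [ExponentMap-class].
#' @param quantile lower-tail mass in (0, 1]; default 0.25.
#' @return a [FeatureMask-class]; `maskThreshold()` gives the exponent
#'   cutoff used.
#' @examples
#' em <- new("ExponentMap", d = matrix(1:16, 4, 4),
#'           logAlpha = matrix(0, 4, 4), r2 = matrix(1, 4, 4))
#' sum(maskMatrix(extractMSM(em, 0.25)))  # the 4 smallest-valued pixels
#' @export
extractMSM <- function(em, quantile = 0.25) {
  stopifnot(is(em, "ExponentMap"))
  if (!is.numeric(quantile) || quantile <= 0 || quantile > 1)
    stop("quantile must lie in (0, 1]", call. = FALSE)
  thr <- if (quantile == 1) max(em@d) else
    as.numeric(stats::quantile(em@d, probs = quantile, type = 7))
  new("FeatureMask", mask = em@d <= thr, dThreshold = thr)
}
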