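# Mixed Poisson-Gaussian image-formation model.

#' Corrupt an image with mixed Poisson-Gaussian noise
#'
#' Applies the fluorescence-microscopy observation model
#' `b = g0 * z + eps`, with the photon count `z ~ Poisson(v / g0)` drawn
#' per pixel and `eps` zero-mean Gaussian noise of standard deviation
#' `sigma`, so that `E[b] = v` and `Var[b] = g0 * v + sigma^2` pixelwise.
#' The output is deliberately not clipped: the Gaussian tail produces
#' negative values and downstream code accepts them.
#'
#' Multichannel images are corrupted channel by channel with independent
#' draws derived from the single user-facing seed (channel c uses
#' `seed + c - 1`).
#'
#' @param v clean image: a non-negative numeric matrix or a
#'   [MultichannelImage-class].
#' @param params a [NoiseParams-class]; see [noiseParams()].
#' @return object of the same type as `v`, noisy.
#' @examples
#' b <- addMixedPGNoise(matrix(0.5, 32, 32), noiseParams(0.01, 0.01, seed = 1))
#' mean(b)
#' @export
setGeneric("addMixedPGNoise",
           function(v, params) standardGeneric("addMixedPGNoise"))

#' @rdname addMixedPGNoise
#' @export
setMethod("addMixedPGNoise", signature(v = "matrix", params = "NoiseParams"),
          function(v, params) {
  validObject(params)
  assertMatrix(v, "clean image")
  if (any(v < 0))
    stop("clean intensities must be non-negative", call. = FALSE)
  withSeed(params@seed, {
    z <- rpois(length(v), lambda = as.vector(v) / params@g0)
    eps <- if (params@sigma > 0) rnorm(length(v), 0, params@sigma) else 0
    matrix(params@g0 * z + eps, nrow(v), ncol(v))
  })
})

#' @rdname addMixedPGNoise
#' @export
setMethod("addMixedPGNoise",
          signature(v = "MultichannelImage", params = "NoiseParams"),
          function(v, params) {
  noisy <- lapply(seq_along(v@channels), function(c) {
    sub <- noiseParams(params@g0, params@sigma, seed = params@seed + c - 1L)
    addMixedPGNoise(v@channels[[c]], sub)
  })
  multichannelImage(noisy, v@channelNames)
})

#' The five-level noise schedule of the simulated-data benchmark
#'
#' Returns the five mixed Poisson-Gaussian settings used throughout the
#' benchmark, `g0 = sigma` on a half-decade grid from `1e-3` (low noise) to
#' `1e-1` (high noise).
#'
#' @param seed RNG seed stored in every returned [NoiseParams-class]
#'   (callers typically replace it per trial).
#' @return list of 5 [NoiseParams-class] objects, low to high noise.
#' @examples
#' vapply(noiseLevelSchedule(), function(p) p@g0, numeric(1))
#' @export
noiseLevelSchedule <- function(seed = 1L) {
  lapply(10^seq(-3, -1, by = 0.5), function(level)
    noiseParams(g0 = level, sigma = level, seed = seed))
}
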