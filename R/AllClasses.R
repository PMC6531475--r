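#' @import methods
#' @importFrom stats fft quantile rnorm rpois runif sd
NULL

#' MultichannelImage: an ordered set of co-registered image channels
#'
#' Container for one or more 2-D scalar channels on a common pixel grid.
#' Channels are numeric matrices indexed `[row, column]` with the origin at
#' the top-left; values are intensities, nominally in `[0, 1]` for clean
#' images but unbounded for noisy ones (the mixed Poisson-Gaussian model
#' produces negative excursions).
#'
#' @slot channels list of numeric matrices, all with identical dimensions.
#' @slot channelNames character vector of channel labels.
#' @export
setClass("MultichannelImage",
  representation(channels = "list", channelNames = "character"),
  validity = function(object) {
    if (length(object@channels) == 0L) return("at least one channel required")
    dims <- lapply(object@channels, dim)
    if (!all(vapply(object@channels, function(ch)
      is.matrix(ch) && is.numeric(ch), logical(1))))
      return("every channel must be a numeric matrix")
    if (!all(vapply(dims, identical, logical(1), y = dims[[1]])))
      return("all channels must share identical dimensions")
    if (!all(vapply(object@channels, function(ch) all(is.finite(ch)),
                    logical(1))))
      return("channel values must be finite")
    if (length(object@channelNames) != length(object@channels))
      return("one name per channel required")
    TRUE
  })

#' Construct a MultichannelImage
#'
#' @param channels a numeric matrix (single channel) or list of matrices.
#' @param channelNames labels; defaults to `"cytoplasm"`, `"nucleus"`,
#'   `"particles"` for 3 channels, `"ch1"`, ... otherwise.
#' @return a [MultichannelImage-class] object.
#' @examples
#' img <- multichannelImage(matrix(runif(64), 8, 8))
#' nChannels(img)
#' @export
multichannelImage <- function(channels, channelNames = NULL) {
  if (is.matrix(channels)) channels <- list(channels)
  if (is.null(channelNames)) {
    channelNames <- if (length(channels) == 3L)
      c("cytoplasm", "nucleus", "particles")
    else paste0("ch", seq_along(channels))
  }
  new("MultichannelImage", channels = channels,
      channelNames = as.character(channelNames))
}

#' PhantomSpec: parameters of the synthetic cell-image generator
#'
#' @slot height,width image size in pixels (at least 32).
#' @slot nCells number of cells to place.
#' @slot nClusters number of spatial clusters the cells gather around.
#' @slot nSubcellularObjects bright particles per cell.
#' @slot cellRadiusRange min/max cell semi-major axis, pixels.
#' @slot nucleusFraction nucleus axis as a fraction of the cell axis, in (0,1).
#' @slot particleRadiusRange min/max particle radius, pixels.
#' @slot intensityLevels per-channel peak intensity in (0,1]
#'   (cytoplasm, nucleus, particles).
#' @slot blurSigma Gaussian blur applied to every channel, pixels.
#' @slot seed RNG seed; the generator is deterministic given the spec.
#' @export
setClass("PhantomSpec",
  representation(height = "integer", width = "integer", nCells = "integer",
                 nClusters = "integer", nSubcellularObjects = "integer",
                 cellRadiusRange = "numeric", nucleusFraction = "numeric",
                 particleRadiusRange = "numeric", intensityLevels = "numeric",
                 blurSigma = "numeric", seed = "integer"),
  validity = function(object) {
    if (object@height < 32L || object@width < 32L)
      return("height and width must be >= 32")
    if (object@nCells < 0L) return("nCells must be >= 0")
    if (object@nCells > 0L && object@nClusters < 1L)
      return("nClusters must be >= 1 when nCells > 0")
    if (object@nSubcellularObjects < 0L)
      return("nSubcellularObjects must be >= 0")
    if (length(object@cellRadiusRange) != 2L ||
        any(object@cellRadiusRange <= 0) ||
        object@cellRadiusRange[1] > object@cellRadiusRange[2])
      return("cellRadiusRange must be positive (min, max) with min <= max")
    if (object@nucleusFraction <= 0 || object@nucleusFraction >= 1)
      return("nucleusFraction must lie strictly between 0 and 1")
    if (length(object@particleRadiusRange) != 2L ||
        any(object@particleRadiusRange <= 0) ||
        object@particleRadiusRange[1] > object@particleRadiusRange[2])
      return("particleRadiusRange must be positive (min, max) with min <= max")
    if (length(object@intensityLevels) != 3L ||
        any(object@intensityLevels <= 0) || any(object@intensityLevels > 1))
      return("intensityLevels must be three values in (0, 1]")
    if (object@blurSigma < 0) return("blurSigma must be >= 0")
    TRUE
  })

#' Construct a PhantomSpec
#'
#' Defaults mirror the simulated-data settings used throughout the package's
#' benchmark: a 512x512 field with 20 cells in 3 clusters and 4 subcellular
#' particles per cell. Radii, intensities and blur have no canonical
#' published values and are free, documented choices.
#'
#' @param height,width image size in pixels.
#' @param nCells,nClusters,nSubcellularObjects population structure.
#' @param cellRadiusRange,nucleusFraction,particleRadiusRange geometry.
#' @param intensityLevels per-channel peaks (cytoplasm, nucleus, particles).
#' @param blurSigma channel blur in pixels.
#' @param seed RNG seed.
#' @return a [PhantomSpec-class] object.
#' @examples
#' spec <- phantomSpec(128, 128, nCells = 5, seed = 7)
#' @export
phantomSpec <- function(height = 512L, width = 512L, nCells = 20L,
                        nClusters = 3L, nSubcellularObjects = 4L,
                        cellRadiusRange = c(14, 26),
                        nucleusFraction = 0.45,
                        particleRadiusRange = c(1.5, 3),
                        intensityLevels = c(0.6, 0.8, 1.0),
                        blurSigma = 1, seed = 1L) {
  new("PhantomSpec", height = as.integer(height), width = as.integer(width),
      nCells = as.integer(nCells), nClusters = as.integer(nClusters),
      nSubcellularObjects = as.integer(nSubcellularObjects),
      cellRadiusRange = as.numeric(cellRadiusRange),
      nucleusFraction = as.numeric(nucleusFraction),
      particleRadiusRange = as.numeric(particleRadiusRange),
      intensityLevels = as.numeric(intensityLevels),
      blurSigma = as.numeric(blurSigma), seed = as.integer(seed))
}

#' PhantomTruth: a generated phantom with its ground truth
#'
#' @slot image the three-channel [MultichannelImage-class] phantom.
#' @slot cellCenters numeric matrix (nCells x 2) of (row, col) centres.
#' @slot labelMap integer matrix; 0 = background, k = pixel owned by cell k.
#' @slot cellMasks list of logical matrices, one cytoplasm support per cell.
#' @slot nucleusMasks list of logical matrices, one nucleus support per cell.
#' @slot particleMasks list of logical matrices, union of each cell's
#'   particle supports.
#' @export
setClass("PhantomTruth",
  representation(image = "MultichannelImage", cellCenters = "matrix",
                 labelMap = "matrix", cellMasks = "list",
                 nucleusMasks = "list", particleMasks = "list"),
  validity = function(object) {
    n <- nrow(object@cellCenters)
    labs <- sort(unique(as.vector(object@labelMap)))
    labs <- labs[labs != 0L]
    if (length(labs) != n)
      return("number of distinct nonzero labels must equal the cell count")
    if (length(object@cellMasks) != n || length(object@nucleusMasks) != n)
      return("one cytoplasm and one nucleus mask per cell required")
    for (k in seq_len(n)) {
      if (any(object@nucleusMasks[[k]] & !object@cellMasks[[k]]))
        return("each nucleus support must lie inside its cell's cytoplasm")
    }
    TRUE
  })

#' MeasureConfig: parameters of the multiscale wavelet measure
#'
#' @slot scales increasing radii r in pixels (at least two, for the log-log
#'   regression).
#' @slot gammas exponents of the kernel family
#'   `Psi(x) = (1 + |x|^2)^(-gamma)`; coefficients are averaged over gammas.
#' @slot densityMode `"gradient_magnitude"` (default: the measure aggregates
#'   `|grad b|`, giving an edge-map-like most singular manifold) or
#'   `"intensity"` (aggregates `b` itself).
#' @slot kernelTruncation kernel support half-width as a multiple of r.
#' @slot floorEpsilon positivity floor applied to the measure before logs.
#' @export
setClass("MeasureConfig",
  representation(scales = "numeric", gammas = "numeric",
                 densityMode = "character", kernelTruncation = "numeric",
                 floorEpsilon = "numeric"),
  validity = function(object) {
    if (length(object@scales) < 2L || any(object@scales <= 0) ||
        is.unsorted(object@scales, strictly = TRUE))
      return("scales must be >= 2 strictly increasing positive radii")
    if (length(object@gammas) < 1L || any(object@gammas < 1))
      return("gammas must all be >= 1")
    if (!object@densityMode %in% c("gradient_magnitude", "intensity"))
      return("densityMode must be 'gradient_magnitude' or 'intensity'")
    if (object@kernelTruncation <= 0)
      return("kernelTruncation must be positive")
    if (object@floorEpsilon <= 0)
      return("floorEpsilon must be positive")
    TRUE
  })

#' Construct a MeasureConfig
#'
#' @param scales radii in pixels; the default `1:5` targets the small-scale
#'   regime where the power law holds.
#' @param gammas kernel exponents, default `1:4`.
#' @param densityMode `"gradient_magnitude"` or `"intensity"`.
#' @param kernelTruncation support half-width in units of r (default 3).
#' @param floorEpsilon measure floor before taking logarithms.
#' @return a [MeasureConfig-class] object.
#' @export
measureConfig <- function(scales = 1:5, gammas = 1:4,
                          densityMode = c("gradient_magnitude", "intensity"),
                          kernelTruncation = 3, floorEpsilon = 1e-12) {
  new("MeasureConfig", scales = as.numeric(scales),
      gammas = as.numeric(gammas), densityMode = match.arg(densityMode),
      kernelTruncation = as.numeric(kernelTruncation),
      floorEpsilon = as.numeric(floorEpsilon))
}

#' ScaleStack: the multiscale measure values
#'
#' Holds `mu(x, r)` for every pixel x over the configured scale grid, one
#' plane per scale. Values are strictly positive (floor-regularized) so
#' logarithms are defined.
#'
#' @slot values numeric array, `height x width x nScales`.
#' @slot scales the radii r, pixels.
#' @slot floor the positivity floor applied when the stack was built
#'   (0 when constructed directly). Pixels whose measure never rises above
#'   the floor at any scale carry no singularity information and are
#'   treated as maximally regular by [estimateExponents()].
#' @export
setClass("ScaleStack",
  representation(values = "array", scales = "numeric", floor = "numeric"),
  prototype = prototype(floor = 0),
  validity = function(object) {
    d <- dim(object@values)
    if (length(d) != 3L) return("values must be a 3-D array")
    if (d[3] != length(object@scales))
      return("one plane per scale required")
    if (length(object@scales) < 2L)
      return("at least two scales required")
    if (any(object@values <= 0) || !all(is.finite(object@values)))
      return("measure values must be strictly positive and finite")
    TRUE
  })

#' ExponentMap: the singularity-exponent field
#'
#' Per-pixel results of the log-log regression `log mu = log alpha +
#' d log r`: the exponent d(x), the intercept log alpha(x), and the
#' coefficient of determination of the fit.
#'
#' @slot d numeric matrix of exponents (dimensionless).
#' @slot logAlpha numeric matrix of regression intercepts.
#' @slot r2 numeric matrix of per-pixel R^2 in `[0, 1]`.
#' @export
setClass("ExponentMap",
  representation(d = "matrix", logAlpha = "matrix", r2 = "matrix"),
  validity = function(object) {
    if (!all(is.finite(object@d))) return("exponents must be finite")
    if (!identical(dim(object@d), dim(object@logAlpha)) ||
        !identical(dim(object@d), dim(object@r2)))
      return("d, logAlpha and r2 must share dimensions")
    if (any(object@r2 < -1e-12) || any(object@r2 > 1 + 1e-12))
      return("r2 must lie in [0, 1]")
    TRUE
  })

#' FeatureMask: a binary pixel set from the exponent decomposition
#'
#' Level sets of d(x) and the most singular manifold are represented as
#' logical masks plus the exponent cutoff that produced them.
#'
#' @slot mask logical matrix.
#' @slot dThreshold the exponent cutoff used.
#' @export
setClass("FeatureMask",
  representation(mask = "matrix", dThreshold = "numeric"),
  validity = function(object) {
    if (!is.logical(object@mask)) return("mask must be logical")
    TRUE
  })

#' TensorField: per-pixel 2x2 symmetric positive-definite diffusion tensors
#'
#' Stored as the three independent elements j11, j12, j22 (j21 = j12 by
#' symmetry). Validity enforces positive definiteness at every pixel.
#'
#' @slot j11,j12,j22 numeric matrices of tensor elements.
#' @export
setClass("TensorField",
  representation(j11 = "matrix", j12 = "matrix", j22 = "matrix"),
  validity = function(object) {
    if (!identical(dim(object@j11), dim(object@j12)) ||
        !identical(dim(object@j11), dim(object@j22)))
      return("tensor element planes must share dimensions")
    if (any(object@j11 <= 0) ||
        any(object@j11 * object@j22 - object@j12^2 <= 0))
      return("tensor must be positive definite at every pixel")
    TRUE
  })

#' NoiseParams: the mixed Poisson-Gaussian image-formation parameters
#'
#' The observation model is `b = g0 * z + eps` with
#' `z ~ Poisson(v / g0)` per pixel and `eps` zero-mean Gaussian with
#' standard deviation `sigma`, so `E[b] = v` and `Var[b] = g0 v + sigma^2`.
#'
#' @slot g0 detector gain (> 0); scales the Poisson photon statistics.
#' @slot sigma Gaussian measurement-noise standard deviation (>= 0).
#' @slot seed RNG seed.
#' @export
setClass("NoiseParams",
  representation(g0 = "numeric", sigma = "numeric", seed = "integer"),
  validity = function(object) {
    if (object@g0 <= 0) return("g0 must be > 0")
    if (object@sigma < 0) return("sigma must be >= 0")
    TRUE
  })

#' Construct NoiseParams
#'
#' @param g0 detector gain, > 0.
#' @param sigma Gaussian standard deviation, >= 0.
#' @param seed RNG seed.
#' @return a [NoiseParams-class] object.
#' @examples
#' noiseParams(g0 = 0.1, sigma = 0.1, seed = 3)
#' @export
noiseParams <- function(g0, sigma, seed = 1L) {
  new("NoiseParams", g0 = as.numeric(g0), sigma = as.numeric(sigma),
      seed = as.integer(seed))
}

#' SolverConfig: weighted-Poisson solver controls
#'
#' @slot tol relative residual tolerance.
#' @slot maxIter iteration cap for the conjugate-gradient solve.
#' @slot meanFix `"input_mean"` (pin the solution mean to a caller-supplied
#'   value, the denoiser's default) or `"zero_mean"`.
#' @export
setClass("SolverConfig",
  representation(tol = "numeric", maxIter = "integer", meanFix = "character"),
  validity = function(object) {
    if (object@tol <= 0) return("tol must be > 0")
    if (object@maxIter < 1L) return("maxIter must be >= 1")
    if (!object@meanFix %in% c("input_mean", "zero_mean"))
      return("meanFix must be 'input_mean' or 'zero_mean'")
    TRUE
  })

#' Construct a SolverConfig
#'
#' @param tol relative residual tolerance (default 1e-10; the gradient field
#'   determines the image only through a rank-deficient operator, so a tight
#'   residual keeps the reconstruction error well below visual precision).
#' @param maxIter conjugate-gradient iteration cap.
#' @param meanFix how the additive constant (the pure-Neumann nullspace) is
#'   fixed.
#' @return a [SolverConfig-class] object.
#' @export
solverConfig <- function(tol = 1e-10, maxIter = 10000L,
                         meanFix = c("input_mean", "zero_mean")) {
  new("SolverConfig", tol = as.numeric(tol), maxIter = as.integer(maxIter),
      meanFix = match.arg(meanFix))
}

#' GradientField: per-pixel image gradients
#'
#' @slot gx d/dx component (x = column index, increasing rightwards).
#' @slot gy d/dy component (y = row index, increasing downwards).
#' @export
setClass("GradientField",
  representation(gx = "matrix", gy = "matrix"),
  validity = function(object) {
    if (!identical(dim(object@gx), dim(object@gy)))
      return("gx and gy must share dimensions")
    if (!all(is.finite(object@gx)) || !all(is.finite(object@gy)))
      return("gradient components must be finite")
    TRUE
  })
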