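# Accessor generics, methods and show() methods for the core classes.

#' Number of channels in a MultichannelImage
#' @param x a [MultichannelImage-class].
#' @return integer count.
#' @export
setGeneric("nChannels", function(x) standardGeneric("nChannels"))

#' @rdname nChannels
#' @export
setMethod("nChannels", "MultichannelImage",
          function(x) length(x@channels))

#' Channel names
#' @param x a [MultichannelImage-class].
#' @return character vector of labels.
#' @export
setGeneric("channelNames", function(x) standardGeneric("channelNames"))

#' @rdname channelNames
#' @export
setMethod("channelNames", "MultichannelImage", function(x) x@channelNames)

#' Extract one channel as a numeric matrix
#' @param x a [MultichannelImage-class].
#' @param i channel index or name.
#' @return numeric matrix.
#' @export
setGeneric("getChannel", function(x, i) standardGeneric("getChannel"))

#' @rdname getChannel
#' @export
setMethod("getChannel", "MultichannelImage", function(x, i) {
  if (is.character(i)) i <- match(i, x@channelNames)
  x@channels[[i]]
})

#' All channels as a list of matrices
#' @param x a [MultichannelImage-class].
#' @return named list of numeric matrices.
#' @export
setGeneric("channelList", function(x) standardGeneric("channelList"))

#' @rdname channelList
#' @export
setMethod("channelList", "MultichannelImage", function(x) {
  stats::setNames(x@channels, x@channelNames)
})

#' @describeIn nChannels image dimensions (rows, columns).
#' @export
setMethod("dim", "MultichannelImage", function(x) dim(x@channels[[1]]))

#' Scale grid of a ScaleStack
#' @param x a [ScaleStack-class].
#' @return numeric vector of radii.
#' @export
setGeneric("measureScales", function(x) standardGeneric("measureScales"))

#' @rdname measureScales
#' @export
setMethod("measureScales", "ScaleStack", function(x) x@scales)

#' Measure values of a ScaleStack
#' @param x a [ScaleStack-class].
#' @return 3-D numeric array (rows x cols x scales).
#' @export
setGeneric("measureValues", function(x) standardGeneric("measureValues"))

#' @rdname measureValues
#' @export
setMethod("measureValues", "ScaleStack", function(x) x@values)

#' Singularity exponents of an ExponentMap
#' @param x an [ExponentMap-class].
#' @return numeric matrix d(x).
#' @export
setGeneric("exponentValues", function(x) standardGeneric("exponentValues"))

#' @rdname exponentValues
#' @export
setMethod("exponentValues", "ExponentMap", function(x) x@d)

#' Regression intercepts (log alpha) of an ExponentMap
#' @param x an [ExponentMap-class].
#' @return numeric matrix.
#' @export
setGeneric("exponentIntercepts",
           function(x) standardGeneric("exponentIntercepts"))

#' @rdname exponentIntercepts
#' @export
setMethod("exponentIntercepts", "ExponentMap", function(x) x@logAlpha)

#' Per-pixel regression quality of an ExponentMap
#' @param x an [ExponentMap-class].
#' @return numeric matrix of R^2 values.
#' @export
setGeneric("exponentFitR2", function(x) standardGeneric("exponentFitR2"))

#' @rdname exponentFitR2
#' @export
setMethod("exponentFitR2", "ExponentMap", function(x) x@r2)

#' Binary mask of a FeatureMask
#' @param x a [FeatureMask-class].
#' @return logical matrix.
#' @export
setGeneric("maskMatrix", function(x) standardGeneric("maskMatrix"))

#' @rdname maskMatrix
#' @export
setMethod("maskMatrix", "FeatureMask", function(x) x@mask)

#' Exponent cutoff that produced a FeatureMask
#' @param x a [FeatureMask-class].
#' @return numeric threshold.
#' @export
setGeneric("maskThreshold", function(x) standardGeneric("maskThreshold"))

#' @rdname maskThreshold
#' @export
setMethod("maskThreshold", "FeatureMask", function(x) x@dThreshold)

#' Tensor element planes of a TensorField
#' @param x a [TensorField-class].
#' @return named list with matrices `j11`, `j12`, `j22`.
#' @export
setGeneric("tensorElements", function(x) standardGeneric("tensorElements"))

#' @rdname tensorElements
#' @export
setMethod("tensorElements", "TensorField",
          function(x) list(j11 = x@j11, j12 = x@j12, j22 = x@j22))

#' Gradient components of a GradientField
#' @param x a [GradientField-class].
#' @return named list with matrices `gx`, `gy`.
#' @export
setGeneric("gradientComponents",
           function(x) standardGeneric("gradientComponents"))

#' @rdname gradientComponents
#' @export
setMethod("gradientComponents", "GradientField",
          function(x) list(gx = x@gx, gy = x@gy))

#' Phantom ground-truth accessors
#' @param x a [PhantomTruth-class].
#' @return `phantomImage`: the [MultichannelImage-class]; `labelMap`: the
#'   integer label matrix; `cellCenters`: an nCells x 2 matrix of (row, col)
#'   centres.
#' @export
setGeneric("phantomImage", function(x) standardGeneric("phantomImage"))

#' @rdname phantomImage
#' @export
setMethod("phantomImage", "PhantomTruth", function(x) x@image)

#' @rdname phantomImage
#' @export
setGeneric("labelMap", function(x) standardGeneric("labelMap"))

#' @rdname phantomImage
#' @export
setMethod("labelMap", "PhantomTruth", function(x) x@labelMap)

#' @rdname phantomImage
#' @export
setGeneric("cellCenters", function(x) standardGeneric("cellCenters"))

#' @rdname phantomImage
#' @export
setMethod("cellCenters", "PhantomTruth", function(x) x@cellCenters)

setMethod("show", "MultichannelImage", function(object) {
  d <- dim(object@channels[[1]])
  cat("MultichannelImage:", d[1], "x", d[2], "pixels,",
      length(object@channels), "channel(s)\n")
  cat("  channels:", paste(object@channelNames, collapse = ", "), "\n")
  rng <- range(unlist(lapply(object@channels, range)))
  cat(sprintf("  intensity range: [%.4g, %.4g]\n", rng[1], rng[2]))
})

setMethod("show", "PhantomTruth", function(object) {
  d <- dim(object@labelMap)
  cat("PhantomTruth:", d[1], "x", d[2], "pixels,",
      nrow(object@cellCenters), "cell(s)\n")
})

setMethod("show", "ScaleStack", function(object) {
  d <- dim(object@values)
  cat("ScaleStack:", d[1], "x", d[2], "pixels,", d[3], "scales (r =",
      paste(signif(object@scales, 3), collapse = ", "), ")\n")
})

setMethod("show", "ExponentMap", function(object) {
  d <- dim(object@d)
  cat("ExponentMap:", d[1], "x", d[2], "pixels\n")
  cat(sprintf("  d range: [%.3f, %.3f], median R2 = %.3f\n",
              min(object@d), max(object@d),
              stats::median(object@r2)))
})

setMethod("show", "FeatureMask", function(object) {
  cat("FeatureMask:", sum(object@mask), "of", length(object@mask),
      sprintf("pixels (%.1f%%), d threshold = %.4g\n",
              100 * mean(object@mask), object@dThreshold))
})

setMethod("show", "TensorField", function(object) {
  d <- dim(object@j11)
  dets <- object@j11 * object@j22 - object@j12^2
  cat("TensorField:", d[1], "x", d[2],
      sprintf("pixels, det(J) in [%.3g, %.3g]\n", min(dets), max(dets)))
})

setMethod("show", "GradientField", function(object) {
  d <- dim(object@gx)
  cat("GradientField:", d[1], "x", d[2], "pixels\n")
})
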