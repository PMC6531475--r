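# Image I/O: TIFF (8/16-bit integer, 32-bit float) and PNG (8/16-bit).
# Internal representation is floating point scaled to [0, 1]; noisy
# intermediates may leave [0, 1] and should therefore be persisted as
# 32-bit float TIFF.

#' Read a TIFF or PNG image
#'
#' Integer inputs are scaled to `[0, 1]` by the format's nominal maximum;
#' floating-point TIFFs are passed through unscaled. Channel order is
#' preserved. The source bit depth is recorded in the `"bitDepth"`
#' attribute for round-tripping.
#'
#' @param path file path; format is inferred from the extension
#'   (`.tif`/`.tiff`/`.png`).
#' @return a [MultichannelImage-class] with attribute `bitDepth`.
#' @export
readImage <- function(path) {
  if (!file.exists(path))
    stop("file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  raw <- tryCatch(switch(ext,
      tif = , tiff = tiff::readTIFF(path, info = TRUE),
      png = png::readPNG(path, info = TRUE),
      stop("unsupported format '", ext, "' for ", path, call. = FALSE)),
    error = function(e)
      stop("failed to read ", path, ": ", conditionMessage(e),
           call. = FALSE))
  # readTIFF attaches metadata as attributes; readPNG nests it under "info"
  bits <- attr(raw, "bits.per.sample")
  if (is.null(bits)) bits <- attr(raw, "info")$bit.depth
  bits <- if (is.null(bits)) 8L else as.integer(bits[1])
  arr <- raw
  channels <- if (length(dim(arr)) == 3L) {
    nch <- dim(arr)[3]
    if (nch == 4L) {  # drop alpha
      nch <- 3L
    }
    if (!nch %in% c(1L, 3L))
      stop("unsupported channel count (", dim(arr)[3], ") in ", path,
           call. = FALSE)
    lapply(seq_len(nch), function(c) arr[, , c])
  } else {
    m <- matrix(as.numeric(arr), nrow(arr), ncol(arr))
    list(m)
  }
  img <- multichannelImage(channels)
  attr(img, "bitDepth") <- bits
  img
}

#' Write an image as TIFF or PNG
#'
#' 32-bit TIFF output stores float values exactly (including negatives);
#' 8- and 16-bit outputs clip to `[0, 1]` and quantize. PNG output is
#' 8-bit.
#'
#' @param img a [MultichannelImage-class] or numeric matrix.
#' @param path output path ending in `.tif`/`.tiff`/`.png`.
#' @param bitDepth 8, 16 or 32 (32 = float, TIFF only; PNG is 8 only).
#' @return `path`, invisibly.
#' @export
writeImage <- function(img, path, bitDepth = 32L) {
  if (is.matrix(img)) img <- multichannelImage(img)
  stopifnot(is(img, "MultichannelImage"), bitDepth %in% c(8L, 16L, 32L))
  ext <- tolower(tools::file_ext(path))
  nch <- nChannels(img)
  d <- dim(img)
  arr <- if (nch == 1L) img@channels[[1]] else {
    a <- array(0, c(d[1], d[2], nch))
    for (c in seq_len(nch)) a[, , c] <- img@channels[[c]]
    a
  }
  if (bitDepth < 32L) arr[] <- pmin(1, pmax(0, arr))
  if (ext %in% c("tif", "tiff")) {
    if (bitDepth == 32L) {
      writeFloatTIFF(arr, path)  # float sample format, preserves negatives
    } else {
      tiff::writeTIFF(arr, path, bits.per.sample = as.integer(bitDepth))
    }
  } else if (ext == "png") {
    if (bitDepth != 8L)
      stop("PNG output supports 8 bits only; use TIFF for 16/32",
           call. = FALSE)
    png::writePNG(arr, path)
  } else {
    stop("unsupported output format '", ext, "'", call. = FALSE)
  }
  invisible(path)
}

#' Serialize a PhantomSpec to a plain-text config file
#'
#' Flat `key = value` format, losslessly re-parsed by [readPhantomSpec()].
#'
#' @param spec a [PhantomSpec-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writePhantomSpec <- function(spec, path) {
  stopifnot(is(spec, "PhantomSpec"))
  slots <- slotNames(spec)
  lines <- vapply(slots, function(s)
    paste0(s, " = ", paste(format(slot(spec, s), digits = 17),
                           collapse = ",")), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname writePhantomSpec
#' @return `readPhantomSpec`: the parsed [PhantomSpec-class].
#' @export
readPhantomSpec <- function(path) {
  lines <- readLines(path)
  kv <- strsplit(lines, "\\s*=\\s*")
  vals <- stats::setNames(
    lapply(kv, function(p) as.numeric(strsplit(p[2], ",")[[1]])),
    vapply(kv, `[`, character(1), 1))
  phantomSpec(height = vals$height, width = vals$width,
              nCells = vals$nCells, nClusters = vals$nClusters,
              nSubcellularObjects = vals$nSubcellularObjects,
              cellRadiusRange = vals$cellRadiusRange,
              nucleusFraction = vals$nucleusFraction,
              particleRadiusRange = vals$particleRadiusRange,
              intensityLevels = vals$intensityLevels,
              blurSigma = vals$blurSigma, seed = vals$seed)
}
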