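# Image-quality metrics: MSE, PSNR, residual power spectral density.

#' Mean squared error between two images
#'
#' `MSE = (1 / (m n)) * sum |v - vhat|^2` over all pixels.
#'
#' @param v reference image (numeric matrix).
#' @param vhat test image, same shape.
#' @return non-negative scalar, squared-intensity units.
#' @examples
#' imageMSE(matrix(c(0, 2), 1), matrix(c(1, 1), 1))  # 1
#' @export
imageMSE <- function(v, vhat) {
  assertMatrix(v, "reference image")
  assertMatrix(vhat, "test image")
  assertSameShape(v, vhat)
  mean((v - vhat)^2)
}

#' Peak signal-to-noise ratio in decibels
#'
#' `PSNR = 20 log10( max(v) / sqrt(MSE) )`, with the peak taken from the
#' reference image `v` (not the format's nominal maximum). Identical images
#' return `Inf`.
#'
#' @param v reference image with a strictly positive peak.
#' @param vhat test image, same shape.
#' @return PSNR in dB (`Inf` when MSE = 0).
#' @examples
#' imagePSNR(matrix(c(1, 1), 1), matrix(c(1, 0.9), 1))
#' @export
imagePSNR <- function(v, vhat) {
  m <- imageMSE(v, vhat)
  peak <- max(v)
  if (peak <= 0)
    stop("reference image peak must be positive", call. = FALSE)
  if (m == 0) return(Inf)
  20 * log10(peak / sqrt(m))
}

#' Radially averaged power spectral density of the residual
#'
#' Computes the residual `dv = v - vhat`, its 2-D discrete Fourier
#' transform (unnormalized convention, so total spectral energy equals
#' `npixels * sum(dv^2)`), and averages the squared magnitudes into
#' log-spaced radial spatial-frequency bins (cycles/pixel). The DC
#' component is excluded so the mean offset does not dominate the curve.
#'
#' @param v reference image.
#' @param vhat test image, same shape.
#' @param nBins number of log-spaced frequency bins (default 32).
#' @return data.frame with columns `freq` (geometric bin centre,
#'   cycles/pixel), `psd` (mean squared Fourier magnitude in the bin; 0 for
#'   bins containing no frequencies), and `n` (frequencies per bin).
#' @export
residualPSD <- function(v, vhat, nBins = 32L) {
  assertMatrix(v, "reference image")
  assertMatrix(vhat, "test image")
  assertSameShape(v, vhat)
  stopifnot(nBins >= 2L)
  dv <- v - vhat
  nr <- nrow(dv); nc <- ncol(dv)
  power <- Mod(stats::fft(dv))^2

  fy <- ifelse(seq_len(nr) - 1L > nr %/% 2, (seq_len(nr) - 1L - nr) / nr,
               (seq_len(nr) - 1L) / nr)
  fx <- ifelse(seq_len(nc) - 1L > nc %/% 2, (seq_len(nc) - 1L - nc) / nc,
               (seq_len(nc) - 1L) / nc)
  freq <- sqrt(outer(fy^2, fx^2, "+"))

  keep <- freq > 0  # exclude DC
  f <- freq[keep]
  p <- power[keep]
  edges <- exp(seq(log(min(f)), log(max(f)), length.out = nBins + 1L))
  edges[1] <- edges[1] * (1 - 1e-12)
  edges[nBins + 1L] <- edges[nBins + 1L] * (1 + 1e-12)
  bin <- findInterval(f, edges, rightmost.closed = TRUE)
  tot <- tapply(p, factor(bin, levels = seq_len(nBins)), sum, default = 0)
  cnt <- tapply(rep(1, length(f)), factor(bin, levels = seq_len(nBins)),
                sum, default = 0)
  data.frame(freq = sqrt(edges[-1] * edges[-(nBins + 1L)]),
             psd = as.numeric(tot) / pmax(as.numeric(cnt), 1),
             n = as.numeric(cnt))
}

#' Per-channel quality report
#'
#' MSE and PSNR for each channel of a multichannel pair, plus an unweighted
#' channel average.
#'
#' @param truth reference [MultichannelImage-class] (or matrix).
#' @param test reconstruction of the same shape.
#' @return data.frame with columns `channel`, `mse`, `psnr_db`; the last
#'   row (`channel == "average"`) is the unweighted mean across channels.
#' @export
qualityReport <- function(truth, test) {
  if (is.matrix(truth)) truth <- multichannelImage(truth)
  if (is.matrix(test)) test <- multichannelImage(test)
  stopifnot(nChannels(truth) == nChannels(test))
  rows <- lapply(seq_len(nChannels(truth)), function(c) {
    v <- truth@channels[[c]]; vhat <- test@channels[[c]]
    data.frame(channel = truth@channelNames[c],
               mse = imageMSE(v, vhat),
               psnr_db = imagePSNR(v, vhat))
  })
  df <- do.call(rbind, rows)
  rbind(df, data.frame(channel = "average", mse = mean(df$mse),
                       psnr_db = mean(df$psnr_db)))
}
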