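# End-to-end simulated-data benchmark: phantom -> noise -> denoise ->
# metrics, swept over the five-level noise schedule.

#' Run the simulated-data denoising benchmark
#'
#' For each of `nDatasets` seeded phantoms and each noise level of the
#' schedule: corrupt the clean phantom with mixed Poisson-Gaussian noise,
#' denoise it, and evaluate MSE/PSNR per channel (noisy vs truth and
#' denoised vs truth) plus the residual PSD curves at the requested noise
#' levels. Fully deterministic given `seed`: phantom d uses seed
#' `seed + 1000 * d` and the noise draw for dataset d at level l uses
#' `seed + 1000 * d + l`.
#'
#' The default problem size (128x128 phantoms, 5 cells) keeps the full
#' 5-level sweep fast on one CPU; full 512x512/20-cell geometry is one argument
#' away (`height = 512, width = 512, nCells = 20`).
#'
#' @param nDatasets phantoms per noise level (default 5).
#' @param height,width,nCells,nClusters,nSubcellularObjects phantom
#'   geometry; remaining phantom parameters take their [phantomSpec()]
#'   defaults with radii scaled to the image size.
#' @param cellRadiusRange cell semi-axis range in pixels.
#' @param schedule list of [NoiseParams-class] (default the five-level
#'   schedule, [noiseLevelSchedule()]).
#' @param seed global seed.
#' @param psdLevels indices of schedule entries for which residual PSD
#'   curves are returned (default: the highest level).
#' @param psdBins log-spaced frequency bins for the PSD curves.
#' @param ... passed to [denoise()] (e.g. `msmQuantile`, `tensor`).
#' @return list with elements `trials` (one row per dataset x level x
#'   channel with noisy/denoised MSE and PSNR), `summary` (per-level means
#'   across datasets and channels), and `psd` (per requested level: noisy
#'   and denoised residual PSD data.frames for dataset 1, channel average).
#' @export
runBenchmark <- function(nDatasets = 5L, height = 128L, width = 128L,
                         nCells = 5L, nClusters = 2L,
                         nSubcellularObjects = 4L,
                         cellRadiusRange = c(10, 18),
                         schedule = noiseLevelSchedule(), seed = 1L,
                         psdLevels = length(schedule), psdBins = 24L,
                         ...) {
  trials <- list()
  psdOut <- list()
  for (d in seq_len(nDatasets)) {
    ph <- generatePhantom(phantomSpec(
      height = height, width = width, nCells = nCells,
      nClusters = nClusters, nSubcellularObjects = nSubcellularObjects,
      cellRadiusRange = cellRadiusRange, seed = seed + 1000L * d))
    truth <- phantomImage(ph)
    for (l in seq_along(schedule)) {
      par <- schedule[[l]]
      noisy <- addMixedPGNoise(truth, noiseParams(
        par@g0, par@sigma, seed = seed + 1000L * d + l))
      den <- denoise(noisy, ...)
      qN <- qualityReport(truth, noisy)
      qD <- qualityReport(truth, den)
      trials[[length(trials) + 1L]] <- data.frame(
        dataset = d, level = l, g0 = par@g0, sigma = par@sigma,
        channel = qN$channel,
        mse_noisy = qN$mse, psnr_noisy = qN$psnr_db,
        mse_denoised = qD$mse, psnr_denoised = qD$psnr_db)
      if (d == 1L && l %in% psdLevels) {
        chN <- lapply(seq_len(nChannels(truth)), function(c)
          residualPSD(getChannel(truth, c), getChannel(noisy, c), psdBins))
        chD <- lapply(seq_len(nChannels(truth)), function(c)
          residualPSD(getChannel(truth, c), getChannel(den, c), psdBins))
        avg <- function(lst) {
          out <- lst[[1]]
          out$psd <- Reduce(`+`, lapply(lst, `[[`, "psd")) / length(lst)
          out
        }
        psdOut[[as.character(l)]] <- list(noisy = avg(chN),
                                          denoised = avg(chD))
      }
    }
  }
  trials <- do.call(rbind, trials)
  perLevel <- trials[trials$channel == "average", ]
  summary <- do.call(rbind, lapply(split(perLevel, perLevel$level),
    function(s) data.frame(
      level = s$level[1], g0 = s$g0[1], sigma = s$sigma[1],
      mse_noisy = mean(s$mse_noisy), psnr_noisy = mean(s$psnr_noisy),
      mse_denoised = mean(s$mse_denoised),
      psnr_denoised = mean(s$psnr_denoised))))
  rownames(summary) <- NULL
  list(trials = trials, summary = summary, psd = psdOut)
}
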