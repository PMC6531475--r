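# MFdenoise

Multifractal feature-based denoising of fluorescence microscopy images.

Fluorescence microscopy images carry mixed Poisson–Gaussian noise: photon
shot noise scaled by the detector gain plus additive measurement noise,

    b = g0·z + ε,   z ~ Poisson(v / g0),   ε ~ N(0, σ²),

so `E[b] = v` and `Var[b] = g0·v + σ²` per pixel. MFdenoise restores such
images in two stages:

1. **Feature extraction.** A multiscale measure `μ(x, r)` is built from the
   noisy image's gradient magnitude with kernels
   `Ψ(x) = (1 + |x|²)^(-γ)`, γ = 1…4, and the per-pixel singularity
   exponent `d(x)` is the slope of the log–log regression
   `log μ(x, r) = log α(x) + d(x) log r`. The *most singular manifold*
   (MSM) — the lower-quantile set of `d(x)` — is an edge-map-like pixel
   set carrying the image's sharpest, least noise-corrupted transitions.
2. **Gradient-domain reconstruction.** The image gradients are zeroed
   outside the MSM and the denoised image solves the tensor-weighted
   discrete Poisson equation `div(J ∇v̂) = div(J ĝ)` with homogeneous
   Neumann boundary conditions, where `J` is a per-pixel symmetric
   positive-definite diffusion tensor that diffuses along, not across,
   edges.

The package is aimed at microscopists and image-analysis method developers
who need a reproducible, fully testable implementation: it includes the
noise simulator, a synthetic fluorescent-cell phantom generator with
complete ground truth, quality metrics (MSE, PSNR, radially averaged
residual power spectral density) and an end-to-end benchmark.

## Worked example

```r
library(MFdenoise)

ph    <- generatePhantom(phantomSpec(128, 128, nCells = 5, nClusters = 2,
                                     cellRadiusRange = c(10, 18), seed = 1))
truth <- phantomImage(ph)
noisy <- addMixedPGNoise(truth, noiseParams(g0 = 0.1, sigma = 0.1, seed = 2))
clean <- denoise(noisy)

qualityReport(truth, noisy)
#>     channel        mse  psnr_db
#> 1 cytoplasm 0.01454360 13.89018
#> 2   nucleus 0.01133098 17.28344
#> 3 particles 0.01210982 19.15496
#> 4   average 0.01266146 16.77620
qualityReport(truth, clean)
#>     channel         mse  psnr_db
#> 1 cytoplasm 0.011558821 14.88777
#> 2   nucleus 0.009344175 18.12071
#> 3 particles 0.009647058 20.14239
#> 4   average 0.010183351 17.71695
```

At this high-noise setting (`g0 = σ = 0.1`) the reconstruction lowers the
MSE of every channel and gains ~0.9 dB PSNR on the channel average; the
high-frequency half of the residual power spectrum drops below the noisy
input's (`residualPSD()`). PSNR is reported as
`20·log10(max(v) / sqrt(MSE))` with the peak taken from the reference
image. The five-level benchmark sweep (`runBenchmark()`) covers
`g0 = σ ∈ {1e-3, 1e-2.5, 1e-2, 1e-1.5, 1e-1}`; see the methods vignette
(`vignettes/multifractal-denoising.Rmd`) for the model, parameter
defaults, and a discussion of the reconstruction error floor at low noise
levels.

A thin command-line front end with subcommands (`simulate-phantom`,
`add-noise`, `exponents`, `msm`, `denoise`, `evaluate`, `benchmark`)
lives at `inst/scripts/mfdenoise.R`.

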