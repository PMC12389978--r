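# csmri — compressed-sensing MRI reconstruction benchmarking

`csmri` is an R toolkit for studying how much a grayscale MR image can be
undersampled and still reconstructed, and by which method. MRI acquisition is
slow because it samples k-space densely; compressed sensing (CS) promises
recovery from a fraction of those samples whenever the image is sparse in
some transform domain. This package implements four reconstruction pipelines
over a shared quality-metric and benchmarking framework, for researchers and
students comparing sparsifying transforms and L1 recovery under controlled
undersampling:

| pipeline | scheme | acquisition model |
|---|---|---|
| `run_dwt_pipeline()` | zero-filled level-1 Haar wavelet, random mask | simulation-only |
| `run_fft_pipeline()` | zero-filled 2-D FFT, random mask | measurement-model-consistent |
| `run_dct_pipeline()` | top-magnitude 2-D DCT retention | simulation-only |
| `run_bp_pipeline()`  | basis pursuit from Gaussian measurements | measurement-model-consistent |

At its core is an equality-constrained L1 minimizer (basis pursuit),

```
min ||s||_1   subject to   Theta s = y,     Theta = Phi Psi^{-1},
```

solved by a primal–dual interior-point method (`solve_bp()`; surrogate
duality-gap tolerance 1e-6, at most 26 iterations, barrier update mu = 10),
where `Phi` is an m×n Gaussian random sensing matrix and `Psi^{-1}` the
orthogonal inverse-DCT dictionary. An independent linear-programming oracle
(`bp_lp_oracle()`, simplex on the nonnegative-split formulation) cross-checks
the solver in the test suite.

Quality metrics follow the standard definitions: MSE, RMSE = sqrt(MSE),
PSNR = 10·log10(peak²/MSE) dB, mean SSIM (11×11 Gaussian window, sigma 1.5; a
global-window mode for hand-checkable values), compression efficiency
`||retained coefficients|| / ||signal||`, and data loss
`100·||x − x1|| / ||x||` %. Everything runs on synthetic inputs generated in
code — a Shepp-Logan-style head phantom, exactly-K-sparse images and vectors
— and a minimal DICOM reader/writer handles single-frame grayscale files.

## Worked example

```r
library(csmri)

img <- shepp_logan_phantom(64)          # 64x64 phantom in [0, 1]
res <- run_dct_pipeline(img, rate = 0.5)
tidy(res)
#> # A tibble: 1 × 13
#>   algorithm label            rate  seed status  time_s memory_gb
#>   <chr>     <chr>           <dbl> <int> <chr>    <dbl>     <dbl>
#> 1 dct       simulation-only   0.5    NA ok     0.00300    0.0834
#>   compression_efficiency    rmse psnr_db  ssim       mse data_loss_pct
#>                    <dbl>   <dbl>   <dbl> <dbl>     <dbl>         <dbl>
#> 1                  0.999 0.00935    40.6 0.976 0.0000874          3.78
```

Keeping the largest half of the DCT coefficients retains 99.9% of the
phantom's energy (compression efficiency 0.999), so the reconstruction is
near-perfect: 40.6 dB PSNR, SSIM 0.976, and only 3.8% of the signal energy
lost. The same image through the full compressed-sensing chain at the same
rate:

```r
bp <- run_bp_pipeline(img, rate = 0.5, seed = 1, size = 64)
glance(bp$solution)
#> # A tibble: 1 × 5
#>   objective duality_gap feasibility_residual iterations status
#>       <dbl>       <dbl>                <dbl>      <int> <chr>
#> 1      369.    0.000317             1.61e-11         26 max_iter
sprintf("BP PSNR: %.2f dB, data loss: %.1f%%", bp$report$psnr_db,
        bp$report$data_loss_pct)
#> "BP PSNR: 17.77 dB, data loss: 52.2%"
```

Basis pursuit reconstructs from m = 2048 random measurements of the
4096-pixel image (not from transform coefficients it could never observe):
it reaches 17.8 dB at the 26-iteration cap, staying on the measurement
manifold to 1.6e-11. Rate sweeps over all four pipelines tabulate and plot
this comparison:

```r
tab <- cs_sweep(img, rates = c(0.35, 0.5, 0.7), bp_size = 64)
autoplot(tab, metric = "psnr_db")
write_report(tab, "sweep_out")   # raw CSV + normalized curves + summary
```

A thin CLI wraps the same functions:

```sh
Rscript inst/scripts/csmri.R phantom --size 256 --out phantom.dcm
Rscript inst/scripts/csmri.R run --input phantom.dcm --algorithm all --rate 0.5 --seed 1 --out out/
Rscript inst/scripts/csmri.R sweep --input phantom --rates 0.35:0.75:0.05 --seed 1 --out out/
```

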