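Package: csmri
Title: Compressed-Sensing MRI Reconstruction Benchmarking Toolkit
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Sparse-transform and compressed-sensing reconstruction of
    undersampled grayscale magnetic-resonance images, with a full quality-metric
    and benchmarking framework. Implements four reconstruction pipelines --
    zero-filled level-1 Haar wavelet and 2-D FFT reconstructions under random
    coefficient subsampling, top-magnitude 2-D DCT retention, and basis-pursuit
    recovery (equality-constrained L1 minimization via a primal-dual
    interior-point solver) from Gaussian random measurements in a DCT
    dictionary. Includes PSNR, SSIM, RMSE, compression-efficiency and data-loss
    metrics, sampling-rate sweep benchmarking with tidy tabular output, a
    Shepp-Logan-style phantom generator, exactly-sparse test-signal generators,
    and a minimal single-frame grayscale DICOM reader/writer for fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    boot,
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    withr,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
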