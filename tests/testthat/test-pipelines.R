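test_that("zero-filled pipelines reconstruct exactly at full sampling", {
  img <- test_phantom(32)
  for (res in list(run_dwt_pipeline(img, 1.0, seed = 1),
                   run_fft_pipeline(img, 1.0, seed = 1),
                   run_dct_pipeline(img, 1.0))) {
    expect_lt(max(abs(res$reconstruction - img)), 1e-10)
    expect_equal(res$report$data_loss_pct, 0, tolerance = 1e-8)
  }
})

test_that("pipeline reports are deterministic given (image, rate, seed)", {
  img <- test_phantom(32)
  a <- tidy(run_dwt_pipeline(img, 0.5, seed = 3))
  b <- tidy(run_dwt_pipeline(img, 0.5, seed = 3))
  cols <- setdiff(names(a), c("time_s", "memory_gb"))
  expect_identical(a[cols], b[cols])

  f1 <- run_fft_pipeline(img, 0.4, seed = 9)
  f2 <- run_fft_pipeline(img, 0.4, seed = 9)
  expect_identical(f1$reconstruction, f2$reconstruction)
})

test_that("the wavelet pipeline retains the rounded coefficient count", {
  img <- test_phantom(32)
  res <- run_dwt_pipeline(img, 0.5, seed = 2)
  M <- length(haar_dwt2(img)$coeffs)
  plan <- random_coefficient_mask(M, 0.5, seed = 2)
  expect_length(plan$indices, round(0.5 * M))
  # pipeline's retained energy matches the plan's coefficients
  expect_equal(res$report$compression_efficiency,
               sqrt(sum(haar_dwt2(img)$coeffs[plan$indices]^2) / sum(img^2)),
               tolerance = 1e-12)
})

test_that("zero images propagate to zero reconstructions in the FFT pipeline", {
  z <- matrix(0, 16, 16)
  expect_warning(res <- run_fft_pipeline(z, 0.5, seed = 1), "zero-norm")
  expect_equal(res$reconstruction, z)
  expect_true(is.na(res$report$data_loss_pct))
})

test_that("DCT-pipeline RMSE is non-increasing in the sampling rate", {
  img <- test_phantom(48)
  rates <- seq(0.05, 1, by = 0.05)
  errs <- vapply(rates, function(r) run_dct_pipeline(img, r)$report$rmse,
                 numeric(1))
  expect_true(all(diff(errs) <= 1e-12))
})

test_that("exactly sparse images reconstruct exactly once all energy is kept", {
  img <- sparse_dct_image(16, K = 10, seed = 5)
  res <- run_dct_pipeline(img, rate = 10 / 256, ssim_window = "global")
  expect_lt(res$report$rmse, 1e-10)
})

test_that("basis pursuit recovers DCT-sparse images in the exact regime", {
  # image exactly 8-sparse in the 1-D DCT of its vectorization, measured at
  # rate 0.35 (m = round(1024 * 0.35) = 358 >> 4K): exact-recovery regime
  img <- sparse_dct_image(32, K = 8, seed = 7, domain = "1d")
  x <- as.vector(img)
  n <- length(x)
  Phi <- gaussian_sensing_matrix(358, n, seed = 8, perturb = FALSE)
  y <- measure_signal(Phi, x)
  Theta <- Phi %*% idct_dictionary(n)
  sol <- suppressWarnings(solve_bp(Theta, y))
  x_rec <- drop(idct_dictionary(n) %*% sol$s)
  expect_lt(sqrt(sum((x_rec - x)^2)) / sqrt(sum(x^2)), 1e-3)
})

test_that("BP pipeline reconstructs exactly at full sampling", {
  img <- test_phantom(32)
  res <- suppressWarnings(run_bp_pipeline(img, 1.0, seed = 1, size = 16,
                                          ssim_window = "global"))
  expect_lt(max(abs(res$reconstruction - res$reference)), 1e-8)
  expect_equal(res$report$data_loss_pct, 0, tolerance = 1e-6)
})

test_that("severe undersampling of a dense image degrades BP gracefully", {
  img <- test_phantom(64)
  res <- suppressWarnings(run_bp_pipeline(img, 0.1, seed = 2, size = 16,
                                          ssim_window = "global"))
  # m = 26 measurements cannot carry a dense 256-pixel image
  expect_gt(res$report$data_loss_pct, 10)
})

test_that("BP metric fields satisfy the metric-module identities", {
  img <- test_phantom(32)
  res <- suppressWarnings(run_bp_pipeline(img, 0.5, seed = 3, size = 16,
                                          ssim_window = "global"))
  rep <- res$report
  expect_equal(rep$rmse^2, rep$mse, tolerance = 1e-14)
  expect_equal(rep$psnr_db, -20 * log10(rep$rmse), tolerance = 1e-9)
  expect_equal(rep$data_loss_pct, data_loss(res$reference, res$reconstruction),
               tolerance = 1e-10)
  expect_equal(rep$compression_efficiency,
               sqrt(sum(res$measurements^2) / sum(res$reference^2)),
               tolerance = 1e-12)
})

test_that("pipeline results carry their acquisition-model labels", {
  img <- test_phantom(32)
  expect_equal(run_dwt_pipeline(img, 0.5, 1)$label, "simulation-only")
  expect_equal(run_dct_pipeline(img, 0.5)$label, "simulation-only")
  expect_equal(run_fft_pipeline(img, 0.5, 1)$label,
               "measurement-model-consistent")
})
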