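# End-to-end reconstruction pipelines.  Each takes a grayscale image in
# [0, 1], undersamples it in a transform domain at the requested rate,
# reconstructs, and reports the full metric row.
#
# The wavelet and DCT pipelines subsample transform coefficients directly and
# are labelled "simulation-only": they do not model k-space acquisition and
# serve as sparsity benchmarks.  The FFT and basis-pursuit pipelines are
# labelled "measurement-model-consistent" (Fourier samples / random linear
# measurements).

new_cs_result <- function(algorithm, rate, seed, reconstruction, reference,
                          report, label, status = "ok", extra = list()) {
  structure(
    c(list(algorithm = algorithm, rate = rate, seed = seed,
           reconstruction = reconstruction, reference = reference,
           report = report, label = label, status = status), extra),
    class = "cs_result"
  )
}

#' @export
print.cs_result <- function(x, ...) {
  cat(sprintf("<cs_result> %s (%s) rate=%.2f status=%s\n",
              x$algorithm, x$label, x$rate, x$status))
  print(x$report)
  invisible(x)
}

#' @rdname run_dwt_pipeline
#' @param x A `cs_result` object.
#' @param ... Unused.
#' @method tidy cs_result
#' @export
tidy.cs_result <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(algorithm = x$algorithm, label = x$label, rate = x$rate,
                   seed = x$seed, status = x$status),
    x$report
  )
}

#' @rdname run_dwt_pipeline
#' @method glance cs_result
#' @export
glance.cs_result <- function(x, ...) tidy(x, ...)

#' @rdname run_dwt_pipeline
#' @param object A `cs_result` object.
#' @method autoplot cs_result
#' @export
autoplot.cs_result <- function(object, ...) {
  to_df <- function(img, panel) {
    tibble::tibble(
      row = rep(seq_len(nrow(img)), times = ncol(img)),
      col = rep(seq_len(ncol(img)), each = nrow(img)),
      intensity = as.vector(img),
      panel = panel
    )
  }
  df <- dplyr::bind_rows(to_df(object$reference, "reference"),
                         to_df(object$reconstruction, "reconstruction"))
  ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row, fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient(low = "black", high = "white", limits = c(0, 1),
                                 oob = scales_squish) +
    ggplot2::facet_wrap(~panel) +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = sprintf("%s reconstruction, rate %.2f",
                                  toupper(object$algorithm), object$rate),
                  x = NULL, y = NULL)
}

# clamp out-of-range fill values instead of dropping them
scales_squish <- function(x, range = c(0, 1)) {
  pmin(pmax(x, range[1]), range[2])
}

#' Zero-filled wavelet reconstruction pipeline
#'
#' Level-1 Haar decomposition, uniform random retention of
#' `round(rate * M)` coefficients, zero-filling, synthesis, and metrics
#' against the original image. A transform-domain simulation benchmark, not a
#' physical acquisition model.
#'
#' @param img Grayscale image matrix in \[0, 1\].
#' @param rate Sampling rate in (0, 1\].
#' @param seed Integer RNG seed for the random mask.
#' @param ssim_window SSIM window mode (see [ssim()]).
#' @return A `cs_result` object; `tidy()` it for the metric row.
#' @export
run_dwt_pipeline <- function(img, rate, seed, ssim_window = "gaussian") {
  assert_image(img)
  probe <- resource_probe(function() {
    dec <- haar_dwt2(img)
    plan <- random_coefficient_mask(length(dec$coeffs), rate, seed)
    sampled <- dec$coeffs[plan$indices]
    dec$coeffs <- zero_fill(dec$coeffs, plan)
    list(recon = haar_idwt2(dec), sampled = sampled, plan = plan)
  })
  report <- metrics_report(img, probe$result$recon, probe$result$sampled,
                           time_s = probe$time_s, memory_gb = probe$memory_gb,
                           ssim_window = ssim_window)
  new_cs_result("dwt", rate, seed, probe$result$recon, img, report,
                label = "simulation-only")
}

#' Zero-filled FFT reconstruction pipeline
#'
#' 2-D DFT, uniform random retention of `round(rate * M)` frequency
#' coefficients, zero-filling, inverse DFT taking the real part, and metrics
#' against the original image. Consistent with the Fourier measurement model
#' of MRI acquisition.
#'
#' @inheritParams run_dwt_pipeline
#' @return A `cs_result` object.
#' @export
run_fft_pipeline <- function(img, rate, seed, ssim_window = "gaussian") {
  assert_image(img)
  probe <- resource_probe(function() {
    coeffs <- fft2(img)
    plan <- random_coefficient_mask(length(coeffs), rate, seed)
    sampled <- as.vector(coeffs)[plan$indices]
    filled <- zero_fill(as.vector(coeffs), plan)
    recon <- ifft2(matrix(filled, nrow(img), ncol(img)), take_real = TRUE)
    list(recon = recon, sampled = sampled)
  })
  report <- metrics_report(img, probe$result$recon, probe$result$sampled,
                           time_s = probe$time_s, memory_gb = probe$memory_gb,
                           ssim_window = ssim_window)
  new_cs_result("fft", rate, seed, probe$result$recon, img, report,
                label = "measurement-model-consistent")
}

#' Top-magnitude DCT reconstruction pipeline
#'
#' 2-D DCT, retention of the `floor(rate * M)` largest-magnitude
#' coefficients, inverse DCT, and metrics against the original image. Fully
#' deterministic. A transform-domain simulation benchmark exploiting the
#' DCT's energy compaction, not a physical acquisition model.
#'
#' @inheritParams run_dwt_pipeline
#' @return A `cs_result` object (its `seed` field is `NA`).
#' @export
run_dct_pipeline <- function(img, rate, ssim_window = "gaussian") {
  assert_image(img)
  probe <- resource_probe(function() {
    coeffs <- dct2(img)
    plan <- top_magnitude_mask(as.vector(coeffs), rate)
    sampled <- as.vector(coeffs)[plan$indices]
    filled <- zero_fill(as.vector(coeffs), plan)
    recon <- idct2(matrix(filled, nrow(img), ncol(img)))
    list(recon = recon, sampled = sampled)
  })
  report <- metrics_report(img, probe$result$recon, probe$result$sampled,
                           time_s = probe$time_s, memory_gb = probe$memory_gb,
                           ssim_window = ssim_window)
  new_cs_result("dct", rate, NA_integer_, probe$result$recon, img, report,
                label = "simulation-only")
}

#' Basis-pursuit compressed-sensing reconstruction pipeline
#'
#' The full compressed-sensing chain: the image is resized to
#' `size x size`, floor-thresholded at `floor_t`, min-max normalized and
#' vectorized; `m = round(n * rate)` Gaussian random measurements
#' `y = Phi x` are taken; the sparse DCT representation is recovered by
#' equality-constrained L1 minimization over the dictionary
#' `Theta = Phi %*% idct_dictionary(n)`; the reconstruction is the inverse
#' DCT of the recovered coefficients, reshaped and floor-thresholded again.
#' Metrics compare the reconstruction against the pre-measurement image (the
#' signal that was actually measured). Solver failures are recorded in the
#' result's `status`, never thrown.
#'
#' @inheritParams run_dwt_pipeline
#' @param size Side length the image is resized to before measurement.
#' @param floor_t Intensity floor applied before measurement and after
#'   reconstruction.
#' @param tol,max_iter Solver settings passed to [solve_bp()].
#' @return A `cs_result` object with extra fields `solution` (the
#'   `bp_solution`) and `measurements` (`y`).
#' @export
run_bp_pipeline <- function(img, rate, seed, size = 128, floor_t = 0.1,
                            tol = 1e-6, max_iter = 26, ssim_window = "gaussian") {
  assert_image(img)
  stopifnot(rate > 0, rate <= 1)
  probe <- resource_probe(function() {
    A <- resize_image(img, c(size, size))
    A <- threshold_floor(A, floor_t)
    A <- normalize_minmax(A)
    x <- as.vector(A)
    n <- length(x)
    m <- as.integer(round_half_away(n * rate))
    Phi <- gaussian_sensing_matrix(m, n, seed)
    y <- measure_signal(Phi, x)
    Theta <- Phi %*% idct_dictionary(n)
    sol <- suppressWarnings(solve_bp(Theta, y, tol = tol, max_iter = max_iter))
    recon <- matrix(idct1(sol$s), size, size)
    recon <- threshold_floor(recon, floor_t)
    list(reference = A, recon = recon, y = y, sol = sol)
  })
  res <- probe$result
  report <- metrics_report(res$reference, res$recon, res$y,
                           time_s = probe$time_s, memory_gb = probe$memory_gb,
                           ssim_window = ssim_window)
  new_cs_result("bp", rate, seed, res$recon, res$reference, report,
                label = "measurement-model-consistent",
                status = res$sol$status,
                extra = list(solution = res$sol, measurements = res$y))
}
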