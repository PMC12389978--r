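# Reconstruction quality and efficiency metrics.

#' Mean squared error between two images
#'
#' @param x,x1 Numeric matrices of identical shape (reference, reconstruction).
#' @return Mean of squared pixel differences.
#' @export
mse <- function(x, x1) {
  assert_same_shape(x, x1)
  mean((x - x1)^2)
}

#' Root mean squared error between two images
#'
#' @inheritParams mse
#' @return `sqrt(mse(x, x1))`, in intensity units.
#' @export
rmse <- function(x, x1) {
  sqrt(mse(x, x1))
}

#' Peak signal-to-noise ratio
#'
#' `10 * log10(peak^2 / MSE)` in decibels. Identical images have infinite
#' PSNR; the `Inf` sentinel is returned explicitly (and serialized as "inf"
#' in reports).
#'
#' @inheritParams mse
#' @param peak Maximum possible pixel value; 1 for unit-normalized images.
#' @return PSNR in dB.
#' @export
psnr <- function(x, x1, peak = 1) {
  stopifnot(peak > 0)
  m <- mse(x, x1)
  if (m == 0) return(Inf)
  10 * log10(peak^2 / m)
}

#' Structural similarity index
#'
#' Mean structural similarity between two images, comparing local luminance,
#' contrast and structure with stabilizing constants `C1 = (K1 L)^2`,
#' `C2 = (K2 L)^2`. Two window modes are available:
#'
#' * `"gaussian"` (default): 11 x 11 Gaussian window, sigma = 1.5, unit
#'   exponents, valid-region convolution — the classic mean-SSIM estimator.
#' * `"global"`: one uniform window spanning the whole image with population
#'   moments, which makes small examples hand-checkable.
#'
#' @inheritParams mse
#' @param K1,K2 Stability parameters (standard values 0.01 and 0.03).
#' @param L Dynamic range of the pixel values (1 for unit-normalized images).
#' @param window `"gaussian"` or `"global"`.
#' @return SSIM value in \[-1, 1\]; 1 for identical images.
#' @export
ssim <- function(x, x1, K1 = 0.01, K2 = 0.03, L = 1, window = c("gaussian", "global")) {
  assert_same_shape(x, x1)
  stopifnot(L > 0)
  window <- match.arg(window)
  C1 <- (K1 * L)^2
  C2 <- (K2 * L)^2
  if (window == "global") {
    mux <- mean(x); muy <- mean(x1)
    vx <- mean((x - mux)^2); vy <- mean((x1 - muy)^2)
    cxy <- mean((x - mux) * (x1 - muy))
    return(((2 * mux * muy + C1) * (2 * cxy + C2)) /
             ((mux^2 + muy^2 + C1) * (vx + vy + C2)))
  }
  win <- 11L
  if (nrow(x) < win || ncol(x) < win) {
    stop("image smaller than the ", win, "x", win,
         " SSIM window; use window = \"global\"", call. = FALSE)
  }
  g <- exp(-((seq_len(win) - (win + 1) / 2)^2) / (2 * 1.5^2))
  g <- g / sum(g)
  filt <- function(z) gaussian_valid_filter(z, g)
  mux <- filt(x); muy <- filt(x1)
  sxx <- filt(x * x) - mux^2
  syy <- filt(x1 * x1) - muy^2
  sxy <- filt(x * x1) - mux * muy
  smap <- ((2 * mux * muy + C1) * (2 * sxy + C2)) /
    ((mux^2 + muy^2 + C1) * (sxx + syy + C2))
  mean(smap)
}

# Separable valid-region correlation with a 1-D kernel g along both axes.
gaussian_valid_filter <- function(z, g) {
  k <- length(g)
  nr <- nrow(z) - k + 1L
  nc <- ncol(z) - k + 1L
  rowpass <- matrix(0, nr, ncol(z))
  for (i in seq_len(k)) {
    rowpass <- rowpass + g[i] * z[i:(i + nr - 1L), , drop = FALSE]
  }
  out <- matrix(0, nr, nc)
  for (j in seq_len(k)) {
    out <- out + g[j] * rowpass[, j:(j + nc - 1L), drop = FALSE]
  }
  out
}

#' Compression efficiency of a retained coefficient set
#'
#' The ratio `||sampled||_2 / ||x||_2` between the energy of the retained
#' (sampled) transform coefficients and the energy of the original signal.
#' For an orthonormal transform with every coefficient retained the ratio is
#' exactly 1. Complex coefficients (FFT case) enter through their modulus.
#'
#' @param sampled Retained coefficient vector (real or complex).
#' @param original Original image matrix or signal vector.
#' @return Dimensionless ratio >= 0.
#' @export
compression_efficiency <- function(sampled, original) {
  denom <- l2norm(original)
  if (denom == 0) stop("original signal has zero norm", call. = FALSE)
  l2norm(sampled) / denom
}

#' Relative data loss in percent
#'
#' `100 * ||x - x1||_2 / ||x||_2`: the relative L2 reconstruction error, an
#' intuitive measure of how much signal energy the compression/reconstruction
#' chain discarded.
#'
#' @inheritParams mse
#' @return Percentage >= 0 (0 for perfect reconstruction, 100 when `x1 = 0`).
#' @export
data_loss <- function(x, x1) {
  assert_same_shape(x, x1)
  denom <- l2norm(x)
  if (denom == 0) stop("reference image has zero norm", call. = FALSE)
  100 * l2norm(x - x1) / denom
}

#' Time and peak-memory probe for a unit of work
#'
#' Runs `task` and reports wall-clock seconds together with the process's
#' peak resident set size in gigabytes (from `/proc/self/status` VmHWM where
#' available, `NA` elsewhere). Informational only: absolute resource numbers
#' are hardware-bound and never asserted against.
#'
#' @param task A function of no arguments.
#' @return List with `result` (the task's value), `time_s` and `memory_gb`.
#' @export
resource_probe <- function(task) {
  stopifnot(is.function(task))
  t0 <- proc.time()[["elapsed"]]
  result <- task()
  elapsed <- proc.time()[["elapsed"]] - t0
  list(result = result, time_s = elapsed, memory_gb = peak_memory_gb())
}

peak_memory_gb <- function() {
  status <- "/proc/self/status"
  if (!file.exists(status)) return(NA_real_)
  lines <- tryCatch(readLines(status), error = function(e) character())
  hwm <- grep("^VmHWM:", lines, value = TRUE)
  if (length(hwm) != 1L) return(NA_real_)
  kb <- suppressWarnings(as.numeric(gsub("[^0-9]", "", hwm)))
  if (is.na(kb)) NA_real_ else kb / 1024^2
}

#' Assemble a metrics report row
#'
#' One tidy row with every quality/efficiency metric comparing a
#' reconstruction against its reference, in the standard benchmarking column
#' order: time, memory, compression efficiency, then error metrics.
#'
#' @param x Reference image.
#' @param x1 Reconstructed image.
#' @param sampled Retained coefficient (or measurement) vector used for the
#'   compression-efficiency ratio.
#' @param time_s,memory_gb Optional resource figures for the run.
#' @param ssim_window Window mode passed to [ssim()].
#' @return A one-row tibble with columns `time_s`, `memory_gb`,
#'   `compression_efficiency`, `rmse`, `psnr_db`, `ssim`, `mse`,
#'   `data_loss_pct`.
#' @export
metrics_report <- function(x, x1, sampled, time_s = NA_real_,
                           memory_gb = NA_real_, ssim_window = "gaussian") {
  m <- mse(x, x1)
  degenerate <- l2norm(x) == 0   # ratio metrics are undefined for a zero image
  if (degenerate) {
    warning("zero-norm reference image: ratio metrics reported as NA",
            call. = FALSE)
  }
  tibble::tibble(
    time_s = time_s,
    memory_gb = memory_gb,
    compression_efficiency =
      if (degenerate) NA_real_ else compression_efficiency(sampled, x),
    rmse = sqrt(m),
    psnr_db = psnr(x, x1),
    ssim = ssim(x, x1, window = ssim_window),
    mse = m,
    data_loss_pct = if (degenerate) NA_real_ else data_loss(x, x1)
  )
}
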