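# Coefficient selection, zero-filling and Gaussian sensing.

new_sampling_plan <- function(mode, rate, seed, indices, total) {
  structure(
    list(mode = mode, rate = rate, seed = seed,
         indices = as.integer(indices), total = as.integer(total)),
    class = "sampling_plan"
  )
}

#' @export
print.sampling_plan <- function(x, ...) {
  cat(sprintf("<sampling_plan> mode=%s rate=%.3f kept=%d of %d\n",
              x$mode, x$rate, length(x$indices), x$total))
  invisible(x)
}

#' Uniform random coefficient mask
#'
#' Selects `round(rate * M)` distinct coefficient positions uniformly at
#' random (half-away-from-zero rounding, the convention of the zero-filled
#' wavelet/FFT pipelines). Reproducible: the same `(M, rate, seed)` always
#' yields the same mask, and the caller's RNG state is untouched.
#'
#' @param M Total number of coefficients.
#' @param rate Sampling rate in (0, 1\].
#' @param seed Integer RNG seed.
#' @return A `sampling_plan` object.
#' @export
random_coefficient_mask <- function(M, rate, seed) {
  stopifnot(M >= 1, rate > 0, rate <= 1)
  n_keep <- as.integer(round_half_away(M * rate))
  if (n_keep < 1L) stop("sampling rate ", rate, " retains no coefficients", call. = FALSE)
  idx <- with_seed(seed, sample.int(M, n_keep))
  new_sampling_plan("random", rate, seed, sort(idx), M)
}

#' Top-magnitude coefficient mask
#'
#' Retains the `floor(rate * M)` largest-magnitude coefficients (the
#' convention of the DCT top-N pipeline). Fully deterministic; ties in
#' magnitude are broken by the lower position first.
#'
#' @param coeffs Numeric (or complex) coefficient vector.
#' @param rate Sampling rate in (0, 1\].
#' @return A `sampling_plan` object.
#' @export
top_magnitude_mask <- function(coeffs, rate) {
  stopifnot(rate > 0, rate <= 1)
  M <- length(coeffs)
  n_keep <- as.integer(floor(rate * M))
  if (n_keep < 1L) stop("sampling rate ", rate, " retains no coefficients", call. = FALSE)
  ord <- order(-abs(coeffs), seq_len(M), method = "radix")
  new_sampling_plan("top_magnitude", rate, NA_integer_, sort(ord[seq_len(n_keep)]), M)
}

#' Zero-fill a coefficient vector
#'
#' Copies the retained positions of `coeffs` and sets every other entry
#' exactly to zero — the reconstruction-side counterpart of undersampling.
#' Idempotent for a fixed plan.
#'
#' @param coeffs Coefficient vector of length `plan$total`.
#' @param plan A `sampling_plan`.
#' @return Vector of the same length and type with dropped entries zeroed.
#' @export
zero_fill <- function(coeffs, plan) {
  stopifnot(inherits(plan, "sampling_plan"))
  if (length(coeffs) != plan$total) {
    stop("coefficient vector length (", length(coeffs),
         ") does not match plan total (", plan$total, ")", call. = FALSE)
  }
  out <- coeffs
  out[] <- 0
  out[plan$indices] <- coeffs[plan$indices]
  out
}

#' Gaussian random sensing matrix
#'
#' i.i.d. normal entries scaled by `1/m` (as the basis-pursuit pipeline
#' specifies; `scale = "1/sqrt(m)"` gives the conventional compressed-sensing
#' normalization instead), optionally with `1e-6` added to the leading
#' diagonal block for numerical conditioning.
#'
#' @param m Number of measurements (rows), `1 <= m <= n`.
#' @param n Signal length (columns).
#' @param seed Integer RNG seed.
#' @param scale Either `"1/m"` (default) or `"1/sqrt(m)"`.
#' @param perturb Add the `1e-6` leading-diagonal perturbation (default TRUE).
#' @return m x n numeric matrix.
#' @export
gaussian_sensing_matrix <- function(m, n, seed, scale = c("1/m", "1/sqrt(m)"),
                                    perturb = TRUE) {
  scale <- match.arg(scale)
  stopifnot(m >= 1, n >= 1)
  if (m > n) {
    warning("m > n: system is overdetermined, not a compressed-sensing regime",
            call. = FALSE)
  }
  denom <- if (scale == "1/m") m else sqrt(m)
  Phi <- with_seed(seed, matrix(stats::rnorm(m * n), m, n)) / denom
  if (perturb) Phi <- add_diag_perturbation(Phi)
  Phi
}

# eye(size(Phi)) * 1e-6 for a wide matrix: perturb the leading m x m block.
add_diag_perturbation <- function(Phi, eps = 1e-6) {
  d <- seq_len(min(dim(Phi)))
  Phi[cbind(d, d)] <- Phi[cbind(d, d)] + eps
  Phi
}

#' Measure a signal through a sensing matrix
#'
#' The exact matrix-vector product `y = Phi x`.
#'
#' @param Phi m x n sensing matrix.
#' @param x Signal vector of length n.
#' @return Measurement vector of length m.
#' @export
measure_signal <- function(Phi, x) {
  if (ncol(Phi) != length(x)) {
    stop("ncol(Phi) = ", ncol(Phi), " does not match length(x) = ",
         length(x), call. = FALSE)
  }
  drop(Phi %*% x)
}
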