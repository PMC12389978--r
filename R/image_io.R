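#' Min-max normalize an image to the unit intensity range
#'
#' Affinely rescales a grayscale image so that its minimum maps to 0 and its
#' maximum to 1, the standard pre-processing step applied before every
#' reconstruction pipeline. A constant image has no dynamic range; it is
#' returned as all zeros with a warning rather than dividing by zero, so that
#' pipelines stay total on pathological inputs.
#'
#' @param img Numeric matrix of finite intensities.
#' @return A matrix of the same shape with values in \[0, 1\] (all zeros for a
#'   constant input).
#' @examples
#' normalize_minmax(matrix(c(0, 2, 4, 8), 2))
#' @export
normalize_minmax <- function(img) {
  assert_image(img)
  lo <- min(img)
  hi <- max(img)
  if (hi == lo) {
    warning("constant image: min-max normalization is degenerate, returning zeros",
            call. = FALSE)
    return(array(0, dim(img)))
  }
  (img - lo) / (hi - lo)
}

#' Set intensities below a floor to zero
#'
#' Applies the hard floor used by the basis-pursuit pipeline before
#' measurement: every pixel strictly below `t` becomes 0, pixels at or above
#' `t` are untouched.
#'
#' @param img Numeric matrix.
#' @param t Non-negative threshold.
#' @return Thresholded matrix of the same shape.
#' @export
threshold_floor <- function(img, t = 0.1) {
  assert_image(img)
  stopifnot(is.numeric(t), length(t) == 1L, t >= 0)
  img[img < t] <- 0
  img
}

#' Resize a grayscale image with bicubic interpolation
#'
#' Separable bicubic resampling (Keys kernel, a = -0.5) with antialiasing when
#' downscaling: the kernel is stretched by the scale factor so that it acts as
#' a low-pass filter, matching the behaviour of the usual image-resize default
#' in scientific imaging toolboxes. Boundary samples are replicated and the
#' result is clipped to \[0, 1\] because cubic kernels can overshoot.
#'
#' @param img Numeric matrix with values in \[0, 1\].
#' @param out_shape Integer vector `c(rows, cols)`, both positive.
#' @param antialias Apply the antialiasing kernel stretch when downscaling
#'   (default `TRUE`).
#' @return Matrix of dimension `out_shape`.
#' @export
resize_image <- function(img, out_shape, antialias = TRUE) {
  assert_image(img)
  out_shape <- as.integer(out_shape)
  if (length(out_shape) != 2L || any(out_shape < 1L)) {
    stop("`out_shape` must be two positive integers", call. = FALSE)
  }
  wr <- resample_weights(nrow(img), out_shape[1], antialias)
  wc <- resample_weights(ncol(img), out_shape[2], antialias)
  out <- wr %*% img %*% t(wc)
  out[out < 0] <- 0
  out[out > 1] <- 1
  out
}

# Keys bicubic kernel, a = -0.5.
cubic_kernel <- function(x) {
  ax <- abs(x)
  ifelse(ax <= 1, 1.5 * ax^3 - 2.5 * ax^2 + 1,
         ifelse(ax < 2, -0.5 * ax^3 + 2.5 * ax^2 - 4 * ax + 2, 0))
}

# Dense out x in interpolation-weight matrix for one dimension.  When
# downscaling with antialiasing the kernel is dilated by 1/scale so its
# footprint covers 4/scale source samples.
resample_weights <- function(n_in, n_out, antialias = TRUE) {
  scale <- n_out / n_in
  kscale <- if (antialias && scale < 1) scale else 1
  # centers of output samples mapped into input coordinates (1-based)
  u <- (seq_len(n_out) - 0.5) / scale + 0.5
  half <- 2 / kscale
  W <- matrix(0, n_out, n_in)
  for (i in seq_len(n_out)) {
    left <- floor(u[i] - half)
    idx <- left:(left + ceiling(2 * half) + 1)
    w <- kscale * cubic_kernel(kscale * (u[i] - idx))
    keep <- w != 0
    idx <- idx[keep]; w <- w[keep]
    idx <- pmin(pmax(idx, 1L), n_in)  # replicate boundary
    w <- w / sum(w)
    for (j in seq_along(idx)) W[i, idx[j]] <- W[i, idx[j]] + w[j]
  }
  W
}
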