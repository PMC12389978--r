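# Forward/inverse 2-D transforms used as sparsifying dictionaries.
#
# Conventions:
#  * DCT is the orthonormal type-II pair, so Parseval holds exactly and a
#    fully-retained coefficient set has compression efficiency 1.
#  * FFT is the plain DFT (negative exponent forward, 1/(MN) on the inverse).
#  * The Haar pair uses orthonormal filters (1/sqrt(2) taps) with periodic
#    extension, so the level-1 coefficient count equals the pixel count for
#    even-sided images; odd sides are zero-padded and cropped on synthesis.

# Orthonormal DCT-II analysis matrix (n x n): row u, column k.
dct_matrix <- function(n) {
  stopifnot(n >= 1)
  if (n == 1L) return(matrix(1, 1, 1))
  k <- 0:(n - 1)
  C <- sqrt(2 / n) * cos(pi * outer(k, 2 * k + 1) / (2 * n))
  C[1, ] <- sqrt(1 / n)
  C
}

#' Forward 2-D discrete cosine transform
#'
#' Orthonormal (energy-preserving) separable type-II DCT.
#'
#' @param img Numeric matrix.
#' @return Real coefficient matrix of the same shape.
#' @export
dct2 <- function(img) {
  assert_image(img)
  dct_matrix(nrow(img)) %*% img %*% t(dct_matrix(ncol(img)))
}

#' Inverse 2-D discrete cosine transform
#'
#' Exact inverse of [dct2()].
#'
#' @param coeffs Real DCT coefficient matrix.
#' @return Image matrix of the same shape.
#' @export
idct2 <- function(coeffs) {
  assert_image(coeffs)
  t(dct_matrix(nrow(coeffs))) %*% coeffs %*% dct_matrix(ncol(coeffs))
}

#' Forward 2-D discrete Fourier transform
#'
#' Unnormalized DFT with the negative-exponent forward convention: the
#' frequency-domain picture of the image that models k-space acquisition.
#'
#' @param img Numeric matrix.
#' @return Complex coefficient matrix of the same shape.
#' @export
fft2 <- function(img) {
  assert_image(img)
  stats::fft(img)
}

#' Inverse 2-D discrete Fourier transform
#'
#' Scaled inverse DFT (division by the pixel count). With `take_real = TRUE`
#' (the default, as used by the zero-filled FFT reconstruction) the imaginary
#' part left over from discarding conjugate-symmetric coefficients is dropped.
#'
#' @param coeffs Complex coefficient matrix.
#' @param take_real Return only the real part.
#' @return Image matrix (real when `take_real`, complex otherwise).
#' @export
ifft2 <- function(coeffs, take_real = TRUE) {
  if (!is.matrix(coeffs) || length(coeffs) == 0L) {
    stop("`coeffs` must be a non-empty matrix", call. = FALSE)
  }
  out <- stats::fft(coeffs, inverse = TRUE) / length(coeffs)
  if (take_real) Re(out) else out
}

# Single-level orthonormal Haar analysis along the rows of x (pairs of rows).
haar_split <- function(x) {
  n <- nrow(x)
  odd <- seq(1, n, by = 2)
  lo <- (x[odd, , drop = FALSE] + x[odd + 1, , drop = FALSE]) / sqrt(2)
  hi <- (x[odd, , drop = FALSE] - x[odd + 1, , drop = FALSE]) / sqrt(2)
  list(lo = lo, hi = hi)
}

haar_merge <- function(lo, hi) {
  n <- 2L * nrow(lo)
  out <- matrix(0, n, ncol(lo))
  odd <- seq(1, n, by = 2)
  out[odd, ] <- (lo + hi) / sqrt(2)
  out[odd + 1, ] <- (lo - hi) / sqrt(2)
  out
}

#' Level-1 2-D Haar wavelet decomposition
#'
#' Orthonormal single-level Haar analysis. The coefficient vector is laid out
#' `[approximation | horizontal | vertical | diagonal]` with a bookkeeping
#' list of sub-band shapes, mirroring the flat-vector-plus-bookkeeping
#' convention of classic wavelet toolboxes. Sign convention: the horizontal
#' band is high-pass across rows (it responds to horizontal edges), the
#' vertical band high-pass across columns, with the `(even - odd)/sqrt(2)`
#' difference. Odd-sized sides are zero-padded to even and cropped by
#' [haar_idwt2()].
#'
#' @param img Numeric matrix.
#' @param levels Decomposition depth; only the single level used by the
#'   zero-filled wavelet pipeline is supported.
#' @return Object of class `haar_dwt2`: list with `coeffs` (flat numeric
#'   vector), `bookkeeping` (sub-band shapes) and the original image size.
#' @export
haar_dwt2 <- function(img, levels = 1) {
  assert_image(img)
  if (!identical(as.integer(levels), 1L)) {
    stop("only level-1 Haar decomposition is supported", call. = FALSE)
  }
  orig_dim <- dim(img)
  pr <- nrow(img) %% 2L
  pc <- ncol(img) %% 2L
  if (pr || pc) {
    padded <- matrix(0, nrow(img) + pr, ncol(img) + pc)
    padded[seq_len(nrow(img)), seq_len(ncol(img))] <- img
    img <- padded
  }
  rows <- haar_split(img)                      # along rows
  llv <- haar_split(t(rows$lo))                # along columns
  hhv <- haar_split(t(rows$hi))
  A <- t(llv$lo)   # low/low: approximation
  V <- t(llv$hi)   # low rows, high cols: vertical detail
  H <- t(hhv$lo)   # high rows, low cols: horizontal detail
  D <- t(hhv$hi)   # high/high: diagonal detail
  structure(
    list(
      coeffs = c(as.vector(A), as.vector(H), as.vector(V), as.vector(D)),
      bookkeeping = list(approx = dim(A), horizontal = dim(H),
                         vertical = dim(V), diagonal = dim(D)),
      orig_dim = orig_dim,
      padded_dim = dim(img)
    ),
    class = "haar_dwt2"
  )
}

#' Level-1 2-D Haar wavelet reconstruction
#'
#' Synthesis inverse of [haar_dwt2()]; exact to floating-point roundoff.
#'
#' @param dec A `haar_dwt2` object, or a list with the same fields (so a
#'   zero-filled coefficient vector can be paired with the original
#'   bookkeeping).
#' @return Image matrix of the originally decomposed size.
#' @export
haar_idwt2 <- function(dec) {
  bk <- dec$bookkeeping
  sizes <- vapply(bk, prod, numeric(1))
  if (length(dec$coeffs) != sum(sizes)) {
    stop("coefficient vector length (", length(dec$coeffs),
         ") inconsistent with bookkeeping (", sum(sizes), ")", call. = FALSE)
  }
  splits <- cumsum(sizes)
  band <- function(i) {
    lo <- if (i == 1L) 1L else splits[i - 1L] + 1L
    matrix(dec$coeffs[lo:splits[i]], bk[[i]][1], bk[[i]][2])
  }
  A <- band(1L); H <- band(2L); V <- band(3L); D <- band(4L)
  lo <- t(haar_merge(t(A), t(V)))
  hi <- t(haar_merge(t(H), t(D)))
  out <- haar_merge(lo, hi)
  out[seq_len(dec$orig_dim[1]), seq_len(dec$orig_dim[2]), drop = FALSE]
}

#' Inverse-DCT dictionary matrix
#'
#' The n x n orthogonal matrix whose columns are the 1-D orthonormal
#' inverse-DCT basis vectors — the sparsifying dictionary composed with the
#' sensing matrix in the basis-pursuit pipeline (`Theta = Phi %*%
#' idct_dictionary(n)`). Equivalent to applying the inverse DCT to each column
#' of the identity.
#'
#' @param n Signal length, at least 1.
#' @return n x n orthogonal matrix.
#' @export
idct_dictionary <- function(n) {
  if (n < 1) stop("`n` must be at least 1", call. = FALSE)
  t(dct_matrix(n))
}

# 1-D orthonormal DCT pair used by the basis-pursuit pipeline.
dct1 <- function(x) drop(dct_matrix(length(x)) %*% x)
idct1 <- function(x) drop(t(dct_matrix(length(x))) %*% x)
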