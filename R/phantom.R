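# Synthetic inputs: phantom images, exactly-sparse signals, DICOM fixtures.

#' Ellipse table of the standard head phantom
#'
#' The ten-ellipse composition of the classic head phantom (modified
#' intensity variant, which has visible soft-tissue contrast). Columns:
#' additive `intensity`, semi-axes `a`, `b`, center `x0`, `y0`, and rotation
#' `phi_deg`, all in the unit square \[-1, 1\]^2.
#'
#' @return A tibble with one row per ellipse.
#' @export
head_phantom_ellipses <- function() {
  tibble::tribble(
    ~intensity,    ~a,     ~b,    ~x0,     ~y0, ~phi_deg,
           1.0, 0.690, 0.9200,  0.00,  0.0000,        0,
          -0.8, 0.6624, 0.8740, 0.00, -0.0184,        0,
          -0.2, 0.1100, 0.3100, 0.22,  0.0000,      -18,
          -0.2, 0.1600, 0.4100, -0.22, 0.0000,       18,
           0.1, 0.2100, 0.2500, 0.00,  0.3500,        0,
           0.1, 0.0460, 0.0460, 0.00,  0.1000,        0,
           0.1, 0.0460, 0.0460, 0.00, -0.1000,        0,
           0.1, 0.0460, 0.0230, -0.08, -0.6050,       0,
           0.1, 0.0230, 0.0230, 0.00, -0.6050,        0,
           0.1, 0.0230, 0.0460, 0.06, -0.6050,        0
  )
}

#' Piecewise-constant anatomical-style phantom
#'
#' Renders a superposition of ellipses (by default the standard head-phantom
#' table) on a `size x size` grid, clipped to \[0, 1\]. The result is
#' piecewise smooth and strongly compressible in the DCT and wavelet domains
#' — the same qualitative structure as a magnitude MR image — and fully
#' deterministic, so it serves as the reference image for all benchmarks. An
#' optional smooth low-frequency texture (seeded, deterministic) can be added
#' to break exact piecewise constancy.
#'
#' @param size Side length in pixels (>= 16).
#' @param ellipses Ellipse table in the format of [head_phantom_ellipses()].
#' @param texture_seed Optional integer; when given, adds a faint smooth
#'   cosine texture inside the support.
#' @return `size x size` matrix in \[0, 1\].
#' @export
shepp_logan_phantom <- function(size = 256, ellipses = head_phantom_ellipses(),
                                texture_seed = NULL) {
  stopifnot(size >= 16)
  u <- seq(-1, 1, length.out = size)
  X <- matrix(u, size, size, byrow = TRUE)   # x varies along columns
  Y <- matrix(rev(u), size, size)            # y decreases down rows
  img <- matrix(0, size, size)
  for (i in seq_len(nrow(ellipses))) {
    e <- ellipses[i, ]
    phi <- e$phi_deg * pi / 180
    xr <- (X - e$x0) * cos(phi) + (Y - e$y0) * sin(phi)
    yr <- -(X - e$x0) * sin(phi) + (Y - e$y0) * cos(phi)
    inside <- (xr / e$a)^2 + (yr / e$b)^2 <= 1
    img[inside] <- img[inside] + e$intensity
  }
  if (!is.null(texture_seed)) {
    tex <- with_seed(texture_seed, {
      k <- matrix(stats::rnorm(9, sd = 0.02), 3, 3)
      f <- seq_len(3)
      Reduce(`+`, lapply(f, function(i) Reduce(`+`, lapply(f, function(j) {
        k[i, j] * cos(pi * i * (X + 1) / 2) * cos(pi * j * (Y + 1) / 2)
      }))))
    })
    img <- img + tex * (img > 0)
  }
  img[img < 0] <- 0
  img[img > 1] <- 1
  img
}

#' Image with an exactly K-sparse DCT representation
#'
#' Constructs an image whose 2-D DCT (or, with `domain = "1d"`, whose 1-D DCT
#' of the column-vectorized image) has exactly `K` nonzero coefficients, by
#' planting K random coefficients and inverse-transforming. Exercises the
#' exact-sparsity premise of compressed-sensing recovery. The image is scaled
#' to unit maximum absolute intensity (values may be negative; rescaling
#' preserves exact sparsity, shifting would not).
#'
#' @param size Side length in pixels.
#' @param K Number of nonzero transform coefficients, `1 <= K <= size^2`.
#' @param seed Integer RNG seed.
#' @param domain `"2d"` (2-D DCT sparsity) or `"1d"` (vectorized 1-D DCT
#'   sparsity, the representation the basis-pursuit pipeline recovers).
#' @return `size x size` matrix with `max(abs(.)) = 1`.
#' @export
sparse_dct_image <- function(size, K, seed, domain = c("2d", "1d")) {
  domain <- match.arg(domain)
  n <- size^2
  stopifnot(K >= 1, K <= n)
  coeffs <- with_seed(seed, {
    idx <- sample.int(n, K)
    val <- stats::runif(K, 0.5, 1.5) * sample(c(-1, 1), K, replace = TRUE)
    out <- numeric(n)
    out[idx] <- val
    out
  })
  img <- if (domain == "2d") {
    idct2(matrix(coeffs, size, size))
  } else {
    matrix(idct1(coeffs), size, size)
  }
  img / max(abs(img))
}

#' Exactly K-sparse test vector
#'
#' `K` nonzeros at uniformly random positions, with magnitudes uniform in
#' `[amp_low, amp_high]` and random signs — the planted ground truth for
#' solver recovery experiments.
#'
#' @param n Vector length.
#' @param K Number of nonzeros, `0 <= K <= n`.
#' @param amp_low,amp_high Magnitude range of the nonzeros.
#' @param seed Integer RNG seed.
#' @return Numeric vector of length `n` with exactly `K` nonzeros.
#' @export
ksparse_vector <- function(n, K, amp_low = 0.5, amp_high = 1.5, seed = 1L) {
  stopifnot(K >= 0, K <= n, amp_low > 0, amp_high >= amp_low)
  if (K == 0) return(numeric(n))
  with_seed(seed, {
    out <- numeric(n)
    idx <- sample.int(n, K)
    out[idx] <- stats::runif(K, amp_low, amp_high) *
      sample(c(-1, 1), K, replace = TRUE)
    out
  })
}
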