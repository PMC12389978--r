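# Internal helpers shared across modules.

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite number", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# MATLAB-style round(): halves go away from zero (base R round() is
# round-half-even, which disagrees on e.g. 4.5).
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

l2norm <- function(x) sqrt(sum(Mod(x)^2))

assert_image <- function(img, arg = deparse(substitute(img))) {
  if (!is.matrix(img) || !is.numeric(img) || length(img) == 0L) {
    stop("`", arg, "` must be a non-empty numeric matrix", call. = FALSE)
  }
  if (!all(is.finite(img))) {
    stop("`", arg, "` contains non-finite values", call. = FALSE)
  }
  invisible(img)
}

assert_same_shape <- function(x, x1) {
  if (!identical(dim(x), dim(x1))) {
    stop("images must have identical dimensions (",
         paste(dim(x), collapse = "x"), " vs ",
         paste(dim(x1), collapse = "x"), ")", call. = FALSE)
  }
  invisible(TRUE)
}
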