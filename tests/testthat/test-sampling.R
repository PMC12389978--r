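test_that("random masks honor the half-away rounding rule and determinism", {
  p <- random_coefficient_mask(9, 0.5, seed = 1)
  expect_length(p$indices, 5L)  # round(4.5) away from zero

  full <- random_coefficient_mask(10, 1.0, seed = 1)
  expect_equal(full$indices, 1:10)

  a <- random_coefficient_mask(100, 0.3, seed = 7)
  b <- random_coefficient_mask(100, 0.3, seed = 7)
  expect_identical(a$indices, b$indices)
  expect_false(identical(a$indices,
                         random_coefficient_mask(100, 0.3, seed = 8)$indices))

  expect_error(random_coefficient_mask(100, 0.001, seed = 1), "retains no")
})

test_that("mask generation leaves the caller's RNG stream untouched", {
  set.seed(42); before <- rnorm(3)
  set.seed(42); invisible(random_coefficient_mask(50, 0.5, seed = 9))
  expect_identical(rnorm(3), before)
})

test_that("top-magnitude masks use the floor rule with stable tie-breaks", {
  p <- top_magnitude_mask(c(3, -5, 2), 2 / 3)
  expect_equal(p$indices, c(1L, 2L))  # |−5| then |3|

  expect_equal(top_magnitude_mask(c(1, 2, 3), 1.0)$indices, 1:3)

  # ties broken by lower position
  p2 <- top_magnitude_mask(c(2, -2, 2, -2), 0.5)
  expect_equal(p2$indices, c(1L, 2L))
})

test_that("zero-filling is an exact projection", {
  p <- random_coefficient_mask(3, 0.7, seed = 2)  # keeps 2 of 3
  x <- c(1, 2, 3)
  filled <- zero_fill(x, p)
  expect_equal(filled[p$indices], x[p$indices])
  expect_equal(filled[-p$indices], rep(0, 1))
  expect_equal(zero_fill(filled, p), filled)

  expect_equal(zero_fill(x, top_magnitude_mask(x, 1.0)), x)
  expect_error(zero_fill(c(1, 2), p), "length")
  expect_lte(sum(filled^2), sum(x^2))
})

test_that("top-magnitude retention minimizes L2 error among all subsets", {
  set.seed(13)
  for (trial in 1:5) {
    v <- rnorm(8)
    n_keep <- 3L
    plan <- top_magnitude_mask(v, n_keep / 8)
    err_top <- sum((v - zero_fill(v, plan))^2)
    combos <- utils::combn(8, n_keep)
    best <- min(apply(combos, 2, function(keep) sum(v[-keep]^2)))
    expect_equal(err_top, best, tolerance = 1e-12)
  }
})

test_that("Gaussian sensing matrices have the documented scale and determinism", {
  Phi <- gaussian_sensing_matrix(50, 100, seed = 3)
  expect_equal(dim(Phi), c(50L, 100L))
  expect_identical(Phi, gaussian_sensing_matrix(50, 100, seed = 3))

  # sample moment check at n*m >= 1e5 (perturbation off to isolate the scale)
  big <- gaussian_sensing_matrix(100, 1000, seed = 4, perturb = FALSE)
  expect_lt(abs(sd(big) - 1 / 100) / (1 / 100), 0.05)

  conv <- gaussian_sensing_matrix(100, 1000, seed = 4, scale = "1/sqrt(m)",
                                  perturb = FALSE)
  expect_lt(abs(sd(conv) - 1 / 10) / (1 / 10), 0.05)

  # the 1e-6 perturbation sits on the leading diagonal block only
  raw <- gaussian_sensing_matrix(5, 9, seed = 6, perturb = FALSE)
  pert <- gaussian_sensing_matrix(5, 9, seed = 6, perturb = TRUE)
  delta <- pert - raw
  expect_equal(delta[cbind(1:5, 1:5)], rep(1e-6, 5))
  delta[cbind(1:5, 1:5)] <- 0
  expect_equal(max(abs(delta)), 0)

  expect_warning(gaussian_sensing_matrix(10, 5, seed = 1), "overdetermined")
})

test_that("measurement is the exact matrix-vector product", {
  expect_equal(measure_signal(diag(4), c(1, 2, 3, 4)), c(1, 2, 3, 4))
  expect_equal(measure_signal(matrix(rnorm(12), 3, 4), rep(0, 4)), rep(0, 3))

  set.seed(21)
  Phi <- matrix(rnorm(20), 4, 5)
  x <- rnorm(5)
  manual <- vapply(1:4, function(i) sum(Phi[i, ] * x), numeric(1))
  expect_equal(measure_signal(Phi, x), manual, tolerance = 1e-14)
  expect_error(measure_signal(Phi, rnorm(4)), "match")
})
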