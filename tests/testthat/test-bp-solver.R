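test_that("feasible initialization lands on the measurement manifold", {
  Theta <- gaussian_sensing_matrix(10, 30, seed = 1, perturb = FALSE)
  y <- rnorm(10)
  s0 <- feasible_init(Theta, y)
  expect_lt(sqrt(sum((drop(Theta %*% s0) - y)^2)), 1e-10)

  expect_equal(feasible_init(Theta, rep(0, 10)), rep(0, 30))

  # orthogonal rows: s0 = Theta' (Theta Theta')^{-1} y reduces to Theta' y
  Q <- qr.Q(qr(matrix(rnorm(36), 6, 6)))[, 1:3]
  ThetaO <- t(Q)
  yo <- rnorm(3)
  expect_equal(feasible_init(ThetaO, yo), drop(t(ThetaO) %*% yo),
               tolerance = 1e-12)
})

test_that("basis pursuit solves degenerate systems exactly", {
  Theta <- gaussian_sensing_matrix(8, 16, seed = 2, perturb = FALSE)
  sol0 <- solve_bp(Theta, rep(0, 8))
  expect_equal(sol0$s, rep(0, 16))
  expect_equal(sol0$status, "converged")

  # square identity: unique feasible point
  y <- rnorm(6)
  soli <- suppressWarnings(solve_bp(diag(6), y))
  expect_equal(soli$s, y, tolerance = 1e-6)
})

test_that("planted sparse vectors are recovered and certified", {
  Theta <- gaussian_sensing_matrix(16, 32, seed = 3, perturb = FALSE)
  s_true <- ksparse_vector(32, 2, seed = 4)
  y <- measure_signal(Theta, s_true)
  sol <- suppressWarnings(solve_bp(Theta, y))
  expect_lt(max(abs(sol$s - s_true)), 1e-4)
  expect_lt(sol$feasibility_residual, 1e-8 * sqrt(sum(y^2)))

  oracle <- bp_lp_oracle(Theta, y)
  expect_lt(abs(sum(abs(sol$s)) - sum(abs(oracle))), 1e-5)
})

test_that("solver agrees with the LP oracle across random instances", {
  for (i in 1:10) {
    Theta <- gaussian_sensing_matrix(16, 32, seed = 100 + i, perturb = FALSE)
    s_true <- ksparse_vector(32, 3, seed = 200 + i)
    y <- measure_signal(Theta, s_true)
    sol <- suppressWarnings(solve_bp(Theta, y))
    oracle <- bp_lp_oracle(Theta, y)
    expect_lt(abs(sol$objective - sum(abs(oracle))), 1e-5)
    expect_lt(max(abs(sol$s - oracle)), 1e-4)
  }
})

test_that("LP oracle handles trivial systems", {
  y <- c(1, -2, 3)
  expect_equal(bp_lp_oracle(diag(3), y), y, tolerance = 1e-9)
  expect_equal(bp_lp_oracle(matrix(rnorm(12), 2, 6), rep(0, 2)), rep(0, 6),
               tolerance = 1e-9)
  expect_error(bp_lp_oracle(matrix(rnorm(2 * 300), 2, 300), rnorm(2)), "n <= 256")
})

test_that("iterates stay feasible and the objective decreases monotonically", {
  Theta <- gaussian_sensing_matrix(20, 40, seed = 5, perturb = FALSE)
  s_true <- ksparse_vector(40, 3, seed = 6)
  y <- measure_signal(Theta, s_true)
  sol <- suppressWarnings(solve_bp(Theta, y, keep_trace = TRUE))
  expect_lt(sol$feasibility_residual, 1e-8 * sqrt(sum(y^2)))
  obj <- sol$trace$objective
  expect_true(all(diff(obj) <= 1e-9 * (1 + obj[-length(obj)])))
})

test_that("an infeasible warm start is replaced, a feasible one honored", {
  Theta <- gaussian_sensing_matrix(12, 24, seed = 7, perturb = FALSE)
  s_true <- ksparse_vector(24, 2, seed = 8)
  y <- measure_signal(Theta, s_true)
  # the conventional zero initial guess is infeasible for y != 0
  sol <- suppressWarnings(solve_bp(Theta, y, s0 = rep(0, 24)))
  expect_lt(sol$feasibility_residual, 1e-8 * sqrt(sum(y^2)))
  expect_lt(max(abs(sol$s - s_true)), 1e-3)
})

test_that("the iteration cap returns a flagged result, not an error", {
  Theta <- gaussian_sensing_matrix(16, 32, seed = 9, perturb = FALSE)
  y <- measure_signal(Theta, ksparse_vector(32, 2, seed = 10))
  expect_warning(sol <- solve_bp(Theta, y, max_iter = 3), "max_iter")
  expect_equal(sol$status, "max_iter")
  expect_equal(sol$iterations, 3L)
})

test_that("tidy and glance summarize solutions", {
  Theta <- gaussian_sensing_matrix(8, 16, seed = 11, perturb = FALSE)
  y <- measure_signal(Theta, ksparse_vector(16, 2, seed = 12))
  sol <- suppressWarnings(solve_bp(Theta, y))
  td <- tidy(sol)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 16L)
  gl <- glance(sol)
  expect_named(gl, c("objective", "duality_gap", "feasibility_residual",
                     "iterations", "status"))
})
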