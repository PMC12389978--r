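test_that("error metrics match closed forms", {
  z <- matrix(0, 1, 2)
  o <- matrix(1, 1, 2)
  expect_equal(mse(z, z), 0)
  expect_equal(mse(z, o), 1)
  expect_equal(mse(matrix(c(0, 1), 1), o), 0.5)
  expect_equal(rmse(z, matrix(0.5, 1, 2)), 0.5)

  expect_equal(psnr(z, matrix(0.1, 1, 2)), 20)
  expect_equal(psnr(z, o), 0)
  expect_identical(psnr(o, o), Inf)

  expect_equal(data_loss(o, o), 0)
  expect_equal(data_loss(o, z), 100)
  expect_equal(data_loss(matrix(c(3, 4), 1), matrix(c(0, 4), 1)), 60)

  expect_error(mse(z, matrix(0, 2, 2)), "dimensions")
  expect_error(data_loss(z, z), "zero norm")
})

test_that("metric identities hold on random image pairs", {
  for (seed in 1:5) {
    x <- random_image(16, seed = seed)
    x1 <- random_image(16, seed = seed + 50)
    expect_equal(rmse(x, x1)^2, mse(x, x1), tolerance = 1e-14)
    expect_equal(psnr(x, x1), -20 * log10(rmse(x, x1)), tolerance = 1e-9)
    expect_equal(data_loss(x, x1),
                 100 * rmse(x, x1) * sqrt(length(x)) / sqrt(sum(x^2)),
                 tolerance = 1e-10)
  }
})

test_that("SSIM is 1 on identical images, symmetric, and bounded", {
  x <- test_phantom(32)
  expect_equal(ssim(x, x), 1)
  expect_equal(ssim(x, x, window = "global"), 1)

  for (seed in 1:5) {
    a <- random_image(16, seed = seed)
    b <- random_image(16, seed = seed + 9)
    s_ab <- ssim(a, b)
    expect_equal(s_ab, ssim(b, a), tolerance = 1e-12)
    expect_gte(s_ab, -1)
    expect_lte(s_ab, 1)
  }

  # constant pair: stabilizers prevent 0/0
  expect_equal(ssim(matrix(0.4, 12, 12), matrix(0.4, 12, 12)), 1)
})

test_that("global-window SSIM reproduces the hand-computed example", {
  x <- matrix(c(0, 1, 0, 1), 2)
  x1 <- matrix(c(1, 0, 1, 0), 2)
  expect_equal(ssim(x, x1, window = "global"), -0.99641, tolerance = 1e-4)
})

test_that("small images demand the global window", {
  expect_error(ssim(matrix(1, 4, 4), matrix(1, 4, 4), window = "gaussian"),
               "global")
})

test_that("compression efficiency reflects retained energy", {
  x <- random_image(8, seed = 3)
  full_dct <- as.vector(dct2(x))
  expect_equal(compression_efficiency(full_dct, x), 1, tolerance = 1e-12)
  expect_equal(compression_efficiency(as.vector(x) / 2, x), 0.5)

  # zero-filled orthonormal retention: efficiency = sqrt(energy fraction) <= 1
  plan <- top_magnitude_mask(full_dct, 0.4)
  kept <- full_dct[plan$indices]
  eff <- compression_efficiency(kept, x)
  expect_equal(eff, sqrt(sum(kept^2) / sum(x^2)), tolerance = 1e-12)
  expect_lte(eff, 1)

  expect_error(compression_efficiency(c(1, 2), matrix(0, 2, 2)), "zero norm")
})

test_that("the resource probe returns sane timings", {
  pr <- resource_probe(function() {
    t0 <- Sys.time(); while (as.numeric(Sys.time() - t0) < 0.1) {}
    "done"
  })
  expect_equal(pr$result, "done")
  expect_gte(pr$time_s, 0.05)
  expect_lt(pr$time_s, 5)
  expect_true(is.na(pr$memory_gb) || pr$memory_gb > 0)
})

test_that("metric report rows carry the full column schema", {
  x <- test_phantom(32)
  rep <- metrics_report(x, x, as.vector(dct2(x)))
  expect_named(rep, c("time_s", "memory_gb", "compression_efficiency",
                      "rmse", "psnr_db", "ssim", "mse", "data_loss_pct"))
  expect_identical(rep$psnr_db, Inf)
  expect_equal(rep$ssim, 1)
  expect_equal(rep$data_loss_pct, 0)
})
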