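# synthetic uniaxial data generation and constrained NLS identification

test_that("synthetic data generation is exact at zero noise and seed-deterministic", {
  p <- ref_params()
  d <- generate_uniaxial_data(p, noise_sd = 0)
  expect_s3_class(d, "uniaxial_data")
  expect_identical(nrow(d), 50L)
  expect_identical(d$nominal_stress_mpa[1], 0)
  i <- which.min(abs(d$stretch - 1.5))
  expect_equal(d$nominal_stress_mpa[i],
               uniaxial_nominal_stress(p, d$stretch[i]), tolerance = 1e-14)
  d1 <- generate_uniaxial_data(p, noise_sd = 0.01, seed = 99)
  d2 <- generate_uniaxial_data(p, noise_sd = 0.01, seed = 99)
  expect_identical(d1$nominal_stress_mpa, d2$nominal_stress_mpa)
  expect_error(generate_uniaxial_data(p, lam_grid = numeric()),
               class = "levatorfem_invalid_input")
  expect_error(generate_uniaxial_data(p, noise_sd = -1),
               class = "levatorfem_invalid_input")
})

test_that("the stress error E matches a brute-force residual loop", {
  p <- ref_params()
  d <- generate_uniaxial_data(p, noise_sd = 0)
  expect_identical(sse_ogden(d, p), 0)
  d2 <- d
  d2$nominal_stress_mpa[17] <- d2$nominal_stress_mpa[17] + 0.003
  expect_equal(sse_ogden(d2, p), 0.003^2 / 2, tolerance = 1e-15)
  other <- random_stable_params(1, seed = 13)[[1]]
  acc <- 0
  for (i in seq_len(nrow(d)))
    acc <- acc + (d$nominal_stress_mpa[i] -
                    uniaxial_nominal_stress(other, d$stretch[i]))^2
  expect_equal(sse_ogden(d, other), acc / 2, tolerance = 1e-12)
})

test_that("two-term fit recovers the reference parameters from noise-free data", {
  p <- ref_params()
  d <- generate_uniaxial_data(p, noise_sd = 0)
  fit <- fit_ogden(d, n_terms = 2, seed = 1)
  expect_true(fit$converged)
  co <- coef(fit)
  expect_equal(unname(co["alpha1"]), 1.81, tolerance = 0.05)
  expect_equal(unname(co["alpha2"]), 17.25, tolerance = 0.05)
  # curve-space agreement within 1 percent where the stress is appreciable
  pred <- predict(fit)
  truth <- d$nominal_stress_mpa
  i <- truth > 1e-4
  expect_lt(max(abs(pred[i] - truth[i]) / truth[i]), 0.01)
  expect_gt(sum(fit$params$mu * fit$params$alpha), 0)
  expect_true(all(diff(fit$params$alpha) >= 0))  # sorted ascending
})

test_that("one-term self-consistency and degenerate inputs", {
  p1 <- ogden_params(mu = 0.1, alpha = 2)
  d <- generate_uniaxial_data(p1, noise_sd = 0)
  fit <- fit_ogden(d, n_terms = 1, seed = 2)
  expect_equal(unname(coef(fit)["mu1"]), 0.1, tolerance = 1e-3)
  expect_equal(unname(coef(fit)["alpha1"]), 2, tolerance = 1e-3)
  degen <- uniaxial_data(1, 0)
  expect_error(fit_ogden(degen, n_terms = 2),
               class = "levatorfem_invalid_input")
  expect_error(fit_ogden(generate_uniaxial_data(p1), n_terms = 2,
                         lower = rep(1, 4), upper = rep(0, 4)),
               class = "levatorfem_invalid_input")
})

test_that("fits improve on their initialisations, stay stable, and benefit from more data", {
  for (seed in 1:3) {
    truth <- random_stable_params(1, seed = seed + 100)[[1]]
    d <- generate_uniaxial_data(truth, noise_sd = 0)
    fit <- fit_ogden(d, n_terms = 2, seed = seed)
    expect_lte(fit$sse, min(fit$start_sse) + 1e-12)
    expect_gt(sum(fit$params$mu * fit$params$alpha), 0)
    pred <- predict(fit)
    i <- d$nominal_stress_mpa > 1e-4
    expect_lt(max(abs(pred[i] - d$nominal_stress_mpa[i]) /
                    d$nominal_stress_mpa[i]), 0.01)
  }
  # held-out RMSE decreases with the number of noisy points
  p <- ref_params()
  hold <- seq(1, 1.6, length.out = 80)
  truth_hold <- uniaxial_nominal_stress(p, hold)
  rmse <- sapply(c(10, 100), function(nd) {
    d <- generate_uniaxial_data(p, lam_grid = seq(1, 1.6, length.out = nd),
                                noise_sd = 0.01, seed = 7)
    f <- fit_ogden(d, n_terms = 2, seed = 7)
    sqrt(mean((uniaxial_nominal_stress(f$params, hold) - truth_hold)^2))
  })
  expect_lt(rmse[2], rmse[1])
})

test_that("ogden_fit behaves like a standard fitted-model object", {
  d <- generate_uniaxial_data(ref_params(), noise_sd = 0.005, seed = 4)
  fit <- fit_ogden(d, seed = 4)
  expect_named(coef(fit), c("mu1", "mu2", "alpha1", "alpha2"))
  expect_length(residuals(fit), nrow(d))
  expect_equal(fitted(fit) + residuals(fit), d$nominal_stress_mpa)
  expect_equal(predict(fit, newdata = c(1.2, 1.4)),
               uniaxial_nominal_stress(fit$params, c(1.2, 1.4)))
  sims <- simulate(fit, nsim = 2, seed = 10)
  expect_length(sims, 2)
  expect_s3_class(sims[[1]], "uniaxial_data")
  out <- capture.output({print(fit); print(summary(fit))})
  expect_true(any(grepl("Ogden", out)))
  pdf(NULL); on.exit(dev.off())
  expect_invisible(plot(fit))
})

test_that("uniaxial CSV round-trips and rejects malformed input", {
  d <- generate_uniaxial_data(ref_params(), noise_sd = 0.002, seed = 6)
  f <- tempfile(fileext = ".csv")
  write_uniaxial_csv(d, f)
  d2 <- read_uniaxial_csv(f)
  expect_equal(d2$stretch, d$stretch, tolerance = 1e-12)
  expect_equal(d2$nominal_stress_mpa, d$nominal_stress_mpa, tolerance = 1e-12)
  bad <- tempfile(fileext = ".csv")
  writeLines(c("a,b", "1,2"), bad)
  expect_error(read_uniaxial_csv(bad), class = "levatorfem_io_error")
  expect_error(uniaxial_data(c(1.2, 1.1), c(0, 0)),
               class = "levatorfem_invalid_input")
  expect_error(uniaxial_data(c(0.8, 1.1), c(0, 0)),
               class = "levatorfem_invalid_input")
})
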