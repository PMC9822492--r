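log_times <- function(n = 200, t_max = 500, t_min = 0.01) {
  exp(seq(log(t_min), log(t_max), length.out = n))
}

test_that("Hill fraction evaluates the saturation model", {
  expect_equal(hill_fraction(500, D_eff = 8.96e-13, n = 0.557, h = 1e-6),
               0.9661612, tolerance = 1e-6)
  expect_identical(hill_fraction(0, 1e-12, 0.8, 1e-6), 0)
  # algebraic midpoint: D_eff t^n = h^2
  t_half <- (1e-12 / 5e-13)^(1 / 0.8)
  expect_equal(hill_fraction(t_half, 5e-13, 0.8, 1e-6), 0.5, tolerance = 1e-12)
  tt <- log_times(50)
  expect_true(all(diff(hill_fraction(tt, 5e-13, 0.8, 1e-6)) > 0))
})

test_that("linearised initialiser is exact on noiseless Hill data", {
  curve <- generate_hill_curve(5e-13, 0.8, 1e-6, times = log_times(100))
  init <- linearized_init(curve, h = 1e-6)
  expect_equal(unname(init["D_eff"]), 5e-13, tolerance = 1e-6)
  expect_equal(unname(init["n"]), 0.8, tolerance = 1e-6)
  # saturated/empty points are excluded, not fatal
  clipped <- rbind(data.frame(time_s = 1e-9, time_norm = 0, n_passed = 0, fraction = 0),
                   as.data.frame(curve),
                   data.frame(time_s = 1e9, time_norm = 1, n_passed = 5000, fraction = 1))
  init2 <- linearized_init(clipped, h = 1e-6)
  expect_equal(unname(init2["D_eff"]), 5e-13, tolerance = 1e-6)
  expect_error(linearized_init(data.frame(time_s = 1:3, fraction = c(0, 1, 1)), 1e-6),
               "interior points")
})

test_that("linearised initialiser stays near truth under noise", {
  curve <- generate_hill_curve(5e-13, 0.8, 1e-6, times = log_times(200),
                               noise_sd = 0.02, seed = 17)
  init <- linearized_init(curve, h = 1e-6)
  expect_lt(abs(init["D_eff"] - 5e-13) / 5e-13, 0.30)
  expect_lt(abs(init["n"] - 0.8) / 0.8, 0.30)
})

test_that("noiseless Hill curves are recovered essentially exactly", {
  curve <- generate_hill_curve(5e-13, 0.8, 1e-6, times = log_times(200))
  fit <- fit_hill(curve, h = 1e-6)
  expect_true(fit$converged)
  expect_lt(abs(fit$D_eff - 5e-13) / 5e-13, 1e-4)
  expect_lt(abs(fit$n - 0.8) / 0.8, 1e-4)
  expect_gte(fit$r_squared, 1 - 1e-8)
})

test_that("round-trip recovery holds across the parameter range", {
  set.seed(23)
  for (i in 1:20) {
    D_true <- 10^runif(1, -13, -11)
    n_true <- runif(1, 0.4, 1.2)
    curve <- generate_hill_curve(D_true, n_true, 1e-6, times = log_times(150))
    fit <- fit_hill(curve, h = 1e-6)
    expect_lt(abs(fit$D_eff - D_true) / D_true, 1e-4)
    expect_lt(abs(fit$n - n_true) / n_true, 1e-4)
  }
})

test_that("fits tolerate 2% observation noise", {
  errs <- vapply(1:10, function(s) {
    curve <- generate_hill_curve(5e-13, 0.8, 1e-6, times = log_times(200),
                                 noise_sd = 0.02, seed = 100 + s)
    fit <- fit_hill(curve, h = 1e-6)
    c(abs(fit$D_eff - 5e-13) / 5e-13, abs(fit$n - 0.8) / 0.8)
  }, numeric(2))
  expect_lt(median(errs[1, ]), 0.20)
  expect_lt(median(errs[2, ]), 0.10)
})

test_that("time-unit rescaling leaves an n = 1 fit invariant up to the factor", {
  tt <- log_times(120)
  curve_s <- generate_hill_curve(5e-13, 1, 1e-6, times = tt)
  curve_min <- curve_s
  curve_min$time_s <- curve_s$time_s / 60
  fit_s <- fit_hill(curve_s, h = 1e-6)
  fit_min <- fit_hill(curve_min, h = 1e-6)
  expect_equal(fit_min$n, 1, tolerance = 1e-4)
  expect_equal(fit_min$D_eff / fit_s$D_eff, 60, tolerance = 1e-3)
})

test_that("generator clips, monotonises and reproduces from the seed", {
  tt <- log_times(100)
  a <- generate_hill_curve(5e-13, 0.8, 1e-6, times = tt, noise_sd = 0.3, seed = 41)
  b <- generate_hill_curve(5e-13, 0.8, 1e-6, times = tt, noise_sd = 0.3, seed = 41)
  expect_identical(a, b)
  expect_true(all(a$fraction >= 0 & a$fraction <= 1))
  expect_true(all(diff(a$fraction) >= 0))
  exact <- generate_hill_curve(5e-13, 0.8, 1e-6, times = tt)
  expect_equal(exact$fraction, hill_fraction(tt, 5e-13, 0.8, 1e-6))
})

test_that("tidy and glance summarise a fit", {
  curve <- generate_hill_curve(5e-13, 0.8, 1e-6, times = log_times(80),
                               noise_sd = 0.01, seed = 3)
  fit <- fit_hill(curve, h = 1e-6)
  td <- tidy(fit)
  expect_identical(td$term, c("D_eff", "n"))
  expect_true(all(is.finite(td$estimate)))
  gl <- glance(fit)
  expect_identical(gl$nobs, nrow(fit$data))
  expect_lte(gl$r.squared, 1)
  expect_true(is.logical(gl$converged))
})
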