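test_that("auto time step obeys the RMS-step rule", {
  # the binding constraint here is r_acc/5 = 1 nm (d_p = 15 nm)
  cfg <- simulation_config(capillary_equivalent(r_h = 12.5e-9, length = 1e-6),
                           particle_spec(15e-9), fluid_medium(0.05))
  D <- free_diffusion_coefficient(cfg$particle, cfg$fluid)
  dt <- auto_timestep(cfg)
  expect_equal(sqrt(2 * D * dt), 1e-9, tolerance = 1e-12)
  expect_gte(dt, 100 * momentum_relaxation_time(cfg$particle, cfg$fluid))
  # higher viscosity -> smaller D -> larger dt at the same RMS bound
  cfg10 <- simulation_config(capillary_equivalent(r_h = 12.5e-9, length = 1e-6),
                             particle_spec(15e-9), fluid_medium(0.01))
  expect_gt(dt, auto_timestep(cfg10))
})

test_that("overdamped increments have the exact Brownian moments", {
  set.seed(21)
  n <- 1e5
  D <- 8.733108e-12; dt <- 1e-7
  x0 <- matrix(0, n, 3)
  dx <- step_overdamped(x0, D, dt)
  v <- 2 * D * dt
  # sample variance of a normal: sd = sigma^2 sqrt(2/n)
  for (k in 1:3) {
    expect_lt(abs(var(dx[, k]) - v), 3 * v * sqrt(2 / n))
    expect_lt(abs(mean(dx[, k])), 3 * sqrt(v / n))
  }
  expect_identical(step_overdamped(x0, 0, dt), x0)
})

test_that("Langevin velocity decays by e^-1 per relaxation time under pure drag", {
  p <- particle_spec(5e-9); f <- fluid_medium(0.01)
  tau <- momentum_relaxation_time(p, f)
  dt <- tau / 100
  state <- list(pos = matrix(0, 1, 3), vel = matrix(1, 1, 3))
  for (i in 1:100) state <- step_langevin(state, p, f, dt, thermal = FALSE)
  expect_equal(state$vel[1, 1], exp(-1), tolerance = 0.01)
})

test_that("Langevin long-time MSD realises the free diffusion coefficient", {
  set.seed(31)
  p <- particle_spec(5e-9); f <- fluid_medium(0.01)
  tau <- momentum_relaxation_time(p, f)
  dt <- 100 * tau
  n_steps <- 1e4; n <- 2000
  state <- list(pos = matrix(0, n, 3), vel = matrix(0, n, 3))
  for (i in seq_len(n_steps)) state <- step_langevin(state, p, f, dt)
  D_hat <- mean(state$pos^2) / (2 * n_steps * dt)
  expect_equal(D_hat, free_diffusion_coefficient(p, f), tolerance = 0.05)
})

test_that("boundary rules: absorption precedes reflection, top wall mirrors", {
  r <- 1e-8; len <- 1e-6
  prev <- rbind(c(0, 0, 9.9e-7), c(0, 0, 1e-8), c(5e-9, 0, 5e-7))
  prop <- rbind(c(0, 0, 1.01e-6),      # beyond the absorbing plane
                c(0, 0, -4e-9),        # through the top wall
                c(1.2e-8, 0, 5e-7))    # through the side wall
  out <- apply_boundaries(prev, prop, r_acc = r, length = len)
  expect_identical(out$absorbed, c(TRUE, FALSE, FALSE))
  expect_equal(out$pos[2, 3], 4e-9)                       # mirrored z
  expect_lte(sqrt(sum(out$pos[3, 1:2]^2)), r + 1e-18)     # back inside
  # specular side reflection preserves the axial coordinate
  expect_equal(out$pos[3, 3], 5e-7)
})

test_that("reflecting cylinder preserves the uniform lateral density", {
  set.seed(11)
  r <- 1e-8
  n <- 400
  D <- 8.733108e-12
  dt <- (r / 5)^2 / (2 * D)
  u <- runif(n); th <- runif(n, 0, 2 * pi)
  pos <- cbind(r * sqrt(u) * cos(th), r * sqrt(u) * sin(th), 0)
  for (i in 1:1e4) {
    prop <- step_overdamped(pos, D, dt)
    pos <- apply_boundaries(pos, prop, r_acc = r, length = Inf,
                            absorb_plane = Inf)$pos
  }
  # rho^2 uniform on [0, r^2] at equilibrium
  ks <- suppressWarnings(ks.test((pos[, 1]^2 + pos[, 2]^2) / r^2, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("passage curve matches the exact first-passage law", {
  cfg <- short_cfg(n_particles = 2000, t_end = 0.01, seed = 5)
  curve <- run_simulation(cfg)
  D <- free_diffusion_coefficient(cfg$particle, cfg$fluid)
  p_exact <- first_passage_fraction(curve$time_s, D, cfg$capillary$length,
                                    cfg$release_offset)
  expect_within_binomial_band(curve$n_passed, p_exact, cfg$n_particles)
})

test_that("curves are conserved, monotone and reproducible from the seed", {
  cfg <- short_cfg(n_particles = 500, t_end = 0.005, seed = 3)
  curve <- run_simulation(cfg)
  fpt <- attr(curve, "absorption_times")
  expect_length(fpt, 500)
  expect_identical(sum(!is.na(fpt)) + sum(is.na(fpt)), 500L)
  expect_identical(max(curve$n_passed), sum(!is.na(fpt)))
  expect_true(all(diff(curve$n_passed) >= 0))
  expect_true(all(curve$fraction >= 0 & curve$fraction <= 1))
  again <- run_simulation(cfg)
  expect_identical(curve$n_passed, again$n_passed)
  other <- run_simulation(short_cfg(n_particles = 500, t_end = 0.005, seed = 4))
  expect_false(identical(curve$n_passed, other$n_passed))
})

test_that("a vanishing horizon yields a flat zero curve", {
  # far too little time to cross ~1 um starting 30 nm below the top
  cap <- capillary_equivalent(r_h = 1.25e-8, length = 1e-6)
  cfg <- simulation_config(cap, particle_spec(5e-9), fluid_medium(0.01),
                           n_particles = 200, t_end = 1e-4, seed = 2)
  curve <- run_simulation(cfg)
  expect_true(all(curve$fraction == 0))
})

test_that("passage is stochastically faster in less viscous fluids", {
  cap <- capillary_equivalent(r_h = 1.25e-8, length = 2e-7)
  curves <- lapply(c(0.01, 0.02, 0.05), function(eta) {
    cfg <- simulation_config(cap, particle_spec(5e-9), fluid_medium(eta),
                             n_particles = 1500, t_end = 0.05, seed = 8,
                             record_times = c(1e-4, 5e-4, 2e-3, 1e-2, 5e-2))
    run_simulation(cfg)
  })
  se3 <- 3 * sqrt(0.25 / 1500)
  expect_true(all(curves[[1]]$fraction >= curves[[2]]$fraction - 2 * se3))
  expect_true(all(curves[[2]]$fraction >= curves[[3]]$fraction - 2 * se3))
  expect_gt(max(curves[[1]]$fraction), max(curves[[3]]$fraction))
})

test_that("axial passage law is independent of lateral confinement", {
  # a strongly confined particle (d_p = 10 nm in a 12.5 nm capillary),
  # with and without the cylindrical wall
  cap <- capillary_equivalent(r_h = 1.25e-8, length = 2e-7)
  base <- list(capillary = cap, particle = particle_spec(1e-8),
               fluid = fluid_medium(0.01))
  cfg_on <- simulation_config(cap, base$particle, base$fluid,
                              n_particles = 1500, t_end = 0.1, seed = 12)
  cfg_off <- simulation_config(cap, base$particle, base$fluid,
                               n_particles = 1500, t_end = 0.1, seed = 13,
                               lateral_walls = FALSE)
  D <- free_diffusion_coefficient(base$particle, base$fluid)
  curve_on <- run_simulation(cfg_on)
  curve_off <- run_simulation(cfg_off)
  p_exact <- first_passage_fraction(curve_on$time_s, D, cap$length, 3e-8)
  expect_within_binomial_band(curve_on$n_passed, p_exact, 1500)
  expect_within_binomial_band(curve_off$n_passed, p_exact, 1500)
})

test_that("Langevin and overdamped schemes agree in passage law", {
  cfg_od <- short_cfg(n_particles = 2000, t_end = 0.01, seed = 14)
  cfg_lv <- short_cfg(n_particles = 2000, t_end = 0.01, seed = 15,
                      scheme = "langevin")
  D <- free_diffusion_coefficient(cfg_od$particle, cfg_od$fluid)
  curve_lv <- run_simulation(cfg_lv)
  p_exact <- first_passage_fraction(curve_lv$time_s, D,
                                    cfg_lv$capillary$length, 3e-8)
  expect_within_binomial_band(curve_lv$n_passed, p_exact, 2000)
  curve_od <- run_simulation(cfg_od)
  # difference of two independent binomial fractions
  se3 <- 3 * sqrt(2 * pmax(p_exact * (1 - p_exact), 1 / 2000) / 2000)
  expect_true(all(abs(curve_od$fraction - curve_lv$fraction) <= se3))
})

test_that("oversized particles are rejected with a clear error", {
  cap <- capillary_equivalent(r_h = 1.25e-8, length = 1e-6)
  expect_error(
    simulation_config(cap, particle_spec(2.5e-8), fluid_medium(0.01)),
    "larger than capillary"
  )
})

test_that("first-passage series has the exact limits and mean", {
  D <- 8.733108e-12; len <- 1e-6; x0 <- 3e-8
  expect_identical(first_passage_fraction(0, D, len, x0), 0)
  mfpt <- mean_first_passage_time(D, len, x0)
  expect_gt(first_passage_fraction(50 * mfpt, D, len, x0), 1 - 1e-8)
  # non-decreasing up to the 1e-12 truncation error of the series
  expect_true(all(diff(first_passage_fraction(10^seq(-4, 1, 0.1), D, len, x0)) >= -1e-11))
  # integral of the survival function equals (len^2 - x0^2) / (2 D)
  quad <- integrate(function(t) 1 - first_passage_fraction(t, D, len, x0),
                    lower = 0, upper = Inf, rel.tol = 1e-9)
  expect_equal(quad$value, mfpt, tolerance = 1e-6)
})
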