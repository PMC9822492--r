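# Independent oracles and shared fixtures for the test suite.

# Brute-force lipid area fraction by explicit tiling: n x n keratinocyte
# bricks with n-1 channels per axis. The lipid area is accumulated strip by
# strip -- each of the n-1 channels per axis spans the full patch, and the
# (n-1)^2 crossings are counted once -- so no large-area cancellation enters.
# Valid when the patch holds an integer number of bricks per axis.
tiled_lipid_fraction <- function(n, a, d) {
  L <- n * a + (n - 1) * d
  lipid <- 0
  for (i in seq_len(n - 1)) lipid <- lipid + d * L   # vertical channels
  for (j in seq_len(n - 1)) lipid <- lipid + d * L   # horizontal channels
  for (i in seq_len(n - 1)) {                        # double-counted crossings
    for (j in seq_len(n - 1)) lipid <- lipid - d * d
  }
  lipid / (L * L)
}

# Reference patch parameters used across tests (2 cm patch, 20 um bricks,
# 50 nm channels, 10 um brick height).
ref_geom <- function() brick_mortar_geometry(L1 = 0.02, a = 2e-5, d1 = 5e-8,
                                             h_k = 1e-5)

# A short capillary configuration for fast stochastic checks: same radius
# as the reference reduction but one fifth of the diffusion length.
short_cfg <- function(n_particles = 1000, t_end = 0.01, seed = 1L, ...) {
  simulation_config(
    capillary_equivalent(r_h = 1.25e-8, length = 2e-7),
    particle_spec(5e-9), fluid_medium(0.01),
    n_particles = n_particles, t_end = t_end, seed = seed, ...
  )
}

# Pointwise stochastic comparison of a simulated passage curve with exact
# probabilities: inside the 99.73% band, taken as the normal 3-SE band or
# the exact central binomial interval (the latter matters only where the
# normal approximation degenerates, i.e. expected counts near 0 or N).
expect_within_binomial_band <- function(n_passed, p_exact, n) {
  dev <- abs(n_passed / n - p_exact)
  se3 <- 3 * sqrt(p_exact * (1 - p_exact) / n)
  lo <- qbinom(0.00135, n, p_exact)
  hi <- qbinom(0.99865, n, p_exact)
  ok <- (dev <= se3) | (n_passed >= lo & n_passed <= hi)
  expect_true(all(ok),
              label = sprintf("passage curve within 99.73%% band (worst dev %.3g at p %.3g)",
                              max(dev), p_exact[which.max(dev)]))
}
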