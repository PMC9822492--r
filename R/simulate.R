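#' Configure a capillary passage simulation
#'
#' Collects everything needed for one stochastic particle-tracing run:
#' the equivalent capillary, the particle and fluid records, the particle
#' count, end time, time step, recording grid, release position, seed and
#' integration scheme. Finite particle size enters only through the
#' accessible radius `r_acc = r_h - d_p/2` (centre-excluded shell); a
#' particle wider than the capillary is rejected.
#'
#' @param capillary A [capillary_equivalent()].
#' @param particle A [particle_spec()].
#' @param fluid A [fluid_medium()].
#' @param n_particles Number of released particles. Default 5000.
#' @param t_end End time of the simulation, s. Default 500 s.
#' @param dt Time step in seconds, or `"auto"` to use [auto_timestep()].
#' @param record_times Optional ascending grid of recording times, s. By
#'   default 200 logarithmically spaced times from `dt` to `t_end`, plus
#'   `t_end` itself.
#' @param release_offset Release depth of the particle centres below the top
#'   (reflecting) face, m. Default 3e-8 m.
#' @param seed Integer seed; the run is bit-reproducible given the seed.
#' @param scheme `"overdamped"` (default; positions follow pure Brownian
#'   increments) or `"langevin"` (explicit velocity with Stokes drag and the
#'   thermal force of [brownian_force_scale()]).
#' @param absorb_at_contact If `TRUE`, absorption occurs when the particle
#'   *surface* reaches the outlet (plane `length - d_p/2`) instead of the
#'   centre crossing `length` (default).
#' @param lateral_walls If `FALSE`, the cylindrical wall is ignored — a
#'   diagnostic mode used to demonstrate that axial passage is independent
#'   of lateral confinement.
#' @return An object of class `simulation_config`.
#' @seealso [run_simulation()]
#' @export
simulation_config <- function(capillary, particle, fluid,
                              n_particles = 5000, t_end = 500, dt = "auto",
                              record_times = NULL, release_offset = 3e-8,
                              seed = 1L, scheme = c("overdamped", "langevin"),
                              absorb_at_contact = FALSE, lateral_walls = TRUE) {
  stopifnot(inherits(capillary, "capillary_equivalent"),
            inherits(particle, "particle_spec"),
            inherits(fluid, "fluid_medium"))
  scheme <- match.arg(scheme)
  .check_finite_num(n_particles, "n_particles")
  if (n_particles < 1 || n_particles != round(n_particles)) {
    stop("`n_particles` must be a positive integer", call. = FALSE)
  }
  .check_finite_num(t_end, "t_end")
  .check_finite_num(release_offset, "release_offset")
  if (release_offset >= capillary$length) {
    stop("`release_offset` must be smaller than the capillary length", call. = FALSE)
  }
  r_acc <- capillary$r_h - particle$d_p / 2
  if (r_acc <= 0) {
    stop("particle larger than capillary: accessible radius r_h - d_p/2 <= 0",
         call. = FALSE)
  }
  if (!identical(dt, "auto")) .check_finite_num(dt, "dt")
  if (!is.null(record_times)) {
    .check_finite_num(record_times, "record_times", allow_zero = TRUE)
    if (is.unsorted(record_times, strictly = TRUE)) {
      stop("`record_times` must be strictly ascending", call. = FALSE)
    }
  }
  structure(
    list(capillary = capillary, particle = particle, fluid = fluid,
         n_particles = as.integer(n_particles), t_end = t_end, dt = dt,
         record_times = record_times, release_offset = release_offset,
         seed = as.integer(seed), scheme = scheme,
         absorb_at_contact = absorb_at_contact, lateral_walls = lateral_walls,
         r_acc = r_acc),
    class = "simulation_config"
  )
}

#' @export
print.simulation_config <- function(x, ...) {
  cat("<simulation_config>\n")
  cat(sprintf("  d_p = %.3g m, eta = %.3g Pa s, T = %g K\n",
              x$particle$d_p, x$fluid$eta, x$fluid$temperature))
  cat(sprintf("  capillary r_h = %.3g m, length = %.3g m, r_acc = %.3g m\n",
              x$capillary$r_h, x$capillary$length, x$r_acc))
  cat(sprintf("  N = %d, t_end = %g s, dt = %s, scheme = %s, seed = %d\n",
              x$n_particles, x$t_end,
              if (identical(x$dt, "auto")) "auto" else format(x$dt),
              x$scheme, x$seed))
  invisible(x)
}

#' Automatic time step for a configuration
#'
#' Largest `dt` such that the per-axis RMS displacement `sqrt(2 D dt)` does
#' not exceed a fifth of the accessible radius nor a third of the release
#' offset (so wall collisions and the initial condition are resolved), while
#' staying at least 100 momentum relaxation times (so the overdamped limit
#' is valid). A deterministic function of the configuration.
#'
#' @param cfg A [simulation_config()].
#' @return Time step, s.
#' @export
auto_timestep <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  D <- free_diffusion_coefficient(cfg$particle, cfg$fluid)
  s_max <- min(cfg$r_acc / 5, cfg$release_offset / 3)
  dt <- s_max^2 / (2 * D)
  tau <- momentum_relaxation_time(cfg$particle, cfg$fluid)
  if (dt < 100 * tau) {
    stop("infeasible time-step constraints: RMS-step bound requires dt < 100 tau",
         call. = FALSE)
  }
  dt
}

#' One overdamped Brownian step
#'
#' Increments every Cartesian coordinate by `sqrt(2 D dt) * zeta` with
#' `zeta` independent standard normals — equal in law to the thermal force
#' of [brownian_force_scale()] balanced instantaneously by Stokes drag.
#' Exposed for diagnostics and testing; full runs use the compiled kernel
#' in [run_simulation()], which applies the identical rule.
#'
#' @param positions Numeric matrix (n x 3) of particle centres, m.
#' @param D Diffusion coefficient, m^2/s.
#' @param dt Time step, s.
#' @return Updated n x 3 matrix.
#' @export
step_overdamped <- function(positions, D, dt) {
  stopifnot(is.matrix(positions), ncol(positions) == 3)
  positions + sqrt(2 * D * dt) *
    matrix(rnorm(length(positions)), nrow = nrow(positions))
}

#' One Langevin step with Stokes drag
#'
#' Semi-implicit Euler update of the velocity under the stochastic thermal
#' force and Stokes drag, followed by the position update:
#' `v <- (v + (sigma_F dt / m_p) zeta) / (1 + dt/tau)`, `x <- x + v dt`.
#' Converges in law to [step_overdamped()] when `dt >> tau`.
#'
#' @param state List with `pos` and `vel`, each an n x 3 matrix.
#' @param particle A [particle_spec()].
#' @param fluid A [fluid_medium()].
#' @param dt Time step, s.
#' @param thermal If `FALSE` the stochastic force is switched off (pure
#'   drag decay; diagnostic).
#' @return Updated state list.
#' @export
step_langevin <- function(state, particle, fluid, dt, thermal = TRUE) {
  stopifnot(is.list(state), is.matrix(state$pos), is.matrix(state$vel))
  tau <- momentum_relaxation_time(particle, fluid)
  v_kick <- if (thermal) {
    brownian_force_scale(particle, fluid, dt) * dt / particle$m_p
  } else 0
  damp <- 1 + dt / tau
  zeta <- matrix(rnorm(length(state$vel)), nrow = nrow(state$vel))
  vel <- (state$vel + v_kick * zeta) / damp
  list(pos = state$pos + vel * dt, vel = vel)
}

#' Apply capillary boundaries to proposed moves
#'
#' Implements the wall rules of the capillary: if the straight segment from
#' `prev` to `prop` crosses the absorbing plane `z = absorb_plane`, the
#' particle is absorbed (checked before any reflection); otherwise specular
#' reflection is applied at the top plane `z = 0` and, repeatedly, at the
#' cylindrical wall `rho = r_acc` until the endpoint lies inside.
#'
#' @param prev,prop n x 3 matrices of previous and proposed centres; `prev`
#'   must lie inside the accessible cylinder.
#' @param r_acc Accessible radius, m.
#' @param length Capillary length, m.
#' @param absorb_plane Absorbing plane, m; defaults to `length`.
#' @return A list with `pos` (n x 3, surviving rule applied to all rows) and
#'   `absorbed` (logical vector).
#' @export
apply_boundaries <- function(prev, prop, r_acc, length, absorb_plane = length) {
  stopifnot(is.matrix(prev), is.matrix(prop), ncol(prev) == 3, ncol(prop) == 3)
  absorbed <- prop[, 3] >= absorb_plane
  z <- abs(prop[, 3])
  xy <- .reflect_into_cylinder(prev[, 1], prev[, 2], prop[, 1], prop[, 2], r_acc)
  pos <- cbind(xy$x, xy$y, z)
  dimnames(pos) <- NULL
  list(pos = pos, absorbed = absorbed)
}

# Vectorised specular reflection at the cylinder rho = r (2-D projection).
# Near-tangential chords can bounce many times; past the cap the residual
# grazing remainder is terminated on the wall.
.reflect_into_cylinder <- function(px, py, qx, qy, r) {
  r2 <- r * r
  for (bounce in seq_len(512)) {
    out <- which(qx * qx + qy * qy > r2)
    if (length(out) == 0) return(list(x = qx, y = qy))
    ux <- qx[out] - px[out]; uy <- qy[out] - py[out]
    A <- pmax(ux * ux + uy * uy, .Machine$double.xmin)
    B <- 2 * (px[out] * ux + py[out] * uy)
    C <- pmin(px[out]^2 + py[out]^2 - r2, 0)  # p may sit epsilon outside
    t <- pmin(pmax((-B + sqrt(pmax(B * B - 4 * A * C, 0))) / (2 * A), 0), 1)
    hx <- px[out] + t * ux; hy <- py[out] + t * uy
    hn <- pmax(sqrt(hx * hx + hy * hy), .Machine$double.xmin)
    hx <- hx * r / hn; hy <- hy * r / hn  # renormalise onto the wall
    nx <- hx / r; ny <- hy / r
    wx <- qx[out] - hx; wy <- qy[out] - hy
    wn <- wx * nx + wy * ny
    qx[out] <- hx + wx - 2 * wn * nx
    qy[out] <- hy + wy - 2 * wn * ny
    px[out] <- hx; py[out] <- hy
  }
  out <- which(qx * qx + qy * qy > r2)
  qn <- sqrt(qx[out]^2 + qy[out]^2)
  if (any(qn > 1.1 * r)) {
    stop("reflection loop did not converge (>512 bounces); offending rows: ",
         paste(utils::head(out[qn > 1.1 * r], 5), collapse = ", "),
         call. = FALSE)
  }
  s <- r * (1 - 1e-12) / qn
  qx[out] <- qx[out] * s; qy[out] <- qy[out] * s
  list(x = qx, y = qy)
}

#' Run a capillary passage simulation
#'
#' Releases `n_particles` with centres at depth `release_offset` below the
#' reflecting top face, laterally uniform over the accessible disk, and
#' integrates Brownian (or Langevin) dynamics with specular side/top walls
#' and an absorbing outlet until `t_end`. The cumulative number of absorbed
#' particles is recorded on the recording grid. Fully reproducible from the
#' seed: particles are simulated in a fixed order from one seeded generator.
#'
#' @param cfg A [simulation_config()].
#' @return A tibble of class `passage_curve` with columns `time_s`,
#'   `time_norm` (`time_s / t_end`), `n_passed` and `fraction`
#'   (`n_passed / n_particles`). Attributes: `config`, `dt`, `n_p0` and
#'   `absorption_times` (per-particle first-passage times, `NA` for
#'   particles still active at `t_end`).
#' @export
#' @examples
#' cap <- capillary_equivalent(r_h = 1.25e-8, length = 2e-7)
#' cfg <- simulation_config(cap, particle_spec(5e-9), fluid_medium(0.01),
#'                          n_particles = 200, t_end = 0.05, seed = 42)
#' curve <- run_simulation(cfg)
#' tail(curve, 3)
run_simulation <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  dt <- if (identical(cfg$dt, "auto")) auto_timestep(cfg) else cfg$dt
  n_steps <- ceiling(cfg$t_end / dt)
  D <- free_diffusion_coefficient(cfg$particle, cfg$fluid)
  absorb_plane <- if (isTRUE(cfg$absorb_at_contact)) {
    cfg$capillary$length - cfg$particle$d_p / 2
  } else {
    cfg$capillary$length
  }
  if (absorb_plane <= cfg$release_offset) {
    stop("absorbing plane lies at or above the release position", call. = FALSE)
  }
  langevin <- identical(cfg$scheme, "langevin")
  v_kick <- damp <- 0
  if (langevin) {
    v_kick <- brownian_force_scale(cfg$particle, cfg$fluid, dt) * dt / cfg$particle$m_p
    damp <- 1 + dt / momentum_relaxation_time(cfg$particle, cfg$fluid)
  }
  set.seed(cfg$seed)
  fpt <- cpp_simulate_fpt(cfg$n_particles, cfg$r_acc, cfg$release_offset,
                          absorb_plane, dt, n_steps, sqrt(2 * D * dt),
                          langevin, v_kick, damp, isTRUE(cfg$lateral_walls))
  times <- cfg$record_times
  if (is.null(times)) {
    times <- unique(c(exp(seq(log(dt), log(cfg$t_end), length.out = 200)),
                      cfg$t_end))
  }
  sorted <- sort(fpt[!is.na(fpt)])
  n_passed <- findInterval(times, sorted)
  out <- tibble::tibble(
    time_s = times,
    time_norm = times / cfg$t_end,
    n_passed = n_passed,
    fraction = n_passed / cfg$n_particles
  )
  class(out) <- c("passage_curve", class(out))
  attr(out, "config") <- cfg
  attr(out, "dt") <- dt
  attr(out, "n_p0") <- cfg$n_particles
  attr(out, "absorption_times") <- fpt
  out
}

#' Analytic first-passage fraction in a reflecting--absorbing interval
#'
#' Closed-form cumulative passage fraction for one-dimensional diffusion on
#' `[0, length]` with a reflecting boundary at 0 and an absorbing boundary
#' at `length`, starting from `x0`. The survival probability is the
#' eigenfunction series
#' \deqn{S(t) = \sum_{k \ge 0} \frac{4(-1)^k}{(2k+1)\pi}
#'   \cos\!\Big(\frac{(2k+1)\pi x_0}{2 L}\Big)
#'   \exp\!\Big(-\frac{D (2k+1)^2 \pi^2 t}{4 L^2}\Big)}
#' and the passage fraction is `1 - S(t)`. The series is truncated when the
#' next term falls below 1e-12. Because axial motion in the capillary is
#' independent of the lateral reflections, this is an exact reference for
#' the simulated passage law at any particle size.
#'
#' @param t Time(s), s. Vectorised.
#' @param D Diffusion coefficient, m^2/s.
#' @param length Interval length, m.
#' @param x0 Starting position, m, in `[0, length)`.
#' @return Passage fraction(s) in `[0, 1]`.
#' @seealso [mean_first_passage_time()]
#' @export
first_passage_fraction <- function(t, D, length, x0) {
  .check_finite_num(D, "D")
  .check_finite_num(length, "length")
  .check_finite_num(x0, "x0", allow_zero = TRUE)
  if (x0 >= length) stop("`x0` must lie in [0, length)", call. = FALSE)
  vapply(t, function(tt) {
    if (tt <= 0) return(0)
    rate <- D * pi^2 * tt / (4 * length^2)
    S <- 0
    k <- 0
    repeat {
      m <- 2 * k + 1
      decay <- 4 / (m * pi) * exp(-m^2 * rate)
      S <- S + (-1)^k * decay * cos(m * pi * x0 / (2 * length))
      # truncate on the cos-free envelope so a single small cosine cannot
      # end the series early
      if (decay < 1e-12 || k > 1e6) break
      k <- k + 1
    }
    min(max(1 - S, 0), 1)
  }, numeric(1))
}

#' Mean first-passage time for the reflecting--absorbing interval
#'
#' Closed form `(length^2 - x0^2) / (2 D)` for diffusion started at `x0`
#' with a reflecting boundary at 0 and absorption at `length`.
#'
#' @inheritParams first_passage_fraction
#' @return Mean first-passage time, s.
#' @export
mean_first_passage_time <- function(D, length, x0) {
  (length^2 - x0^2) / (2 * D)
}
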