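#' Nanoparticle specification
#'
#' A spherical nanoparticle of diameter `d_p` and material density `rho_p`.
#' The mass is derived from the sphere volume, `m_p = rho_p * pi * d_p^3 / 6`.
#' The default density (2200 kg/m^3) is typical for mineral powders such as
#' silica.
#'
#' @param d_p Particle diameter, m.
#' @param rho_p Particle density, kg/m^3.
#' @return An object of class `particle_spec` with fields `d_p`, `rho_p`, `m_p`.
#' @export
#' @examples
#' particle_spec(5e-9)
particle_spec <- function(d_p, rho_p = 2200) {
  .check_finite_num(d_p, "d_p")
  .check_finite_num(rho_p, "rho_p")
  structure(
    list(d_p = d_p, rho_p = rho_p, m_p = rho_p * pi * d_p^3 / 6),
    class = "particle_spec"
  )
}

#' @export
print.particle_spec <- function(x, ...) {
  cat(sprintf("<particle_spec> d_p = %.3g m, rho_p = %.4g kg/m^3, m_p = %.4g kg\n",
              x$d_p, x$rho_p, x$m_p))
  invisible(x)
}

#' Fluid medium
#'
#' The liquid filling the lipid channel: dynamic viscosity `eta`, density
#' `rho_f` and absolute temperature. Thermal formulas use the Boltzmann
#' constant [boltzmann_constant()], `1.381e-23` J/K.
#'
#' @param eta Dynamic viscosity, Pa s (10 mPa s = 0.01 Pa s).
#' @param rho_f Fluid density, kg/m^3.
#' @param temperature Absolute temperature, K. Default 298 K; the
#'   Stokes-Einstein comparison table pipeline pins 293 K (see
#'   [build_comparison()]).
#' @return An object of class `fluid_medium`.
#' @export
#' @examples
#' fluid_medium(0.01)
fluid_medium <- function(eta, rho_f = 1000, temperature = 298) {
  .check_finite_num(eta, "eta")
  .check_finite_num(rho_f, "rho_f")
  .check_finite_num(temperature, "temperature")
  structure(
    list(eta = eta, rho_f = rho_f, temperature = temperature),
    class = "fluid_medium"
  )
}

#' @export
print.fluid_medium <- function(x, ...) {
  cat(sprintf("<fluid_medium> eta = %.3g Pa s, rho_f = %.4g kg/m^3, T = %g K\n",
              x$eta, x$rho_f, x$temperature))
  invisible(x)
}

#' Stokes drag coefficient
#'
#' Drag coefficient of a sphere in creeping flow, `gamma = 3 pi eta d_p`, so
#' the drag force on a particle moving at velocity `v` is `gamma * v`.
#' Algebraically identical to `18 eta m_p / (rho_p d_p^2)` when
#' `m_p = rho_p pi d_p^3 / 6`, i.e. the mass-based form of the same law.
#'
#' @param particle A [particle_spec()].
#' @param fluid A [fluid_medium()].
#' @return Drag coefficient, kg/s.
#' @export
drag_coefficient <- function(particle, fluid) {
  stopifnot(inherits(particle, "particle_spec"), inherits(fluid, "fluid_medium"))
  3 * pi * fluid$eta * particle$d_p
}

#' Brownian force scale
#'
#' Standard deviation of the stochastic thermal force applied per Cartesian
#' component per time step in the Langevin scheme:
#' `sigma_F = sqrt(6 pi k_B eta T d_p / dt)`. The force at each step is
#' `zeta * sigma_F` with `zeta` an independent standard-normal draw per
#' component; this convention closes the fluctuation-dissipation balance
#' exactly: `(sigma_F dt / gamma)^2 = 2 D dt` with `D` the free diffusion
#' coefficient.
#'
#' @inheritParams drag_coefficient
#' @param dt Time step, s.
#' @return Force scale, N.
#' @export
brownian_force_scale <- function(particle, fluid, dt) {
  stopifnot(inherits(particle, "particle_spec"), inherits(fluid, "fluid_medium"))
  .check_finite_num(dt, "dt")
  sqrt(6 * pi * .kB * fluid$eta * fluid$temperature * particle$d_p / dt)
}

#' Free diffusion coefficient realised by the dynamics
#'
#' Einstein relation `D = k_B T / gamma = k_B T / (3 pi eta d_p)`. This is
#' the diffusion coefficient the simulated Brownian dynamics actually
#' realises, and coincides with the standard Stokes-Einstein expression
#' `k_B T / (6 pi eta r)` written with the particle radius.
#'
#' @inheritParams drag_coefficient
#' @return Diffusion coefficient, m^2/s.
#' @export
#' @examples
#' free_diffusion_coefficient(particle_spec(5e-9), fluid_medium(0.01))
free_diffusion_coefficient <- function(particle, fluid) {
  .kB * fluid$temperature / drag_coefficient(particle, fluid)
}

#' Diameter-form Stokes-Einstein coefficient
#'
#' Evaluates `D = k_B T / (6 pi eta d_p)` with the particle *diameter* in
#' the denominator. This diameter-form convention (half the standard
#' radius-form value) is kept as a separately named operation because the
#' reference comparison tables this package reproduces were computed with
#' it; use [free_diffusion_coefficient()] for the physical free diffusion
#' coefficient.
#'
#' @inheritParams drag_coefficient
#' @return Diffusion coefficient, m^2/s.
#' @export
stokes_einstein_printed <- function(particle, fluid) {
  .kB * fluid$temperature / (6 * pi * fluid$eta * particle$d_p)
}

#' Momentum relaxation time
#'
#' Time constant of velocity decay under Stokes drag,
#' `tau = m_p / gamma = rho_p d_p^2 / (18 eta)`. For nanoparticles in the
#' viscosities considered here tau is of order 1e-13 s, at least six orders
#' of magnitude below any feasible simulation step, which is what licenses
#' the overdamped (position-only) integrator as the default scheme.
#'
#' @inheritParams drag_coefficient
#' @return Relaxation time, s.
#' @export
momentum_relaxation_time <- function(particle, fluid) {
  stopifnot(inherits(particle, "particle_spec"), inherits(fluid, "fluid_medium"))
  particle$rho_p * particle$d_p^2 / (18 * fluid$eta)
}
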