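#' Specify a diameter-by-viscosity sweep
#'
#' Declares the grid of particle diameters and fluid viscosities to
#' simulate, together with the shared geometry, capillary length, fitting
#' length and simulation template. Default grid and conditions follow the
#' reference parameter set: diameters 1, 5, 10, 15 nm; viscosities 10, 20,
#' 50 mPa s; density 2200 kg/m^3 particles in a 1000 kg/m^3 fluid.
#'
#' With `t_end = "auto"`, each cell runs to 20 times its analytic mean
#' first-passage time — a desk-scale surrogate for a single long end time
#' that allocates simulation effort where the slow cells need it. Set
#' `t_end` to a number (e.g. 500) for a fixed horizon.
#'
#' @param diameters Particle diameters, m.
#' @param viscosities Dynamic viscosities, Pa s.
#' @param geometry A [brick_mortar_geometry()].
#' @param cap_length Capillary length, m.
#' @param n_particles Particles per cell.
#' @param t_end `"auto"` or end time in s.
#' @param rho_p,rho_f Particle and fluid densities, kg/m^3.
#' @param temperature Fluid temperature, K.
#' @param seed Base seed; cell `i` uses `seed + i`.
#' @param scheme Integration scheme, see [simulation_config()].
#' @param h_fit Diffusion length fixed in the Hill fit, m.
#' @return An object of class `sweep_spec`.
#' @export
sweep_spec <- function(diameters = c(1, 5, 10, 15) * 1e-9,
                       viscosities = c(10, 20, 50) * 1e-3,
                       geometry = brick_mortar_geometry(),
                       cap_length = 1e-6, n_particles = 1000,
                       t_end = "auto", rho_p = 2200, rho_f = 1000,
                       temperature = 298, seed = 1L,
                       scheme = "overdamped", h_fit = 1e-6) {
  if (length(diameters) == 0 || length(viscosities) == 0) {
    stop("`diameters` and `viscosities` must be non-empty", call. = FALSE)
  }
  .check_finite_num(diameters, "diameters")
  .check_finite_num(viscosities, "viscosities")
  .check_finite_num(cap_length, "cap_length")
  .check_finite_num(h_fit, "h_fit")
  if (!identical(t_end, "auto")) .check_finite_num(t_end, "t_end")
  stopifnot(inherits(geometry, "brick_mortar_geometry"))
  structure(
    list(diameters = diameters, viscosities = viscosities, geometry = geometry,
         cap_length = cap_length, n_particles = as.integer(n_particles),
         t_end = t_end, rho_p = rho_p, rho_f = rho_f,
         temperature = temperature, seed = as.integer(seed),
         scheme = scheme, h_fit = h_fit),
    class = "sweep_spec"
  )
}

#' @export
print.sweep_spec <- function(x, ...) {
  cat("<sweep_spec>\n")
  cat("  d_p [nm]:", paste(x$diameters * 1e9, collapse = ", "), "\n")
  cat("  eta [mPa s]:", paste(x$viscosities * 1e3, collapse = ", "), "\n")
  cat(sprintf("  N = %d per cell, t_end = %s, T = %g K, seed = %d\n",
              x$n_particles,
              if (identical(x$t_end, "auto")) "auto (20 x MFPT)" else format(x$t_end),
              x$temperature, x$seed))
  invisible(x)
}

#' Run a diameter-by-viscosity sweep
#'
#' For every grid cell: builds the particle/fluid records, simulates the
#' passage curve in the equivalent capillary and fits the Hill model with
#' the fixed diffusion length `h_fit`. Cells whose particle does not fit in
#' the capillary (`r_h - d_p/2 <= 0`) are reported as skipped rather than
#' failing the sweep. Deterministic given the spec's seed.
#'
#' @param spec A [sweep_spec()].
#' @param out_dir Optional directory; when given, writes `table1.csv`
#'   (columns `d_p_nm`, `eta_mPas`, `D_eff_m2_per_s`, `n`, `r_squared`),
#'   one curve CSV per cell (`time_s,time_norm,n_passed,fraction`) with a
#'   JSON sidecar echoing the cell configuration, and a plain-text
#'   `run.log`.
#' @param verbose Emit one progress message per cell.
#' @return A tibble with one row per cell: `d_p`, `eta`, `D_eff`, `n`,
#'   `r_squared`, `converged`, `t_end`, `seed`, `skipped` (reason or `NA`).
#' @export
run_sweep <- function(spec, out_dir = NULL, verbose = FALSE) {
  stopifnot(inherits(spec, "sweep_spec"))
  cap <- build_capillary(spec$geometry, length = spec$cap_length)
  grid <- tidyr::expand_grid(d_p = spec$diameters, eta = spec$viscosities)
  t0 <- Sys.time()
  curves <- vector("list", nrow(grid))
  rows <- purrr::pmap(
    list(grid$d_p, grid$eta, seq_len(nrow(grid))),
    function(d_p, eta, i) {
      particle <- particle_spec(d_p, rho_p = spec$rho_p)
      fl <- fluid_medium(eta, rho_f = spec$rho_f, temperature = spec$temperature)
      if (cap$r_h - d_p / 2 <= 0) {
        if (verbose) message(sprintf("cell %d (d_p=%g nm, eta=%g mPa s): skipped",
                                     i, d_p * 1e9, eta * 1e3))
        return(tibble::tibble(d_p = d_p, eta = eta, D_eff = NA_real_,
                              n = NA_real_, r_squared = NA_real_,
                              converged = NA, t_end = NA_real_,
                              seed = spec$seed + i,
                              skipped = "particle larger than capillary"))
      }
      t_end <- if (identical(spec$t_end, "auto")) {
        D <- free_diffusion_coefficient(particle, fl)
        20 * mean_first_passage_time(D, cap$length, 3e-8)
      } else spec$t_end
      cfg <- simulation_config(cap, particle, fl,
                               n_particles = spec$n_particles, t_end = t_end,
                               seed = spec$seed + i, scheme = spec$scheme)
      curve <- run_simulation(cfg)
      curves[[i]] <<- curve
      fit <- fit_hill(curve, h = spec$h_fit)
      if (verbose) {
        message(sprintf("cell %d (d_p=%g nm, eta=%g mPa s): D_eff=%.3g, n=%.3g, R2=%.4f",
                        i, d_p * 1e9, eta * 1e3, fit$D_eff, fit$n, fit$r_squared))
      }
      tibble::tibble(d_p = d_p, eta = eta, D_eff = fit$D_eff, n = fit$n,
                     r_squared = fit$r_squared, converged = fit$converged,
                     t_end = t_end, seed = spec$seed + i, skipped = NA_character_)
    }
  )
  out <- dplyr::bind_rows(rows)
  if (!is.null(out_dir)) {
    .write_sweep_outputs(spec, out, curves, out_dir, t0)
  }
  out
}

.write_sweep_outputs <- function(spec, out, curves, out_dir, t0) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  table1 <- out |>
    dplyr::transmute(d_p_nm = .data$d_p * 1e9, eta_mPas = .data$eta * 1e3,
                     D_eff_m2_per_s = .data$D_eff, n = .data$n,
                     r_squared = .data$r_squared)
  write.csv(table1, file.path(out_dir, "table1.csv"), row.names = FALSE)
  for (i in seq_along(curves)) {
    if (is.null(curves[[i]])) next
    stem <- sprintf("curve_dp%gnm_eta%gmPas", out$d_p[i] * 1e9, out$eta[i] * 1e3)
    write.csv(as.data.frame(curves[[i]]), file.path(out_dir, paste0(stem, ".csv")),
              row.names = FALSE)
    cfg <- attr(curves[[i]], "config")
    jsonlite::write_json(
      list(d_p_m = cfg$particle$d_p, rho_p_kg_m3 = cfg$particle$rho_p,
           eta_Pa_s = cfg$fluid$eta, temperature_K = cfg$fluid$temperature,
           r_h_m = cfg$capillary$r_h, length_m = cfg$capillary$length,
           n_particles = cfg$n_particles, t_end_s = cfg$t_end,
           dt_s = attr(curves[[i]], "dt"), seed = cfg$seed,
           scheme = cfg$scheme),
      file.path(out_dir, paste0(stem, ".json")), auto_unbox = TRUE, digits = NA)
  }
  log_lines <- c(
    sprintf("corneocap %s sweep", as.character(packageVersion("corneocap"))),
    sprintf("base seed: %d", spec$seed),
    sprintf("grid: d_p [nm] = %s; eta [mPa s] = %s",
            paste(spec$diameters * 1e9, collapse = ","),
            paste(spec$viscosities * 1e3, collapse = ",")),
    sprintf("n_particles per cell: %d; t_end: %s; T: %g K",
            spec$n_particles,
            if (identical(spec$t_end, "auto")) "auto (20 x MFPT)" else format(spec$t_end),
            spec$temperature),
    sprintf("wall clock: %.1f s", as.numeric(difftime(Sys.time(), t0, units = "secs")))
  )
  writeLines(log_lines, file.path(out_dir, "run.log"))
}

#' Compare fitted effective diffusion with the Stokes-Einstein prediction
#'
#' Adds, to a table of fitted `(d_p, eta, D_eff)` rows, the diameter-form
#' Stokes-Einstein coefficient [stokes_einstein_printed()] evaluated at the
#' given temperature and the ratio `D / D_eff`. The default temperature is
#' 293 K, the value the reference comparison table is numerically
#' consistent with (the surrounding text states 298 K; the two readings
#' differ by 1.7%).
#'
#' @param fits Data frame with columns `d_p` (m), `eta` (Pa s) and `D_eff`
#'   (m^2/s); e.g. the output of [run_sweep()] or [reference_fit_table()].
#' @param temperature Temperature for the Stokes-Einstein evaluation, K.
#' @return The input tibble with columns `D` (m^2/s) and `ratio`
#'   (`D / D_eff`) appended.
#' @export
#' @examples
#' build_comparison(reference_fit_table())
build_comparison <- function(fits, temperature = 293) {
  stopifnot(is.data.frame(fits), all(c("d_p", "eta", "D_eff") %in% names(fits)))
  if (any(!is.na(fits$D_eff) & fits$D_eff <= 0)) {
    stop("all `D_eff` values must be positive", call. = FALSE)
  }
  fits |>
    tibble::as_tibble() |>
    dplyr::mutate(
      D = purrr::map2_dbl(.data$d_p, .data$eta, function(dp, et) {
        stokes_einstein_printed(particle_spec(dp), fluid_medium(et, temperature = temperature))
      }),
      ratio = .data$D / .data$D_eff
    )
}

# config files ----------------------------------------------------------------

.config_keys <- c("diameters_nm", "diameters_m", "viscosities_mPas",
                  "viscosities_Pa_s", "n_particles", "t_end_s",
                  "temperature_K", "rho_p_kg_m3", "rho_f_kg_m3", "seed",
                  "cap_length_m", "h_fit_m", "scheme", "geometry")
.geometry_keys <- c("L1_m", "L2_m", "a_m", "b_m", "d1_m", "d2_m", "h_k_m")

#' Read a sweep specification from a YAML config
#'
#' Parses a declarative sweep configuration with explicit units in the key
#' names (`diameters_nm` or `diameters_m`; `viscosities_mPas` or
#' `viscosities_Pa_s`; lengths in m). Unknown keys are a validation error,
#' as are ambiguous or invalid values; the resolved specification is
#' returned as a [sweep_spec()]. A packaged example with the reference
#' conditions ships at
#' `system.file("extdata", "default_sweep.yaml", package = "corneocap")`.
#'
#' @param path Path to a YAML file.
#' @return A [sweep_spec()].
#' @seealso [save_config()]
#' @export
load_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  unknown <- setdiff(names(cfg), .config_keys)
  if (length(unknown) > 0) {
    stop("unknown config keys: ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (!is.null(cfg$geometry)) {
    bad <- setdiff(names(cfg$geometry), .geometry_keys)
    if (length(bad) > 0) {
      stop("unknown geometry keys: ", paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  if (!is.null(cfg$diameters_nm) && !is.null(cfg$diameters_m)) {
    stop("give diameters in exactly one unit (diameters_nm or diameters_m)",
         call. = FALSE)
  }
  if (is.null(cfg$diameters_nm) && is.null(cfg$diameters_m)) {
    stop("missing diameters (diameters_nm or diameters_m)", call. = FALSE)
  }
  if (!is.null(cfg$viscosities_mPas) && !is.null(cfg$viscosities_Pa_s)) {
    stop("give viscosities in exactly one unit (viscosities_mPas or viscosities_Pa_s)",
         call. = FALSE)
  }
  if (is.null(cfg$viscosities_mPas) && is.null(cfg$viscosities_Pa_s)) {
    stop("missing viscosities (viscosities_mPas or viscosities_Pa_s)", call. = FALSE)
  }
  diameters <- if (!is.null(cfg$diameters_nm)) unlist(cfg$diameters_nm) * 1e-9
               else unlist(cfg$diameters_m)
  viscosities <- if (!is.null(cfg$viscosities_mPas)) unlist(cfg$viscosities_mPas) * 1e-3
                 else unlist(cfg$viscosities_Pa_s)
  g <- cfg$geometry
  geometry <- if (is.null(g)) brick_mortar_geometry() else {
    brick_mortar_geometry(
      L1 = g$L1_m %||% 0.02, L2 = g$L2_m %||% g$L1_m %||% 0.02,
      a = g$a_m %||% 2e-5, b = g$b_m %||% g$a_m %||% 2e-5,
      d1 = g$d1_m %||% 5e-8, d2 = g$d2_m %||% g$d1_m %||% 5e-8,
      h_k = g$h_k_m %||% 1e-5
    )
  }
  sweep_spec(
    diameters = diameters, viscosities = viscosities, geometry = geometry,
    cap_length = cfg$cap_length_m %||% 1e-6,
    n_particles = cfg$n_particles %||% 1000,
    t_end = cfg$t_end_s %||% "auto",
    rho_p = cfg$rho_p_kg_m3 %||% 2200,
    rho_f = cfg$rho_f_kg_m3 %||% 1000,
    temperature = cfg$temperature_K %||% 298,
    seed = cfg$seed %||% 1L,
    scheme = cfg$scheme %||% "overdamped",
    h_fit = cfg$h_fit_m %||% 1e-6
  )
}

#' Write a sweep specification to a YAML config
#'
#' Inverse of [load_config()]: serialises a [sweep_spec()] with explicit
#' units so that `load_config(save_config(spec, path))` round-trips.
#'
#' @param spec A [sweep_spec()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_config <- function(spec, path) {
  stopifnot(inherits(spec, "sweep_spec"))
  g <- spec$geometry
  yaml::write_yaml(list(
    diameters_nm = spec$diameters * 1e9,
    viscosities_mPas = spec$viscosities * 1e3,
    n_particles = spec$n_particles,
    t_end_s = if (identical(spec$t_end, "auto")) "auto" else spec$t_end,
    temperature_K = spec$temperature,
    rho_p_kg_m3 = spec$rho_p,
    rho_f_kg_m3 = spec$rho_f,
    seed = spec$seed,
    cap_length_m = spec$cap_length,
    h_fit_m = spec$h_fit,
    scheme = spec$scheme,
    geometry = list(L1_m = g$L1, L2_m = g$L2, a_m = g$a, b_m = g$b,
                    d1_m = g$d1, d2_m = g$d2, h_k_m = g$h_k)
  ), path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
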