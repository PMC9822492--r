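#' Hill-form passage fraction
#'
#' The saturation model derived from Fick's first law for the cumulative
#' passage fraction through a channel of diffusion length `h`:
#' \deqn{F(t) = \frac{D_{eff}\, t^n}{h^2 + D_{eff}\, t^n}}
#' With `n = 1` this is the plain Fickian balance; the empirical exponent
#' `n` absorbs the shape of the simulated curves. `F` is strictly
#' increasing in `t` and tends to 1.
#'
#' @param t Time(s), s. Vectorised.
#' @param D_eff Effective diffusion coefficient, m^2/s.
#' @param n Hill exponent (dimensionless, > 0).
#' @param h Diffusion length, m.
#' @return Fraction(s) in `[0, 1)`.
#' @export
#' @examples
#' hill_fraction(500, D_eff = 8.96e-13, n = 0.557, h = 1e-6)
hill_fraction <- function(t, D_eff, n, h) {
  .check_finite_num(D_eff, "D_eff")
  .check_finite_num(n, "n")
  .check_finite_num(h, "h")
  .check_finite_num(t, "t", allow_zero = TRUE)
  x <- D_eff * t^n
  x / (h^2 + x)
}

#' Linearised initial estimates for the Hill fit
#'
#' Least squares on the exact linearisation of the Hill form,
#' `log(F / (1 - F)) = log(D_eff / h^2) + n log(t)`, over interior points
#' (`0 < fraction < 1`, `t > 0`), weighted by `(F (1 - F))^2` — the
#' delta-method precision of the logit under additive noise on the fraction
#' scale, which stops near-saturated points from dominating. On noiseless
#' Hill data the transform is exactly linear, so the estimates are exact;
#' on noisy data they serve as starting values for [fit_hill()].
#'
#' @param curve A data frame with columns `time_s` and `fraction` (e.g. a
#'   `passage_curve`).
#' @param h Diffusion length, m (fixed).
#' @return Named numeric vector `c(D_eff = ..., n = ...)`, both positive.
#' @export
linearized_init <- function(curve, h) {
  .check_finite_num(h, "h")
  stopifnot(is.data.frame(curve), all(c("time_s", "fraction") %in% names(curve)))
  keep <- curve$fraction > 0 & curve$fraction < 1 & curve$time_s > 0
  if (sum(keep) < 3) {
    stop("need at least 3 interior points (0 < fraction < 1) for initialisation",
         call. = FALSE)
  }
  x <- log(curve$time_s[keep])
  f <- curve$fraction[keep]
  y <- log(f / (1 - f))
  co <- coef(lm(y ~ x, weights = (f * (1 - f))^2))
  n0 <- min(max(unname(co[2]), 1e-3), 5)
  D0 <- exp(unname(co[1])) * h^2
  c(D_eff = max(D0, .Machine$double.xmin), n = n0)
}

#' Fit the Hill passage model to a curve
#'
#' Bounded nonlinear least squares (Levenberg--Marquardt via
#' \pkg{minpack.lm}) of [hill_fraction()] to a passage curve, with `D_eff`
#' and `n` free and the diffusion length `h` fixed (a third free length
#' parameter would be degenerate with `D_eff` in this functional form).
#' The fit is performed unweighted on the fraction scale; points with
#' fraction exactly 0 or 1 are retained (they are excluded only from the
#' linearised initialiser). Non-convergence is flagged on the returned
#' object, not raised.
#'
#' @inheritParams linearized_init
#' @param h Diffusion length, m, fixed during fitting. Default 1e-6 m.
#' @return An object of class `hill_fit`: list with `D_eff`, `n`, `h`,
#'   `r_squared` (computed as `1 - SS_res/SS_tot` on the fraction scale),
#'   `residual_norm`, `converged`, `n_obs`, the underlying `nls` object
#'   (`fit`, `NULL` if the optimiser failed) and the fitted `data`.
#' @seealso [tidy.hill_fit()], [glance.hill_fit()], [autoplot.hill_fit()]
#' @export
#' @examples
#' curve <- generate_hill_curve(5e-13, 0.8, 1e-6,
#'                              times = exp(seq(log(0.01), log(500), length.out = 80)))
#' fit <- fit_hill(curve, h = 1e-6)
#' fit$D_eff
#' glance(fit)
fit_hill <- function(curve, h = 1e-6) {
  .check_finite_num(h, "h")
  stopifnot(is.data.frame(curve), all(c("time_s", "fraction") %in% names(curve)))
  df <- data.frame(t = curve$time_s, f = curve$fraction)
  df <- df[df$t > 0, , drop = FALSE]
  init <- linearized_init(curve, h)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      f ~ D * t^n / (h^2 + D * t^n),
      data = df,
      start = list(D = unname(init["D_eff"]), n = unname(init["n"])),
      lower = c(D = 1e-300, n = 1e-6),
      upper = c(D = Inf, n = 5),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    D_eff <- unname(init["D_eff"]); nn <- unname(init["n"]); converged <- FALSE
  } else {
    co <- coef(fit)
    D_eff <- unname(co["D"]); nn <- unname(co["n"])
    converged <- isTRUE(fit$convInfo$isConv)
  }
  fhat <- hill_fraction(df$t, D_eff, nn, h)
  ss_res <- sum((df$f - fhat)^2)
  ss_tot <- sum((df$f - mean(df$f))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else if (ss_res == 0) 1 else NA_real_
  structure(
    list(D_eff = D_eff, n = nn, h = h, r_squared = r2,
         residual_norm = sqrt(ss_res), converged = converged,
         n_obs = nrow(df), fit = fit, data = df),
    class = "hill_fit"
  )
}

#' @export
print.hill_fit <- function(x, ...) {
  cat("<hill_fit>\n")
  cat(sprintf("  D_eff = %.4g m^2/s, n = %.4g (h fixed at %.3g m)\n",
              x$D_eff, x$n, x$h))
  cat(sprintf("  R^2 = %.6g, residual norm = %.3g, converged = %s, n = %d points\n",
              x$r_squared, x$residual_norm, x$converged, x$n_obs))
  invisible(x)
}

#' Generate a synthetic Hill passage curve
#'
#' Evaluates [hill_fraction()] on a time grid, optionally adds independent
#' Gaussian noise, clips to `[0, 1]` and enforces monotonicity of the
#' cumulative record by a running maximum. Used as a controlled fixture
#' for fit validation; reproducible from the seed.
#'
#' @inheritParams hill_fraction
#' @param times Ascending time grid, s.
#' @param noise_sd Standard deviation of additive noise on the fraction
#'   scale (0 for exact values).
#' @param seed Optional integer seed.
#' @param n_p0 Nominal initial particle count used to form the integer
#'   `n_passed` column. Default 5000.
#' @return A `passage_curve` tibble (columns `time_s`, `time_norm`,
#'   `n_passed`, `fraction`).
#' @export
generate_hill_curve <- function(D_eff, n, h, times, noise_sd = 0, seed = NULL,
                                n_p0 = 5000) {
  .check_finite_num(times, "times", allow_zero = TRUE)
  .check_finite_num(noise_sd, "noise_sd", allow_zero = TRUE)
  if (!is.null(seed)) set.seed(seed)
  f <- hill_fraction(times, D_eff, n, h)
  if (noise_sd > 0) f <- f + rnorm(length(f), sd = noise_sd)
  f <- cummax(pmin(pmax(f, 0), 1))
  out <- tibble::tibble(
    time_s = times,
    time_norm = times / max(times),
    n_passed = round(f * n_p0),
    fraction = f
  )
  class(out) <- c("passage_curve", class(out))
  attr(out, "n_p0") <- n_p0
  out
}
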