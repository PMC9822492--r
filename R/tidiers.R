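#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy and summarise fitted objects
#'
#' `tidy()` on a `hill_fit` returns one row per fitted parameter (`D_eff`,
#' `n`) with standard errors when the optimiser produced them;
#' `glance()` returns the one-row fit summary; `tidy()` on a
#' `capillary_equivalent` returns its derived quantities as one row.
#'
#' @param x A `hill_fit` or `capillary_equivalent` object.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.hill_fit <- function(x, ...) {
  se <- c(NA_real_, NA_real_)
  if (!is.null(x$fit)) {
    se <- tryCatch(summary(x$fit)$coefficients[, "Std. Error"],
                   error = function(e) se)
  }
  tibble::tibble(
    term = c("D_eff", "n"),
    estimate = c(x$D_eff, x$n),
    std.error = unname(se)
  )
}

#' @rdname tidy.hill_fit
#' @export
glance.hill_fit <- function(x, ...) {
  tibble::tibble(
    r.squared = x$r_squared,
    residual.norm = x$residual_norm,
    converged = x$converged,
    nobs = x$n_obs,
    h = x$h
  )
}
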