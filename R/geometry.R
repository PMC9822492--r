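#' Brick-and-mortar stratum-corneum geometry
#'
#' Describes a rectangular patch of stratum corneum of size `L1` x `L2`
#' tiled by keratinocyte "bricks" of footprint `a` x `b` and height `h_k`,
#' separated by lipid channels ("mortar") of widths `d1` (along `L1`) and
#' `d2` (along `L2`). All dimensions are in metres. The defaults are the
#' reference parameter set used throughout the package: a 2 cm square patch,
#' 20 um square keratinocytes, 50 nm lipid channels and a 10 um keratinocyte
#' layer.
#'
#' The number of keratinocytes per direction is kept real-valued (the
#' closed-form area algebra assumes the exact ratio `(L + d)/(a + d)`), so
#' `L1`/`L2` need not be integer multiples of the brick pitch.
#'
#' @param L1,L2 Patch length and width, m.
#' @param a,b Keratinocyte footprint dimensions along `L1` and `L2`, m.
#' @param d1,d2 Lipid-channel widths along `L1` and `L2`, m (zero allowed;
#'   a channel-free patch is degenerate for the capillary reduction but valid
#'   geometry).
#' @param h_k Keratinocyte height (single-layer thickness), m.
#'
#' @return An object of class `brick_mortar_geometry` (a named list of the
#'   seven dimensions).
#' @seealso [lipid_area_fraction()], [hydraulic_radius()], [build_capillary()]
#' @export
#' @examples
#' geom <- brick_mortar_geometry()
#' lipid_area_fraction(geom)
#' hydraulic_radius(geom) * 1e9 # nm
brick_mortar_geometry <- function(L1 = 0.02, L2 = L1, a = 2e-5, b = a,
                                  d1 = 5e-8, d2 = d1, h_k = 1e-5) {
  .check_finite_num(L1, "L1")
  .check_finite_num(L2, "L2")
  .check_finite_num(a, "a")
  .check_finite_num(b, "b")
  .check_finite_num(d1, "d1", allow_zero = TRUE)
  .check_finite_num(d2, "d2", allow_zero = TRUE)
  .check_finite_num(h_k, "h_k")
  if (a > L1 || b > L2) {
    stop("keratinocyte footprint must fit in the patch (a <= L1, b <= L2)",
         call. = FALSE)
  }
  structure(
    list(L1 = L1, L2 = L2, a = a, b = b, d1 = d1, d2 = d2, h_k = h_k),
    class = "brick_mortar_geometry"
  )
}

#' @export
print.brick_mortar_geometry <- function(x, ...) {
  cat("<brick_mortar_geometry>\n")
  cat(sprintf("  patch        : %.3g x %.3g m\n", x$L1, x$L2))
  cat(sprintf("  keratinocyte : %.3g x %.3g x %.3g m\n", x$a, x$b, x$h_k))
  cat(sprintf("  lipid channel: %.3g / %.3g m\n", x$d1, x$d2))
  invisible(x)
}

#' Real-valued keratinocyte count along one patch direction
#'
#' Number of keratinocytes of dimension `a` separated by channels of width
#' `d` that tile a patch edge of length `L`: `(L + d)/(a + d)`. The value is
#' deliberately not rounded -- the area-fraction algebra requires the exact
#' ratio, under which `a * n + (n - 1) * d == L` holds identically.
#'
#' @param L Patch edge length, m.
#' @param a Keratinocyte dimension along the edge, m.
#' @param d Lipid-channel width along the edge, m.
#' @return The real-valued count `(L + d)/(a + d)`. Vectorised.
#' @export
#' @examples
#' keratinocyte_count(0.02, 2e-5, 5e-8)
keratinocyte_count <- function(L, a, d) {
  .check_finite_num(L, "L", allow_zero = TRUE)
  .check_finite_num(a, "a", allow_zero = TRUE)
  .check_finite_num(d, "d", allow_zero = TRUE)
  if (any(a + d <= 0)) stop("`a + d` must be positive", call. = FALSE)
  (L + d) / (a + d)
}

#' Lipid area fraction of the patch surface
#'
#' Fraction of the patch surface occupied by lipid channels,
#' `epsilon = (S - S_n)/S`, where `S` is the patch area rebuilt from the
#' real-valued brick counts and `S_n` the area covered by keratinocytes.
#' This is the porosity entering the Kozeny-Carman capillary reduction.
#'
#' @param geom A [brick_mortar_geometry()].
#' @return The lipid area fraction, in `[0, 1)`.
#' @export
lipid_area_fraction <- function(geom) {
  stopifnot(inherits(geom, "brick_mortar_geometry"))
  n1 <- keratinocyte_count(geom$L1, geom$a, geom$d1)
  n2 <- keratinocyte_count(geom$L2, geom$b, geom$d2)
  S1 <- geom$a * n1 + (n1 - 1) * geom$d1   # == L1 identically
  S2 <- geom$b * n2 + (n2 - 1) * geom$d2   # == L2 identically
  S <- S1 * S2
  Sn <- (geom$a * n1) * (geom$b * n2)
  (S - Sn) / S
}

#' Specific surface of a keratinocyte brick
#'
#' Wall area over volume of a rectangular brick,
#' `a_p = 2 (a b + b h_k + a h_k) / (a b h_k)`. The full surface of all six
#' faces is used by default; only this convention reproduces the 12.5 nm
#' hydraulic radius of the reference parameter set. `printed_form = TRUE`
#' drops the factor 2 (half the faces), provided for comparison with the
#' halved variant that circulates in the literature of this reduction.
#'
#' @param a,b Brick footprint, m.
#' @param h_k Brick height, m.
#' @param printed_form If `TRUE`, omit the factor 2.
#' @return Specific surface, 1/m.
#' @export
#' @examples
#' specific_surface(2e-5, 2e-5, 1e-5)   # 4e5 1/m
#' specific_surface(1e-6, 1e-6, 1e-6)   # cube: 6/a
specific_surface <- function(a, b, h_k, printed_form = FALSE) {
  .check_finite_num(a, "a")
  .check_finite_num(b, "b")
  .check_finite_num(h_k, "h_k")
  fac <- if (isTRUE(printed_form)) 1 else 2
  fac * (a * b + b * h_k + a * h_k) / (a * b * h_k)
}

#' Kozeny-Carman hydraulic radius of the equivalent capillary
#'
#' Reduces the network of lipid channels to a single capillary of radius
#' `r_h = epsilon / (a_p (1 - epsilon))`, with `epsilon` the lipid area
#' fraction and `a_p` the keratinocyte specific surface.
#'
#' @inheritParams lipid_area_fraction
#' @param printed_form Passed to [specific_surface()].
#' @return Hydraulic radius, m.
#' @export
#' @examples
#' hydraulic_radius(brick_mortar_geometry()) # ~1.25e-8 m
hydraulic_radius <- function(geom, printed_form = FALSE) {
  eps <- lipid_area_fraction(geom)
  if (eps >= 1) stop("degenerate geometry: lipid area fraction is 1", call. = FALSE)
  a_p <- specific_surface(geom$a, geom$b, geom$h_k, printed_form = printed_form)
  eps / (a_p * (1 - eps))
}

#' Assemble the equivalent-capillary record
#'
#' Bundles the derived quantities of the capillary reduction -- lipid area
#' fraction, specific surface, hydraulic radius, capillary diameter
#' `d_c = 2 r_h` -- together with the capillary length. The length is the
#' diffusion distance of the transport model and is independent of the
#' keratinocyte height used by the geometry (the two enter different parts
#' of the model and are never shared).
#'
#' @inheritParams hydraulic_radius
#' @param length Capillary length (diffusion distance), m. Default 1e-6 m.
#' @return An object of class `capillary_equivalent` with fields `epsilon`,
#'   `a_p`, `r_h`, `d_c`, `length`.
#' @export
#' @examples
#' cap <- build_capillary(brick_mortar_geometry())
#' cap$d_c * 1e9 # ~25 nm
build_capillary <- function(geom, length = 1e-6, printed_form = FALSE) {
  .check_finite_num(length, "length")
  eps <- lipid_area_fraction(geom)
  if (eps <= 0 || eps >= 1) {
    stop("degenerate geometry: lipid area fraction must lie strictly in (0, 1)",
         call. = FALSE)
  }
  a_p <- specific_surface(geom$a, geom$b, geom$h_k, printed_form = printed_form)
  r_h <- eps / (a_p * (1 - eps))
  capillary_equivalent(r_h = r_h, length = length, epsilon = eps, a_p = a_p)
}

#' Construct an equivalent capillary directly
#'
#' Low-level constructor for a capillary record from a hydraulic radius and
#' length, used when the capillary is prescribed rather than derived from a
#' patch geometry (e.g. in simulator tests).
#'
#' @param r_h Hydraulic radius, m.
#' @param length Capillary length, m.
#' @param epsilon,a_p Optional provenance fields from the geometric
#'   reduction; `NA` when the capillary is prescribed directly.
#' @return A `capillary_equivalent` object.
#' @export
capillary_equivalent <- function(r_h, length, epsilon = NA_real_, a_p = NA_real_) {
  .check_finite_num(r_h, "r_h")
  .check_finite_num(length, "length")
  structure(
    list(epsilon = epsilon, a_p = a_p, r_h = r_h, d_c = 2 * r_h, length = length),
    class = "capillary_equivalent"
  )
}

#' @export
print.capillary_equivalent <- function(x, ...) {
  cat("<capillary_equivalent>\n")
  if (!is.na(x$epsilon)) cat(sprintf("  epsilon: %.4g   a_p: %.4g 1/m\n", x$epsilon, x$a_p))
  cat(sprintf("  r_h: %.4g m (%.3g nm)   d_c: %.4g m\n", x$r_h, x$r_h * 1e9, x$d_c))
  cat(sprintf("  length: %.4g m\n", x$length))
  invisible(x)
}

#' @rdname tidy.hill_fit
#' @export
tidy.capillary_equivalent <- function(x, ...) {
  tibble::tibble(epsilon = x$epsilon, a_p = x$a_p, r_h = x$r_h,
                 d_c = x$d_c, length = x$length)
}
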