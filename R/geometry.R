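#' Curved surface area of a spherical dome
#'
#' The retina is modelled as a spherical dome (a sphere cap cut by a plane).
#' With base radius `c` and height `h`, the curved surface area is
#' \deqn{S = 2\pi r h = \pi (c^2 + h^2),}
#' where `r` is the radius of the generating sphere. The second form needs
#' only the cap dimensions and is the one used here.
#'
#' @param c Base radius of the dome (mm), non-negative.
#' @param h Height of the dome (mm), non-negative.
#' @return Curved surface area in mm^2 (excluding the base).
#' @examples
#' dome_surface_area(3, 4) # 25 * pi
#' @export
dome_surface_area <- function(c, h) {
  check_nonneg(c, "c")
  check_nonneg(h, "h")
  if (any(c == 0 & h == 0)) {
    stop("dome_surface_area(): c and h must not both be zero", call. = FALSE)
  }
  pi * (c^2 + h^2)
}

#' Equal-area equivalent radius of a spherical dome
#'
#' Radius of the flat circle whose area equals the dome's curved surface
#' area: \eqn{\sqrt{c^2 + h^2}}. Flattening each retinal region to its
#' equivalent circle preserves areas exactly, so all downstream layout and
#' integration work can be done on a flat disc.
#'
#' @inheritParams dome_surface_area
#' @return Equivalent radius in mm; `pi * result^2` equals
#'   [dome_surface_area()].
#' @examples
#' equivalent_radius(3, 4) # 5
#' @export
equivalent_radius <- function(c, h) {
  check_nonneg(c, "c")
  check_nonneg(h, "h")
  sqrt(c^2 + h^2)
}

#' Equal-area disc model of the retina
#'
#' Holds the equivalent radii of the three concentric retinal regions used
#' by the simulation, all measured on the flattened equal-area disc:
#' the whole retina (ora serrata), the retina up to the equator (outer
#' limit of scatter PRP), and the central PRP-free zone (vascular arcades,
#' macula and optic disc).
#'
#' @param radius_total Equivalent radius of the whole retina (mm).
#' @param radius_equator Equivalent radius of the retina up to the equator
#'   (mm).
#' @param radius_free Equivalent radius of the central PRP-free zone (mm).
#' @return An object of class `equivalent_disc`.
#' @examples
#' equivalent_disc()
#' @export
equivalent_disc <- function(radius_total = 18.6, radius_equator = 15.6,
                            radius_free = 5.14) {
  check_num1(radius_total, "radius_total")
  check_num1(radius_equator, "radius_equator")
  check_num1(radius_free, "radius_free")
  if (!(0 < radius_free && radius_free < radius_equator &&
        radius_equator < radius_total)) {
    stop("equivalent_disc(): need 0 < radius_free < radius_equator < ",
         "radius_total", call. = FALSE)
  }
  structure(
    list(radius_total = radius_total, radius_equator = radius_equator,
         radius_free = radius_free),
    class = "equivalent_disc"
  )
}

#' @export
print.equivalent_disc <- function(x, ...) {
  cat("Equal-area retinal disc (mm):\n")
  cat(sprintf("  whole retina   %.2f\n", x$radius_total))
  cat(sprintf("  equator        %.2f\n", x$radius_equator))
  cat(sprintf("  PRP-free zone  %.2f\n", x$radius_free))
  invisible(x)
}

# -- internal argument checks -------------------------------------------------

check_num1 <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  }
  invisible(x)
}

check_nonneg <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0)) {
    stop(sprintf("'%s' must be finite and non-negative", name), call. = FALSE)
  }
  invisible(x)
}
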