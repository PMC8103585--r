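#' Rotationally averaged photoreceptor density profile
#'
#' A `density_profile` tabulates photoreceptor density (cells/mm^2) against
#' eccentricity (mm, distance from the foveal center on the flattened
#' equal-area disc). Density between grid nodes is piecewise-linear; beyond
#' the last node it is zero. Rotating the profile about the vertical axis
#' yields the island-shaped solid of revolution whose volume encodes the
#' total photoreceptor count (see [volume_from_count()]).
#'
#' @param eccentricity Strictly increasing numeric vector of eccentricities
#'   (mm), starting at 0.
#' @param density Non-negative densities (cells/mm^2), same length.
#' @param optic_disc An [optic_disc_spec()] describing the photoreceptor-free
#'   cylinder hollowed out for the optic nerve head, or `NULL` for none.
#' @return An object of class `density_profile`.
#' @seealso [density_at()], [total_count()], [count_in_spot()]
#' @export
density_profile <- function(eccentricity, density, optic_disc = NULL) {
  if (!is.numeric(eccentricity) || !is.numeric(density) ||
      length(eccentricity) != length(density) || length(eccentricity) < 2L) {
    stop("density_profile(): eccentricity and density must be numeric ",
         "vectors of equal length >= 2", call. = FALSE)
  }
  if (any(!is.finite(eccentricity)) || any(!is.finite(density))) {
    stop("density_profile(): values must be finite", call. = FALSE)
  }
  if (eccentricity[1L] != 0) {
    stop("density_profile(): eccentricity grid must start at 0",
         call. = FALSE)
  }
  if (any(diff(eccentricity) <= 0)) {
    stop("density_profile(): eccentricity grid must be strictly increasing",
         call. = FALSE)
  }
  if (any(density < 0)) {
    stop("density_profile(): densities must be non-negative", call. = FALSE)
  }
  if (!is.null(optic_disc) && !inherits(optic_disc, "optic_disc_spec")) {
    stop("density_profile(): optic_disc must be an optic_disc_spec or NULL",
         call. = FALSE)
  }
  structure(
    list(eccentricity = as.numeric(eccentricity),
         density = as.numeric(density),
         optic_disc = optic_disc),
    class = "density_profile"
  )
}

#' Optic disc hollow specification
#'
#' The optic nerve head carries no photoreceptors; the solid of revolution
#' has a right circular cylinder hollowed out at its location. Defaults are
#' standard human anatomy: a 1.5 mm diameter disc centered about 3.4 mm from
#' the fovea.
#'
#' @param radius Optic disc radius (mm), positive.
#' @param center_eccentricity Distance of the disc center from the fovea
#'   (mm), non-negative.
#' @return An object of class `optic_disc_spec`.
#' @export
optic_disc_spec <- function(radius = 0.75, center_eccentricity = 3.4) {
  check_num1(radius, "radius")
  check_num1(center_eccentricity, "center_eccentricity")
  if (radius <= 0) stop("optic disc radius must be > 0", call. = FALSE)
  if (center_eccentricity < 0) {
    stop("optic disc center_eccentricity must be >= 0", call. = FALSE)
  }
  structure(list(radius = radius, center_eccentricity = center_eccentricity),
            class = "optic_disc_spec")
}

#' @export
print.density_profile <- function(x, ...) {
  cat(sprintf("Photoreceptor density profile: %d nodes, 0-%.2f mm\n",
              length(x$eccentricity), max(x$eccentricity)))
  cat(sprintf("  peak density %.0f cells/mm^2 at %.2f mm\n",
              max(x$density), x$eccentricity[which.max(x$density)]))
  if (!is.null(x$optic_disc)) {
    cat(sprintf("  optic disc hollow: radius %.2f mm at %.2f mm\n",
                x$optic_disc$radius, x$optic_disc$center_eccentricity))
  }
  invisible(x)
}

#' Interpolated density at given eccentricities
#'
#' Piecewise-linear interpolation on the profile grid; exactly the tabulated
#' value at a node, and zero beyond the last node (the solid ends at the
#' retinal edge).
#'
#' @param profile A [density_profile()].
#' @param e Eccentricities (mm), non-negative; vectorized.
#' @return Densities in cells/mm^2.
#' @export
density_at <- function(profile, e) {
  stopifnot(inherits(profile, "density_profile"))
  if (!is.numeric(e) || any(!is.finite(e)) || any(e < 0)) {
    stop("density_at(): eccentricity must be finite and >= 0", call. = FALSE)
  }
  stats::approx(profile$eccentricity, profile$density, xout = e,
                method = "linear", yleft = profile$density[1L],
                yright = 0, ties = "ordered")$y
}

#' Total photoreceptor count of the island-shaped solid
#'
#' Volume of the solid of revolution, expressed directly as a photoreceptor
#' count: \deqn{N = 2\pi \int_0^{R} \rho(e)\, e \, de - \pi r_d^2\,
#' \rho(e_d),} where `R` is the whole-retina equivalent radius, and the
#' second term removes the optic-disc cylinder (radius \eqn{r_d} at
#' eccentricity \eqn{e_d}) when the profile carries one. The radial integral
#' is evaluated in closed form on each grid interval (the integrand is
#' piecewise quadratic), so the quadrature is exact for the piecewise-linear
#' profile.
#'
#' @param profile A [density_profile()].
#' @param disc An [equivalent_disc()]; integration stops at
#'   `disc$radius_total`.
#' @return Photoreceptor count (a non-negative number).
#' @export
total_count <- function(profile, disc = equivalent_disc()) {
  stopifnot(inherits(profile, "density_profile"),
            inherits(disc, "equivalent_disc"))
  n <- radial_count_integral(profile, disc$radius_total)
  od <- profile$optic_disc
  if (!is.null(od)) {
    n <- n - pi * od$radius^2 * density_at(profile, od$center_eccentricity)
  }
  max(n, 0)
}

# 2*pi * int_0^R rho(e) e de, exact for the piecewise-linear rho.
radial_count_integral <- function(profile, R) {
  e <- profile$eccentricity
  d <- profile$density
  R <- min(R, max(e))
  if (R <= 0) return(0)
  # clip the grid at R, inserting an interpolated node there
  keep <- e < R
  e2 <- c(e[keep], R)
  d2 <- c(d[keep], density_at(profile, R))
  lo <- e2[-length(e2)]
  hi <- e2[-1L]
  dlo <- d2[-length(d2)]
  dhi <- d2[-1L]
  # on [lo, hi]: rho(e) = a + b (e - lo) with b = (dhi-dlo)/(hi-lo)
  b <- (dhi - dlo) / (hi - lo)
  # int e*rho de = a*(hi^2-lo^2)/2 + b*(hi^3/3 - lo*hi^2/2 - lo^3/3 + lo^3/2)
  term <- dlo * (hi^2 - lo^2) / 2 +
    b * ((hi^3 - lo^3) / 3 - lo * (hi^2 - lo^2) / 2)
  2 * pi * sum(term)
}

#' Photoreceptors destroyed inside one laser spot
#'
#' Integrates the density over the spot disc,
#' \eqn{\int\!\!\int_{spot} \rho(|p|)\, dA}: the burn punches a right-angle
#' cylinder through the island solid, so the destroyed count is exactly this
#' area integral. Quadrature is a midpoint rule on a Cartesian grid of pitch
#' `step` clipped to the spot disc, normalized by the exact disc area (the
#' sum is `pi r^2` times the mean density over the retained grid centers),
#' which makes the rule exact for constant density and second-order accurate
#' otherwise.
#'
#' @param profile A [density_profile()].
#' @param spot A [spot()].
#' @param step Quadrature grid pitch (mm); default 0.01 (10 um).
#' @return Photoreceptor count destroyed in the spot.
#' @seealso [mc_count_in_spot()] for a Monte Carlo cross-check.
#' @export
count_in_spot <- function(profile, spot, step = 0.01) {
  stopifnot(inherits(profile, "density_profile"), inherits(spot, "spot"))
  check_num1(step, "step")
  if (step <= 0) stop("step must be > 0", call. = FALSE)
  emax <- max(profile$eccentricity)
  r <- spot$diameter / 2
  if (sqrt(spot$x^2 + spot$y^2) + r > emax + 1e-9) {
    stop("count_in_spot(): spot extends beyond the profile domain (",
         format(emax), " mm)", call. = FALSE)
  }
  count_in_spots_batch(profile, spot$x, spot$y, spot$diameter, step)
}

# Vectorized core: spots share one diameter; x, y are equal-length vectors.
count_in_spots_batch <- function(profile, x, y, diameter, step) {
  r <- diameter / 2
  n <- ceiling(diameter / step)
  off <- (seq_len(n) - (n + 1) / 2) * step
  g <- expand.grid(dx = off, dy = off)
  inside <- g$dx^2 + g$dy^2 <= r^2
  dx <- g$dx[inside]
  dy <- g$dy[inside]
  area <- pi * r^2
  out <- numeric(length(x))
  # chunk to bound memory: ~2e6 points at a time
  chunk <- max(1L, floor(2e6 / length(dx)))
  for (i0 in seq(1L, length(x), by = chunk)) {
    idx <- i0:min(i0 + chunk - 1L, length(x))
    ex <- outer(x[idx], dx, "+")
    ey <- outer(y[idx], dy, "+")
    ecc <- sqrt(ex^2 + ey^2)
    rho <- density_at(profile, as.numeric(ecc))
    dim(rho) <- dim(ecc)
    out[idx] <- area * rowMeans(rho)
  }
  out
}

#' Monte Carlo estimate of the count inside a spot
#'
#' Brute-force oracle for [count_in_spot()]: uniform rejection sampling over
#' the spot disc (points drawn in the bounding square, kept if inside the
#' disc). The estimate is spot area times the mean sampled density; the
#' standard error is spot area times the standard error of that mean.
#' Reproducible for a fixed seed; the caller's RNG state is left untouched.
#'
#' @inheritParams count_in_spot
#' @param n_samples Number of accepted sample points, at least 100.
#' @param seed Integer seed.
#' @return A list with `estimate`, `se`, and `n_samples`.
#' @export
mc_count_in_spot <- function(profile, spot, n_samples = 10000L, seed = 1L) {
  stopifnot(inherits(profile, "density_profile"), inherits(spot, "spot"))
  if (n_samples < 100) stop("n_samples must be >= 100", call. = FALSE)
  r <- spot$diameter / 2
  rho <- with_local_seed(seed, {
    acc <- numeric(0)
    while (length(acc) < n_samples) {
      m <- ceiling((n_samples - length(acc)) * 4 / pi * 1.1) + 16L
      px <- stats::runif(m, -r, r)
      py <- stats::runif(m, -r, r)
      keep <- px^2 + py^2 <= r^2
      ecc <- sqrt((spot$x + px[keep])^2 + (spot$y + py[keep])^2)
      acc <- c(acc, density_at(profile, ecc))
    }
    acc[seq_len(n_samples)]
  })
  area <- pi * r^2
  list(estimate = area * mean(rho),
       se = area * stats::sd(rho) / sqrt(n_samples),
       n_samples = as.integer(n_samples))
}

# Run expr under set.seed(seed) without disturbing the caller's RNG stream.
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Rescale a profile so its total count hits a target
#'
#' Multiplies every density by `target_total / total_count(profile, disc)`.
#' Because every count in the model is linear in the densities, calibration
#' changes counts proportionally and leaves the destruction and
#' photocoagulation indexes unchanged.
#'
#' @inheritParams total_count
#' @param target_total Desired total photoreceptor count, positive.
#' @return A new [density_profile()] whose [total_count()] equals
#'   `target_total`.
#' @export
calibrate_profile <- function(profile, disc = equivalent_disc(),
                              target_total) {
  stopifnot(inherits(profile, "density_profile"))
  check_num1(target_total, "target_total")
  if (target_total <= 0) stop("target_total must be > 0", call. = FALSE)
  cur <- total_count(profile, disc)
  if (cur <= 0) {
    stop("calibrate_profile(): profile has zero total count", call. = FALSE)
  }
  density_profile(profile$eccentricity,
                  profile$density * (target_total / cur),
                  optic_disc = profile$optic_disc)
}

#' Convert between island-solid volume and photoreceptor count
#'
#' The density axis of the solid is scaled so that 1 mm of solid height
#' corresponds to 10^4 cells/mm^2; hence 1 mm^3 of solid volume corresponds
#' to exactly 10^4 photoreceptors, and the conversion is exact in both
#' directions.
#'
#' @param volume_mm3,count Non-negative volume (mm^3) or count.
#' @return The corresponding count, resp. volume.
#' @examples
#' count_from_volume(9657.19) # 96,571,900
#' @export
count_from_volume <- function(volume_mm3) {
  check_nonneg(volume_mm3, "volume_mm3")
  volume_mm3 * 1e4
}

#' @rdname count_from_volume
#' @export
volume_from_count <- function(count) {
  check_nonneg(count, "count")
  count / 1e4
}

#' Read / write a density profile CSV
#'
#' The CSV has a header `eccentricity_mm,density_cells_per_mm2`, rows sorted
#' by increasing eccentricity, and `#` comment lines.
#'
#' @param path File path.
#' @param profile A [density_profile()].
#' @param optic_disc Passed to [density_profile()] when reading.
#' @return `read_density_profile()` returns a [density_profile()];
#'   `write_density_profile()` returns `path` invisibly.
#' @export
read_density_profile <- function(path, optic_disc = NULL) {
  df <- utils::read.csv(path, comment.char = "#")
  need <- c("eccentricity_mm", "density_cells_per_mm2")
  if (!all(need %in% names(df))) {
    stop("density profile CSV must have columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  density_profile(df$eccentricity_mm, df$density_cells_per_mm2,
                  optic_disc = optic_disc)
}

#' @rdname read_density_profile
#' @export
write_density_profile <- function(profile, path) {
  stopifnot(inherits(profile, "density_profile"))
  df <- data.frame(eccentricity_mm = profile$eccentricity,
                   density_cells_per_mm2 = profile$density)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
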