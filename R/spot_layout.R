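#' A single laser spot
#'
#' A photocoagulation burn, modelled as a closed disc on the flattened
#' retina. The clinical standard burn is 400 um on the retina, hence the
#' default diameter of 0.4 mm.
#'
#' @param x,y Center coordinates on the flattened disc (mm).
#' @param diameter Spot diameter (mm), positive.
#' @return An object of class `spot`.
#' @export
spot <- function(x, y, diameter = 0.4) {
  check_num1(x, "x"); check_num1(y, "y"); check_num1(diameter, "diameter")
  if (diameter <= 0) stop("spot diameter must be > 0", call. = FALSE)
  structure(list(x = x, y = y, diameter = diameter), class = "spot")
}

#' Layout generation configuration
#'
#' Parameters of the deterministic annular spot generator. The clinical
#' protocol is 400-um spots, one spot width apart, giving the defaults
#' `spot_diameter = 0.4` and `spacing = 0.4` (center-to-center pitch
#' 0.8 mm).
#'
#' @param inner_radius,outer_radius Annulus bounds (mm); every spot disc
#'   must lie inside the closed annulus.
#' @param spot_diameter Spot diameter (mm).
#' @param spacing Edge-to-edge spacing between neighbouring spots (mm).
#' @param radial_pitch_mode `"hex"` (ring separation `(d+s)*sqrt(3)/2`, the
#'   default, densest regular packing of rings), `"square"` (ring
#'   separation `d+s`), or `"count_match"` (hex ring radii with the
#'   circumferential pitch scaled so the generated layout has exactly
#'   `target_count` spots).
#' @param target_count Required spot count for `count_match` mode.
#' @return An object of class `layout_config`.
#' @export
layout_config <- function(inner_radius, outer_radius, spot_diameter = 0.4,
                          spacing = 0.4,
                          radial_pitch_mode = c("hex", "square",
                                                "count_match"),
                          target_count = NULL) {
  radial_pitch_mode <- match.arg(radial_pitch_mode)
  check_num1(inner_radius, "inner_radius")
  check_num1(outer_radius, "outer_radius")
  check_num1(spot_diameter, "spot_diameter")
  check_num1(spacing, "spacing")
  if (spot_diameter <= 0) stop("spot_diameter must be > 0", call. = FALSE)
  if (spacing < 0) stop("spacing must be >= 0", call. = FALSE)
  if (inner_radius < 0) stop("inner_radius must be >= 0", call. = FALSE)
  if (inner_radius >= outer_radius) {
    stop("layout_config(): inner_radius must be < outer_radius",
         call. = FALSE)
  }
  if (radial_pitch_mode == "count_match") {
    if (is.null(target_count) || target_count < 1) {
      stop("count_match mode requires a positive target_count",
           call. = FALSE)
    }
    target_count <- as.integer(target_count)
  }
  structure(
    list(inner_radius = inner_radius, outer_radius = outer_radius,
         spot_diameter = spot_diameter, spacing = spacing,
         radial_pitch_mode = radial_pitch_mode, target_count = target_count),
    class = "layout_config"
  )
}

#' A spot layout
#'
#' A set of laser spots with the configuration that generated it (if any).
#' Validity requires that no two spots overlap (center distance at least the
#' spot diameter, tangency allowed) and, when an annulus configuration is
#' attached, that every spot disc lies inside the closed annulus.
#'
#' @param spots A data.frame with columns `x`, `y`, `diameter`.
#' @param config A [layout_config()] or `NULL` (custom layouts).
#' @param validate Check the invariants (default `TRUE`).
#' @return An object of class `spot_layout`.
#' @export
spot_layout <- function(spots, config = NULL, validate = TRUE) {
  if (!is.data.frame(spots) || !all(c("x", "y", "diameter") %in%
                                    names(spots))) {
    stop("spots must be a data.frame with columns x, y, diameter",
         call. = FALSE)
  }
  spots <- as.data.frame(spots)[, c("x", "y", "diameter")]
  layout <- structure(list(spots = spots, config = config),
                      class = "spot_layout")
  if (validate) validate_layout(layout)
  layout
}

#' @export
print.spot_layout <- function(x, ...) {
  cat(sprintf("Spot layout: %d spots\n", nrow(x$spots)))
  if (nrow(x$spots) > 0) {
    cat(sprintf("  diameter %.3g mm, lesion area %.2f mm^2\n",
                x$spots$diameter[1L],
                sum(pi * (x$spots$diameter / 2)^2)))
  }
  if (!is.null(x$config)) {
    cat(sprintf("  annulus %.2f-%.2f mm, mode %s\n",
                x$config$inner_radius, x$config$outer_radius,
                x$config$radial_pitch_mode))
  }
  invisible(x)
}

#' Number of spots in a layout
#' @param layout A [spot_layout()].
#' @return Integer spot count.
#' @export
n_spots <- function(layout) {
  stopifnot(inherits(layout, "spot_layout"))
  nrow(layout$spots)
}

#' Validate a spot layout
#'
#' Checks the non-overlap invariant (every pair of spots at center distance
#' at least the mean of their diameters, within 1e-9) and, when the layout
#' carries an annulus configuration, containment of every spot disc in the
#' closed annulus. Violations raise an error listing the offending spot
#' indices.
#'
#' @param layout A [spot_layout()].
#' @return The layout, invisibly.
#' @export
validate_layout <- function(layout) {
  stopifnot(inherits(layout, "spot_layout"))
  s <- layout$spots
  if (nrow(s) == 0) return(invisible(layout))
  if (any(s$diameter <= 0)) {
    stop("invalid layout: non-positive diameters at spots ",
         paste(which(s$diameter <= 0), collapse = ", "), call. = FALSE)
  }
  if (nrow(s) > 1) {
    d <- as.matrix(stats::dist(s[, c("x", "y")]))
    need <- outer(s$diameter, s$diameter, "+") / 2
    diag(d) <- Inf
    bad <- which(d < need - 1e-9, arr.ind = TRUE)
    if (nrow(bad) > 0) {
      idx <- sort(unique(as.vector(bad)))
      stop("invalid layout: overlapping spots at indices ",
           paste(idx, collapse = ", "), call. = FALSE)
    }
  }
  cfg <- layout$config
  if (!is.null(cfg)) {
    ecc <- sqrt(s$x^2 + s$y^2)
    out <- which(ecc - s$diameter / 2 < cfg$inner_radius - 1e-9 |
                 ecc + s$diameter / 2 > cfg$outer_radius + 1e-9)
    if (length(out) > 0) {
      stop("invalid layout: spots outside the annulus at indices ",
           paste(out, collapse = ", "), call. = FALSE)
    }
  }
  invisible(layout)
}

# Ring radii and per-ring counts for given pitches; returns a data.frame.
# First ring is tangent to the inner boundary; rings advance by p_rad and a
# ring is kept iff its spot discs fit inside the closed annulus.
ring_plan <- function(inner, outer, diameter, p_rad, p_circ) {
  r0 <- inner + diameter / 2
  if (r0 + diameter / 2 > outer + 1e-9) {
    return(data.frame(radius = numeric(0), count = integer(0)))
  }
  k <- 0:floor((outer - diameter / 2 - r0) / p_rad + 1e-9)
  radius <- r0 + k * p_rad
  count <- pmax(1L, as.integer(floor(2 * pi * radius / p_circ + 1e-9)))
  data.frame(radius = radius, count = count)
}

ring_spots <- function(plan, diameter) {
  if (nrow(plan) == 0) {
    return(data.frame(x = numeric(0), y = numeric(0),
                      diameter = numeric(0)))
  }
  do.call(rbind, lapply(seq_len(nrow(plan)), function(i) {
    n <- plan$count[i]
    # alternate a half-pitch angular offset between consecutive rings
    theta <- (seq_len(n) - 1 + 0.5 * ((i - 1) %% 2)) * (2 * pi / n)
    data.frame(x = plan$radius[i] * cos(theta),
               y = plan$radius[i] * sin(theta),
               diameter = diameter)
  }))
}

#' Generate a deterministic annular spot layout
#'
#' Places spots on concentric rings inside the closed annulus
#' `[inner_radius, outer_radius]`. The first ring is tangent to the inner
#' boundary (centers at `inner_radius + diameter/2`); rings advance outward
#' by the radial pitch of the chosen mode; each ring holds
#' `floor(2*pi*radius / pitch)` evenly spaced spots with an alternating
#' half-pitch angular offset between rings. Rings whose spots would cross
#' the outer boundary are dropped (tangency is allowed: a spot is kept iff
#' its closed disc lies inside the closed annulus). The result is fully
#' deterministic. In `count_match` mode the circumferential pitch is scaled
#' by a factor found by search so the layout has exactly
#' `config$target_count` spots (ring radii keep the hex radial pitch).
#'
#' @param config A [layout_config()].
#' @return A validated [spot_layout()]; empty (zero spots) if the annulus is
#'   too narrow for any spot.
#' @examples
#' scatter <- layout_config(inner_radius = 5.14, outer_radius = 15.6)
#' n_spots(generate_annulus_layout(scatter))
#' @export
generate_annulus_layout <- function(config) {
  stopifnot(inherits(config, "layout_config"))
  d <- config$spot_diameter
  pitch <- d + config$spacing
  base_rad <- switch(config$radial_pitch_mode,
                     square = pitch,
                     hex = pitch * sqrt(3) / 2,
                     count_match = pitch * sqrt(3) / 2)
  f <- 1
  if (config$radial_pitch_mode == "count_match") {
    f <- match_pitch_scale(config, base_rad, pitch)
  }
  plan <- ring_plan(config$inner_radius, config$outer_radius, d,
                    base_rad, f * pitch)
  spot_layout(ring_spots(plan, d), config = config)
}

# Search a circumferential pitch scale so the ring plan yields exactly
# target_count spots. Only the in-ring pitch is scaled (ring radii keep the
# hex radial pitch): the count is then a step function of the scale with
# unit-sized jumps, so exact targets are reachable; scaling the radial
# pitch too would add whole rings (~100 spots) at a time. The count is
# nonincreasing in the scale; bisect for the loosest scale that reaches
# the target, then verify equality.
match_pitch_scale <- function(config, base_rad, base_circ) {
  target <- config$target_count
  count_at <- function(f) {
    sum(ring_plan(config$inner_radius, config$outer_radius,
                  config$spot_diameter, base_rad, f * base_circ)$count)
  }
  # tight packing bound: center spacing must stay >= diameter
  lo <- max(0.2, config$spot_diameter / base_circ + 1e-6)
  hi <- 2
  if (count_at(lo) < target || count_at(hi) > target) {
    stop("count_match: target_count ", target, " unreachable by scaling ",
         "the circumferential pitch", call. = FALSE)
  }
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    if (count_at(mid) >= target) lo <- mid else hi <- mid
  }
  if (count_at(lo) != target) {
    stop("count_match: no circumferential pitch scale yields exactly ",
         target, " spots for this annulus", call. = FALSE)
  }
  lo
}

#' Generate a single ring of spots
#'
#' One ring of evenly spaced spots at the given center radius, with
#' `floor(2*pi*ring_radius / (diameter + spacing))` spots. Used, e.g., for
#' one additional row of photocoagulation just inside the vascular arcade.
#'
#' @param ring_radius Ring center radius (mm), must exceed the spot radius.
#' @param config A [layout_config()] supplying diameter and spacing (its
#'   annulus bounds are ignored).
#' @return A [spot_layout()] without an attached annulus config.
#' @export
generate_single_ring <- function(ring_radius, config) {
  stopifnot(inherits(config, "layout_config"))
  check_num1(ring_radius, "ring_radius")
  d <- config$spot_diameter
  if (ring_radius <= d / 2) {
    stop("ring_radius must exceed the spot radius", call. = FALSE)
  }
  pitch <- d + config$spacing
  n <- max(1L, as.integer(floor(2 * pi * ring_radius / pitch + 1e-9)))
  plan <- data.frame(radius = ring_radius, count = n)
  spot_layout(ring_spots(plan, d), config = NULL)
}

#' Photocoagulation index of a layout
#'
#' Ratio of the total photocoagulated lesion area to the whole retinal
#' area, in percent:
#' \deqn{100 \times \frac{\sum_i \pi (d_i/2)^2}{\pi R_{total}^2}.}
#'
#' @param layout A [spot_layout()].
#' @param disc An [equivalent_disc()].
#' @return Percent of the retinal area photocoagulated.
#' @export
photocoagulation_index <- function(layout, disc = equivalent_disc()) {
  stopifnot(inherits(layout, "spot_layout"),
            inherits(disc, "equivalent_disc"))
  100 * sum((layout$spots$diameter / 2)^2) / disc$radius_total^2
}

#' Read / write a spot layout CSV
#'
#' The CSV has a header `x_mm,y_mm,diameter_mm`. Reading validates the
#' non-overlap invariant and reports offending spot indices; writing and
#' re-reading is a lossless round trip.
#'
#' @param path File path.
#' @param layout A [spot_layout()].
#' @return `read_spot_layout()` returns a [spot_layout()];
#'   `write_spot_layout()` returns `path` invisibly.
#' @export
read_spot_layout <- function(path) {
  df <- utils::read.csv(path, comment.char = "#")
  need <- c("x_mm", "y_mm", "diameter_mm")
  if (!all(need %in% names(df))) {
    stop("layout CSV must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  spot_layout(data.frame(x = df$x_mm, y = df$y_mm,
                         diameter = df$diameter_mm))
}

#' @rdname read_spot_layout
#' @export
write_spot_layout <- function(layout, path) {
  stopifnot(inherits(layout, "spot_layout"))
  df <- data.frame(x_mm = layout$spots$x, y_mm = layout$spots$y,
                   diameter_mm = layout$spots$diameter)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
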