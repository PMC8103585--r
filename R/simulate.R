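#' Photoreceptor destruction index
#'
#' Ratio of the number of photoreceptors destroyed to the total number of
#' photoreceptors, in percent: `100 * destroyed / total`. The value is
#' returned at full precision; reports render it to one decimal.
#'
#' @param destroyed Photoreceptors destroyed, with
#'   `0 <= destroyed <= total`.
#' @param total Total photoreceptor count, positive.
#' @return Percent destroyed.
#' @examples
#' destruction_index(15608200, 96571900) # 16.2
#' @export
destruction_index <- function(destroyed, total) {
  check_nonneg(destroyed, "destroyed")
  if (!is.numeric(total) || any(total <= 0)) {
    stop("total must be > 0", call. = FALSE)
  }
  if (any(destroyed > total)) {
    stop("destruction_index(): destroyed exceeds total", call. = FALSE)
  }
  100 * destroyed / total
}

#' Run the full PRP simulation
#'
#' Combines a density profile and a spot layout into the simulation
#' summary: each burn punches a right-angle cylinder out of the island
#' solid, so the destroyed count is the sum over spots of the area integral
#' of the density over the spot disc ([count_in_spot()]); generated layouts
#' never overlap, so the summation is exact. Residual count, both indexes
#' and the equivalent solid volumes are derived from it.
#'
#' @param profile A [density_profile()].
#' @param layout A [spot_layout()]; layouts with overlapping spots are
#'   rejected.
#' @param disc An [equivalent_disc()].
#' @param step Quadrature pitch for [count_in_spot()] (mm).
#' @return An object of class `prp_simulation` with fields `total_count`,
#'   `destroyed_count`, `residual_count`, `destruction_index_pct`,
#'   `photocoagulation_index_pct`, `n_spots`, `total_volume_mm3`,
#'   `residual_volume_mm3`.
#' @export
run_simulation <- function(profile, layout, disc = equivalent_disc(),
                           step = 0.01) {
  stopifnot(inherits(profile, "density_profile"),
            inherits(layout, "spot_layout"),
            inherits(disc, "equivalent_disc"))
  validate_layout(layout)
  total <- total_count(profile, disc)
  s <- layout$spots
  destroyed <- 0
  if (nrow(s) > 0) {
    emax <- max(profile$eccentricity)
    ecc <- sqrt(s$x^2 + s$y^2)
    if (any(ecc + s$diameter / 2 > emax + 1e-9)) {
      stop("run_simulation(): spots extend beyond the profile domain",
           call. = FALSE)
    }
    for (d in unique(s$diameter)) {
      i <- s$diameter == d
      destroyed <- destroyed +
        sum(count_in_spots_batch(profile, s$x[i], s$y[i], d, step))
    }
  }
  structure(
    list(total_count = total,
         destroyed_count = destroyed,
         residual_count = total - destroyed,
         destruction_index_pct = destruction_index(destroyed, total),
         photocoagulation_index_pct = photocoagulation_index(layout, disc),
         n_spots = nrow(s),
         total_volume_mm3 = volume_from_count(total),
         residual_volume_mm3 = volume_from_count(total - destroyed)),
    class = "prp_simulation"
  )
}

# counts are printed to the nearest 100, matching 2-decimal mm^3 volumes
round100 <- function(x) round(x / 100) * 100

#' @export
print.prp_simulation <- function(x, ...) {
  fmt <- function(v) format(round100(v), big.mark = ",", scientific = FALSE)
  cat("PRP simulation result\n")
  cat(sprintf("  spots                         %d\n", x$n_spots))
  cat(sprintf("  total photoreceptors          %s\n", fmt(x$total_count)))
  cat(sprintf("  destroyed photoreceptors      %s\n",
              fmt(x$destroyed_count)))
  cat(sprintf("  residual photoreceptors       %s\n",
              fmt(x$residual_count)))
  cat(sprintf("  destruction index             %.1f %%\n",
              x$destruction_index_pct))
  cat(sprintf("  photocoagulation index        %.1f %%\n",
              x$photocoagulation_index_pct))
  cat(sprintf("  residual solid volume         %.2f mm^3\n",
              round100(x$residual_count) / 1e4))
  invisible(x)
}

#' Compare treatment patterns on one profile
#'
#' Runs [run_simulation()] once per layout configuration on the same
#' density profile and reports pairwise differences in the destruction
#' index (row minus column, percentage points).
#'
#' @param profile A [density_profile()].
#' @param configs A list of [layout_config()] objects, at least two.
#' @param labels Unique labels, one per config.
#' @param disc An [equivalent_disc()].
#' @param step Quadrature pitch (mm).
#' @return An object of class `prp_comparison`: a list with `results`
#'   (named list of `prp_simulation`) and `index_differences` (matrix of
#'   pairwise destruction-index differences).
#' @export
compare_patterns <- function(profile, configs, labels,
                             disc = equivalent_disc(), step = 0.01) {
  if (!is.list(configs) || length(configs) < 2) {
    stop("compare_patterns(): need at least two configs", call. = FALSE)
  }
  if (length(labels) != length(configs) || anyDuplicated(labels)) {
    stop("compare_patterns(): labels must be unique, one per config",
         call. = FALSE)
  }
  results <- lapply(configs, function(cfg) {
    run_simulation(profile, generate_annulus_layout(cfg), disc, step)
  })
  names(results) <- labels
  di <- vapply(results, `[[`, numeric(1), "destruction_index_pct")
  diffs <- outer(di, di, "-")
  dimnames(diffs) <- list(labels, labels)
  structure(list(results = results, index_differences = diffs),
            class = "prp_comparison")
}

#' @export
print.prp_comparison <- function(x, ...) {
  cat("PRP pattern comparison\n")
  for (lab in names(x$results)) {
    r <- x$results[[lab]]
    cat(sprintf("  %-14s %5d spots  destruction %.1f %%  ",
                lab, r$n_spots, r$destruction_index_pct))
    cat(sprintf("photocoagulation %.1f %%\n", r$photocoagulation_index_pct))
  }
  cat("destruction-index differences (percentage points):\n")
  print(round(x$index_differences, 2))
  invisible(x)
}
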