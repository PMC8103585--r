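#' Parameters of the synthetic rod-density generator
#'
#' The generator emulates the qualitative shape of the human rod
#' photoreceptor topography: a narrow central peak at the fovea, a rod
#' "ridge" (annulus of maximal rod density) a few millimetres out, and a
#' slow decline toward the retinal periphery. The density at eccentricity
#' `e` (mm) is
#' \deqn{\rho(e) = A_c e^{-e^2 / 2 w_c^2}
#'   + A_r e^{-(e - e_r)^2 / 2 w_r^2} e^{-\max(0, e - e_r)/L},}
#' where the exponential decay acts only peripheral to the ridge so that the
#' ridge eccentricity `e_r` is the true density maximum.
#'
#' Defaults were fixed once so that the calibrated profile reproduces
#' published whole-retina destruction statistics; they are frozen and not
#' data-driven.
#'
#' @param cone_peak_amplitude Amplitude of the central peak (cells/mm^2).
#' @param cone_peak_width Gaussian width of the central peak (mm).
#' @param rod_ridge_amplitude Amplitude of the rod ridge (cells/mm^2).
#' @param rod_ridge_eccentricity Ridge location (mm), default 4.
#' @param rod_ridge_width Gaussian width of the ridge (mm).
#' @param peripheral_decay_length e-folding length of the peripheral
#'   decline (mm).
#' @param noise_sd_fraction Relative standard deviation of multiplicative
#'   node noise, in `[0, 0.5)`; 0 (the default) gives a smooth profile.
#' @param seed Integer seed used by [perturbed_profile()].
#' @return An object of class `synthetic_density_params`.
#' @export
synthetic_density_params <- function(cone_peak_amplitude = 10000,
                                     cone_peak_width = 0.5,
                                     rod_ridge_amplitude = 150000,
                                     rod_ridge_eccentricity = 4.0,
                                     rod_ridge_width = 15.0,
                                     peripheral_decay_length = 12.0,
                                     noise_sd_fraction = 0,
                                     seed = 20210507L) {
  for (nm in c("cone_peak_amplitude", "cone_peak_width",
               "rod_ridge_amplitude", "rod_ridge_eccentricity",
               "rod_ridge_width", "peripheral_decay_length")) {
    check_nonneg(get(nm), nm)
  }
  check_num1(noise_sd_fraction, "noise_sd_fraction")
  if (noise_sd_fraction < 0 || noise_sd_fraction >= 0.5) {
    stop("noise_sd_fraction must be in [0, 0.5)", call. = FALSE)
  }
  structure(
    list(cone_peak_amplitude = cone_peak_amplitude,
         cone_peak_width = cone_peak_width,
         rod_ridge_amplitude = rod_ridge_amplitude,
         rod_ridge_eccentricity = rod_ridge_eccentricity,
         rod_ridge_width = rod_ridge_width,
         peripheral_decay_length = peripheral_decay_length,
         noise_sd_fraction = noise_sd_fraction,
         seed = as.integer(seed)),
    class = "synthetic_density_params"
  )
}

synthetic_density_fun <- function(params, e) {
  p <- params
  cone <- if (p$cone_peak_amplitude > 0 && p$cone_peak_width > 0) {
    p$cone_peak_amplitude * exp(-e^2 / (2 * p$cone_peak_width^2))
  } else 0 * e
  rod <- if (p$rod_ridge_amplitude > 0 && p$rod_ridge_width > 0) {
    decay <- if (p$peripheral_decay_length > 0) {
      exp(-pmax(0, e - p$rod_ridge_eccentricity) /
            p$peripheral_decay_length)
    } else 1
    p$rod_ridge_amplitude *
      exp(-(e - p$rod_ridge_eccentricity)^2 / (2 * p$rod_ridge_width^2)) *
      decay
  } else 0 * e
  cone + rod
}

#' Evaluate the parametric density on a grid
#'
#' @param params A [synthetic_density_params()].
#' @param grid_step Grid spacing (mm), default 0.1.
#' @param max_eccentricity Outer end of the grid (mm), default the
#'   whole-retina equivalent radius 18.6.
#' @param optic_disc Optional [optic_disc_spec()] attached to the profile.
#' @return A smooth, deterministic [density_profile()].
#' @export
parametric_profile <- function(params, grid_step = 0.1,
                               max_eccentricity = 18.6, optic_disc = NULL) {
  stopifnot(inherits(params, "synthetic_density_params"))
  check_num1(grid_step, "grid_step")
  check_num1(max_eccentricity, "max_eccentricity")
  if (grid_step <= 0 || max_eccentricity <= 0) {
    stop("grid_step and max_eccentricity must be > 0", call. = FALSE)
  }
  e <- seq(0, max_eccentricity, by = grid_step)
  if (e[length(e)] < max_eccentricity) e <- c(e, max_eccentricity)
  density_profile(e, synthetic_density_fun(params, e),
                  optic_disc = optic_disc)
}

#' Noisy variant of the parametric density
#'
#' Applies independent multiplicative lognormal noise (unit mean, relative
#' standard deviation `noise_sd_fraction`) to each grid node of the smooth
#' profile. Used to emulate inter-eye variability; reproducible for a fixed
#' seed, and the caller's RNG state is left untouched.
#'
#' @inheritParams parametric_profile
#' @param seed Integer seed; defaults to `params$seed`.
#' @return A [density_profile()].
#' @export
perturbed_profile <- function(params, seed = params$seed, grid_step = 0.1,
                              max_eccentricity = 18.6, optic_disc = NULL) {
  stopifnot(inherits(params, "synthetic_density_params"))
  if (params$noise_sd_fraction <= 0) {
    stop("perturbed_profile(): params$noise_sd_fraction must be > 0",
         call. = FALSE)
  }
  smooth <- parametric_profile(params, grid_step, max_eccentricity,
                               optic_disc)
  frac <- params$noise_sd_fraction
  sdlog <- sqrt(log1p(frac^2))
  noise <- with_local_seed(seed, {
    stats::rlnorm(length(smooth$eccentricity),
                  meanlog = -sdlog^2 / 2, sdlog = sdlog)
  })
  density_profile(smooth$eccentricity, pmax(0, smooth$density * noise),
                  optic_disc = optic_disc)
}

#' The packaged calibrated density profile
#'
#' The default smooth parametric profile, with the optic-disc hollow
#' enabled, calibrated so that its total photoreceptor count is exactly
#' 96,571,900 (equivalently, an island-solid volume of 9657.19 mm^3). This
#' is a synthetic stand-in for the (untabulated) measured rod topography
#' and is the profile used in all worked examples. A CSV copy ships in
#' `inst/extdata/synthetic_calibrated_profile.csv`.
#'
#' @param target_total Calibration target; default 96,571,900 cells.
#' @return A calibrated [density_profile()] with optic disc.
#' @examples
#' total_count(packaged_fixture()) # 96,571,900
#' @export
packaged_fixture <- function(target_total = 96571900) {
  p <- parametric_profile(synthetic_density_params(),
                          optic_disc = optic_disc_spec())
  calibrate_profile(p, equivalent_disc(), target_total)
}
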