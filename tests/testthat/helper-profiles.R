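# Analytic test profiles. Both are exactly representable by the
# piecewise-linear profile class, so closed-form integrals are exact
# references for the quadrature.

# constant density k over [0, R]
uniform_profile <- function(k = 1e4, R = 18.6, optic_disc = NULL) {
  density_profile(c(0, R), c(k, k), optic_disc = optic_disc)
}

# density k * e over [0, R]
linear_profile <- function(k = 1e3, R = 18.6) {
  density_profile(c(0, R), c(0, k * R))
}

scatter_config <- function(...) {
  layout_config(inner_radius = 5.14, outer_radius = 15.6, ...)
}

full_scatter_config <- function(...) {
  layout_config(inner_radius = 5.14, outer_radius = 18.6, ...)
}

# area-weighted mean density over an annulus, by fine trapezoidal rule
annulus_mean_density <- function(profile, r_in, r_out, n = 4000) {
  e <- seq(r_in, r_out, length.out = n)
  w <- e * c(0.5, rep(1, n - 2), 0.5)
  sum(density_at(profile, e) * w) / sum(w)
}
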