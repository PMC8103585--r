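test_that("density interpolation is linear with zero extension", {
  p <- density_profile(c(0, 1, 2, 4), c(10, 30, 30, 0))
  expect_equal(density_at(p, c(0, 1, 2, 4)), c(10, 30, 30, 0))
  expect_equal(density_at(p, 0.5), 20)            # midpoint = mean
  expect_equal(density_at(p, 3), 15)
  expect_equal(density_at(p, 5), 0)               # beyond the grid
  expect_error(density_at(p, -0.1), ">= 0")
})

test_that("density profile constructor enforces its invariants", {
  expect_error(density_profile(c(0.5, 1), c(1, 1)), "start at 0")
  expect_error(density_profile(c(0, 1, 1), c(1, 1, 1)),
               "strictly increasing")
  expect_error(density_profile(c(0, 1), c(1, -1)), "non-negative")
})

test_that("total count is exact for analytic profiles", {
  disc <- equivalent_disc()
  # constant density: N = rho * pi * R^2
  expect_equal(total_count(uniform_profile(1e4), disc),
               1e4 * pi * 18.6^2, tolerance = 1e-12)
  # linear density rho = k e: N = 2 pi k R^3 / 3
  k <- 123.4
  expect_equal(total_count(linear_profile(k), disc),
               2 * pi * k * 18.6^3 / 3, tolerance = 1e-12)
  expect_equal(total_count(density_profile(c(0, 18.6), c(0, 0)), disc), 0)
  # integration stops at the disc radius even if the grid extends further
  wide <- density_profile(c(0, 30), c(1e4, 1e4))
  expect_equal(total_count(wide, disc), 1e4 * pi * 18.6^2,
               tolerance = 1e-12)
})

test_that("the optic disc hollow removes a cylinder from the total", {
  disc <- equivalent_disc()
  od <- optic_disc_spec(radius = 0.75, center_eccentricity = 3.4)
  with_od <- total_count(uniform_profile(1e4, optic_disc = od), disc)
  without <- total_count(uniform_profile(1e4), disc)
  expect_equal(without - with_od, pi * 0.75^2 * 1e4, tolerance = 1e-12)
})

test_that("spot quadrature matches closed forms", {
  # constant integrand: exact by construction of the area-normalized rule
  u <- uniform_profile(2.5e4)
  expect_equal(count_in_spot(u, spot(7, -3, 0.4)),
               2.5e4 * pi * 0.2^2, tolerance = 1e-12)
  # rho = k e, spot of radius a at the origin: k * (2 pi / 3) * a^3
  k <- 1e3; a <- 0.35
  expect_equal(count_in_spot(linear_profile(k), spot(0, 0, 2 * a)),
               k * 2 * pi * a^3 / 3, tolerance = 2e-3)
  expect_equal(count_in_spot(density_profile(c(0, 18.6), c(0, 0)),
                             spot(5, 5, 0.4)), 0)
  expect_error(count_in_spot(u, spot(18.6, 0, 0.4)), "beyond")
})

test_that("counts are linear in the density and rotation invariant", {
  prof <- packaged_fixture()
  scaled <- density_profile(prof$eccentricity, prof$density * 3.7,
                            optic_disc = prof$optic_disc)
  disc <- equivalent_disc()
  expect_equal(total_count(scaled, disc), 3.7 * total_count(prof, disc),
               tolerance = 1e-9)
  sp <- spot(9, 2, 0.4)
  expect_equal(count_in_spot(scaled, sp), 3.7 * count_in_spot(prof, sp),
               tolerance = 1e-9)
  # a spot's count depends only on its center eccentricity, not the angle
  set.seed(7)
  for (ecc in c(6.2, 11.7, 15.1)) {
    theta <- runif(6, 0, 2 * pi)
    v <- vapply(theta, function(a) {
      count_in_spot(prof, spot(ecc * cos(a), ecc * sin(a), 0.4))
    }, numeric(1))
    expect_lt(diff(range(v)) / mean(v), 1e-4)
  }
})

test_that("halving the quadrature step barely changes the fixture counts", {
  prof <- packaged_fixture()
  for (sp in list(spot(5.5, 0, 0.4), spot(0, -12, 0.4),
                  spot(10, 10, 0.4))) {
    c1 <- count_in_spot(prof, sp, step = 0.01)
    c2 <- count_in_spot(prof, sp, step = 0.005)
    expect_lt(abs(c2 - c1) / c1, 1e-3)
  }
})

test_that("count converges to density times area for shrinking spots", {
  prof <- packaged_fixture()
  lim <- density_at(prof, 8)
  err <- vapply(c(0.8, 0.4, 0.2), function(d) {
    abs(count_in_spot(prof, spot(8, 0, d)) / (pi * (d / 2)^2) - lim) / lim
  }, numeric(1))
  expect_lt(err[3], 1e-3)
  # relative error shrinks roughly with diameter^2
  expect_lt(err[2], err[1] / 2)
  expect_lt(err[3], err[2] / 2)
})

test_that("Monte Carlo oracle is exact for constant density and seeded", {
  u <- uniform_profile(2.5e4)
  mc <- mc_count_in_spot(u, spot(3, 4, 0.4), n_samples = 500, seed = 11)
  expect_equal(mc$estimate, 2.5e4 * pi * 0.2^2, tolerance = 1e-12)
  expect_equal(mc$se, 0)
  sp <- spot(6, -2, 0.4)
  prof <- packaged_fixture()
  a <- mc_count_in_spot(prof, sp, n_samples = 2000, seed = 99)
  b <- mc_count_in_spot(prof, sp, n_samples = 2000, seed = 99)
  expect_identical(a, b)
  expect_error(mc_count_in_spot(u, sp, n_samples = 50), ">= 100")
})

test_that("Monte Carlo oracle brackets the linear closed form", {
  k <- 1e3; a <- 0.35
  mc <- mc_count_in_spot(linear_profile(k), spot(0, 0, 2 * a),
                         n_samples = 1e5, seed = 3)
  exact <- k * 2 * pi * a^3 / 3
  expect_lt(abs(mc$estimate - exact), 3 * mc$se)
})

test_that("calibration rescales the profile to the target total", {
  disc <- equivalent_disc()
  p <- uniform_profile(1e4)
  cur <- total_count(p, disc)
  expect_equal(calibrate_profile(p, disc, cur)$density, p$density)
  expect_equal(calibrate_profile(p, disc, 2 * cur)$density, 2 * p$density)
  cal <- calibrate_profile(p, disc, 5e7)
  expect_equal(total_count(cal, disc), 5e7, tolerance = 1e-9)
  expect_error(calibrate_profile(density_profile(c(0, 1), c(0, 0)),
                                 disc, 1), "zero total")
})

test_that("volume and count conversions are exact inverses", {
  expect_equal(count_from_volume(9657.19), 96571900)
  expect_equal(volume_from_count(96571900), 9657.19)
  expect_equal(count_from_volume(0), 0)
  x <- c(0.5, 123.456, 9999)
  expect_equal(volume_from_count(count_from_volume(x)), x)
  expect_error(count_from_volume(-1), "non-negative")
  expect_error(volume_from_count(-1), "non-negative")
})

test_that("density profile CSV round-trips", {
  p <- density_profile(c(0, 0.5, 2, 7), c(100, 200, 50, 0))
  path <- withr::local_tempfile(fileext = ".csv")
  write_density_profile(p, path)
  q <- read_density_profile(path)
  expect_equal(q$eccentricity, p$eccentricity)
  expect_equal(q$density, p$density)
  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines("a,b\n1,2", bad)
  expect_error(read_density_profile(bad), "columns")
})
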