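# One shared small spectral run keeps these tests cheap; the physics checks
# do not depend on grid resolution.
local_spectral_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- run_spectrum(default_skin_stack(), spectrum_model(),
                             coarse_settings(n_photons = 4000, seed = 11),
                             incident_energy_J = 10)
    }
    cache
  }
})

test_that("combined results are the convex combination of per-wavelength runs", {
  sres <- local_spectral_fixture()
  w <- sres$weights
  expect_equal(sum(w), 1, tolerance = 1e-12)
  manual_layer <- Reduce(`+`, Map(function(r, wi) wi * r$absorbed_by_layer,
                                  sres$per_wavelength, w))
  expect_equal(sres$absorbed_by_layer, manual_layer, tolerance = 1e-12)
  manual_grid <- Reduce(`+`, Map(function(r, wi) wi * r$absorption_rz,
                                 sres$per_wavelength, w))
  expect_equal(sres$absorption_rz, manual_grid, tolerance = 1e-12)
  manual_cross <- Reduce(`+`, Map(function(r, wi) wi * r$crossing_z,
                                  sres$per_wavelength, w))
  expect_equal(sres$crossing_z, manual_cross, tolerance = 1e-12)

  # combined fractions lie within the per-wavelength envelope
  for (nm in sres$layer_names) {
    per <- vapply(sres$per_wavelength, function(r)
      r$absorbed_by_layer[[nm]], numeric(1))
    expect_gte(sres$absorbed_by_layer[[nm]], min(per) - 1e-12)
    expect_lte(sres$absorbed_by_layer[[nm]], max(per) + 1e-12)
  }
})

test_that("a degenerate single-wavelength spectrum reduces to one run", {
  set <- coarse_settings(n_photons = 2000, seed = 21)
  sres <- run_spectrum(default_skin_stack(), spectrum_model(wavelengths_nm = 800),
                       set, incident_energy_J = 1)
  expect_equal(sres$weights, 1)
  single_set <- set
  single_set$seed <- child_seed(set$seed, 800)
  single <- run_single_wavelength(default_skin_stack(), single_set, 800)
  expect_identical(sres$absorption_rz, single$absorption_rz)
  expect_equal(sres$absorbed_by_layer, single$absorbed_by_layer)
})

test_that("energy outputs scale linearly with incident energy", {
  set <- coarse_settings(n_photons = 2000, seed = 33)
  s1 <- run_spectrum(default_skin_stack(), spectrum_model(), set, 1)
  s10 <- run_spectrum(default_skin_stack(), spectrum_model(), set, 10)
  zs <- c(0, 0.5, 1.315, 5, 13.315)
  expect_equal(energy_at_depth(s10, zs), 10 * energy_at_depth(s1, zs),
               tolerance = 1e-12)
  expect_equal(energy_density(s10), 10 * energy_density(s1),
               tolerance = 1e-12)
  expect_equal(radial_profile(s10, 0.25)$energy_density_J_mm2,
               10 * radial_profile(s1, 0.25)$energy_density_J_mm2,
               tolerance = 1e-12)
})

test_that("energy-vs-depth starts at (1 - specular), never increases, and
           interpolates linearly", {
  sres <- local_spectral_fixture()
  expect_equal(energy_at_depth(sres, 0),
               sres$incident_energy_J * (1 - sres$specular_reflectance),
               tolerance = 1e-9)
  zgrid <- seq(0, max(sres$z_planes), length.out = 400)
  ez <- energy_at_depth(sres, zgrid)
  expect_true(all(diff(ez) <= 1e-9))
  expect_true(all(ez >= 0))
  # piecewise linear between tally planes
  z1 <- sres$z_planes[10]; z2 <- sres$z_planes[11]
  expect_equal(energy_at_depth(sres, (z1 + z2) / 2),
               mean(energy_at_depth(sres, c(z1, z2))), tolerance = 1e-12)
  expect_error(energy_at_depth(sres, -1), "out of tally range")
  expect_error(energy_at_depth(sres, 1e4), "out of tally range")
})

test_that("capture fraction is monotone in detector radius and reaches 1", {
  sres <- local_spectral_fixture()
  depth <- 13.315
  radii <- c(0.5, 1, 2, 5, 10, 20, 40, 60, 79)
  caps <- vapply(radii, function(r) captured_fraction(sres, r, depth),
                 numeric(1))
  expect_true(all(diff(caps) >= -1e-12))
  expect_true(all(caps >= 0 & caps <= 1))
  expect_equal(captured_fraction(sres, 160 * 0.5, depth), 1)
  expect_error(captured_fraction(sres, 0, depth), "detector_radius")
  expect_error(captured_fraction(sres, 5, 1e4), "out of tally range")
})

test_that("radial energy-density profiles are physical", {
  sres <- local_spectral_fixture()
  on_axis <- radial_profile(sres, 0.25)
  expect_true(all(on_axis$energy_density_J_mm2 >= 0))
  # far outside the beam the density is negligible relative to on-axis surface
  far <- radial_profile(sres, 60)
  expect_lt(max(far$energy_density_J_mm2),
            1e-4 * on_axis$energy_density_J_mm2[1])
  # attenuation with depth: dermis band > mid-fat band > deep band
  z <- on_axis$z_mm
  m1 <- mean(on_axis$energy_density_J_mm2[z > 0.065 & z < 1.315])
  m2 <- mean(on_axis$energy_density_J_mm2[z > 5 & z < 10])
  m3 <- mean(on_axis$energy_density_J_mm2[z > 15 & z < 20])
  expect_gt(m1, m2)
  expect_gt(m2, m3)
  expect_error(radial_profile(sres, 1e3), "out of tally range")
})

test_that("capture report covers boundaries and applies the efficiency band", {
  sres <- local_spectral_fixture()
  rep <- capture_report(sres)
  # interior boundaries within the 20 mm grid: 0.065, 1.315, 13.315
  expect_setequal(unique(rep$depth_mm), c(0.065, 1.315, 13.315))
  expect_setequal(unique(rep$detector_radius_mm), c(5, 10))
  expect_equal(rep$captured_energy_J,
               rep$energy_at_depth_J * rep$captured_fraction)
  expect_equal(rep$electric_low_J, 0.1 * rep$captured_energy_J)
  expect_equal(rep$electric_high_J, 0.2 * rep$captured_energy_J)
})

test_that("child seeds are deterministic, distinct and in range", {
  s <- child_seed(1, c(800, 825, 850, 875, 900))
  expect_identical(s, child_seed(1, c(800, 825, 850, 875, 900)))
  expect_length(unique(s), 5L)
  expect_true(all(s >= 1 & s <= 2147483646))
  expect_false(any(child_seed(2, c(800, 825, 850, 875, 900)) == s))
})
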