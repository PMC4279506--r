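# Spectral orchestration: run the transport at each discrete LED wavelength,
# combine the results by normalized spectral weights, and derive the
# aggregate products (energy-vs-depth curves, radial profiles, detector
# capture fractions).

#' Deterministic child seed for a per-wavelength run
#'
#' Child runs use independent, reproducible streams derived from the master
#' seed and the wavelength; the mapping is recorded in run manifests.
#'
#' @param master_seed integer master seed.
#' @param wavelength_nm wavelength(s) in nm.
#' @return Integer seed(s) in \code{[1, 2^31 - 2]}.
#' @export
child_seed <- function(master_seed, wavelength_nm) {
  s <- (abs(as.numeric(master_seed)) %% 2147483647)
  as.integer(1 + (s * 100003 + round(wavelength_nm) * 7919) %% 2147483645)
}

#' Run the spectrally weighted simulation
#'
#' Executes [run_single_wavelength()] at each discrete wavelength of the
#' spectrum model (child seeds derived deterministically from the master
#' seed in \code{settings}) and combines every tally and summary fraction as
#' a convex combination with the normalized spectral weights.
#'
#' @param stack a [tissue_stack()].
#' @param spectrum a [spectrum_model()].
#' @param settings a [run_settings()]; \code{settings$seed} acts as the
#'   master seed.
#' @param incident_energy_J total incident optical energy (J).
#' @return An object of class \code{spectral_result}: the per-wavelength
#'   \code{mc_result}s, the weights, and combined fractions/grids.
#' @export
#' @examples
#' sres <- run_spectrum(default_skin_stack(), spectrum_model(),
#'                      run_settings(n_photons = 1000, seed = 3,
#'                                   dr_mm = 0.5, nr = 160),
#'                      incident_energy_J = 10)
#' energy_at_depth(sres, c(0, 1.315, 13.315))
run_spectrum <- function(stack, spectrum, settings, incident_energy_J = 1) {
  stopifnot(inherits(stack, "tissue_stack"),
            inherits(spectrum, "spectrum_model"),
            inherits(settings, "run_settings"))
  ds <- discretize_spectrum(spectrum)
  seeds <- child_seed(settings$seed, ds$wavelength_nm)
  runs <- Map(function(wl, sd) {
    s <- settings
    s$seed <- sd
    run_single_wavelength(stack, s, wl, incident_energy_J)
  }, ds$wavelength_nm, seeds)
  names(runs) <- as.character(ds$wavelength_nm)
  w <- ds$weight
  wsum <- function(field) Reduce(`+`, Map(function(r, wi) wi * r[[field]],
                                          runs, w))
  res <- list(
    wavelengths_nm = ds$wavelength_nm,
    weights = w,
    raw_weights = ds$raw_weight,
    child_seeds = seeds,
    master_seed = settings$seed,
    settings = settings,
    incident_energy_J = incident_energy_J,
    per_wavelength = runs,
    layer_names = runs[[1]]$layer_names,
    boundaries_mm = runs[[1]]$boundaries_mm,
    specular_reflectance = wsum("specular_reflectance"),
    diffuse_reflectance = wsum("diffuse_reflectance"),
    transmittance = wsum("transmittance"),
    absorbed_by_layer = wsum("absorbed_by_layer"),
    roulette_net = wsum("roulette_net"),
    absorption_rz = wsum("absorption_rz"),
    crossing_rz = wsum("crossing_rz"),
    crossing_z = wsum("crossing_z"),
    reflectance_r = wsum("reflectance_r"),
    r_edges = runs[[1]]$r_edges,
    z_planes = runs[[1]]$z_planes,
    r_centers = runs[[1]]$r_centers,
    z_centers = runs[[1]]$z_centers)
  class(res) <- "spectral_result"
  res
}

#' @export
print.spectral_result <- function(x, ...) {
  cat(sprintf(
    "spectral_result: %s nm, %d photons/wavelength, incident %g J\n",
    paste(x$wavelengths_nm, collapse = "/"), x$settings$n_photons,
    x$incident_energy_J))
  cat(sprintf("  weights: %s\n", paste(sprintf("%.4f", x$weights),
                                       collapse = " ")))
  cat(sprintf("  specular %.5f, diffuse %.5f, transmittance %.3g\n",
              x$specular_reflectance, x$diffuse_reflectance, x$transmittance))
  for (nm in x$layer_names)
    cat(sprintf("  absorbed (%-9s) %.5f\n", nm, x$absorbed_by_layer[[nm]]))
  invisible(x)
}

#' @export
energy_budget.spectral_result <- function(result) {
  data.frame(
    component = c("specular_reflectance", "diffuse_reflectance",
                  paste0("absorbed_", result$layer_names),
                  "transmittance", "roulette_residual"),
    fraction = c(result$specular_reflectance, result$diffuse_reflectance,
                 unname(result$absorbed_by_layer),
                 result$transmittance, result$roulette_net))
}

#' Optical energy arriving at a depth
#'
#' Interpolates the combined first-downward-crossing tally linearly between
#' tally planes and scales by the incident energy.  At the surface (z = 0+)
#' it equals \code{incident * (1 - specular reflectance)}; it is
#' nonincreasing in depth by construction of the first-crossing tally.
#'
#' @param result a [run_spectrum()] result (also accepts a single-wavelength
#'   \code{mc_result}).
#' @param z_mm depth(s) in mm, within \code{[0, nz * dz]}.
#' @return Energy in J (vectorized over \code{z_mm}).
#' @export
energy_at_depth <- function(result, z_mm) {
  zp <- result$z_planes
  if (any(z_mm < 0) || any(z_mm > max(zp)))
    stop(sprintf("depth out of tally range [0, %g] mm", max(zp)))
  vals <- result$incident_energy_J * result$crossing_z
  approx(zp, vals, xout = z_mm)$y
}

#' Depth profile of areal energy density at a radius
#'
#' @param result a \code{spectral_result} or \code{mc_result}.
#' @param r_center_mm radius (mm) selecting the radial bin of the profile;
#'   must lie within the tally grid.
#' @return data.frame with \code{z_mm} (bin centers) and
#'   \code{energy_density_J_mm2} (deposited energy per annulus area).
#' @export
radial_profile <- function(result, r_center_mm) {
  s <- result$settings
  if (r_center_mm < 0 || r_center_mm >= s$nr * s$dr_mm)
    stop(sprintf("radius out of tally range [0, %g) mm", s$nr * s$dr_mm))
  ir <- findInterval(r_center_mm, result$r_edges, rightmost.closed = FALSE)
  ir <- max(1L, min(ir, s$nr))
  r_out <- ir * s$dr_mm
  area <- pi * (r_out^2 - (r_out - s$dr_mm)^2)
  vals <- result$incident_energy_J *
    result$absorption_rz[ir, seq_len(s$nz)] / area
  data.frame(z_mm = result$z_centers, energy_density_J_mm2 = vals)
}

#' Fraction of crossing energy captured by a coaxial detector
#'
#' Of the energy making its first downward crossing of the tally plane
#' nearest \code{depth_mm}, the fraction that crosses within
#' \code{detector_radius_mm} of the beam axis.  Whole radial bins inside the
#' detector are counted fully and the straddled bin is prorated by annular
#' area; a detector at least as large as the radial grid captures everything
#' (fraction 1, overflow included).
#'
#' @param result a \code{spectral_result} or \code{mc_result}.
#' @param detector_radius_mm detector radius (mm, > 0).
#' @param depth_mm implant depth (mm).
#' @return Captured fraction in \code{[0, 1]} (NA if no energy crosses the
#'   plane).
#' @export
captured_fraction <- function(result, detector_radius_mm, depth_mm) {
  s <- result$settings
  if (detector_radius_mm <= 0) stop("detector_radius_mm must be > 0")
  zp <- result$z_planes
  if (depth_mm < 0 || depth_mm > max(zp))
    stop(sprintf("depth out of tally range [0, %g] mm", max(zp)))
  k <- which.min(abs(zp - depth_mm))
  col <- result$crossing_rz[, k]
  tot <- sum(col)
  if (tot <= 0) return(NA_real_)
  rmax <- s$nr * s$dr_mm
  if (detector_radius_mm >= rmax) return(1)
  nfull <- floor(detector_radius_mm / s$dr_mm)
  cap <- if (nfull > 0) sum(col[seq_len(nfull)]) else 0
  r_in <- nfull * s$dr_mm
  r_out <- r_in + s$dr_mm
  frac <- (detector_radius_mm^2 - r_in^2) / (r_out^2 - r_in^2)
  cap <- cap + frac * col[nfull + 1]
  cap / tot
}

#' Capture report at the layer boundaries
#'
#' Tabulates, for each interior layer boundary and a set of detector radii,
#' the energy arriving at that depth, the captured fraction and energy, and
#' the recoverable electric energy band at 10--20\% photovoltaic efficiency.
#'
#' @param result a [run_spectrum()] result.
#' @param detector_radii_mm detector radii to report; defaults to half and a
#'   quarter of the spot diameter (i.e. the beam radius and half of it).
#' @return data.frame, one row per (depth, radius).
#' @export
capture_report <- function(result,
                           detector_radii_mm = c(
                             result$settings$beam_radius_mm / 2,
                             result$settings$beam_radius_mm)) {
  b <- result$boundaries_mm
  depths <- b[b > 0 & b <= max(result$z_planes)]
  rows <- expand.grid(depth_mm = depths,
                      detector_radius_mm = detector_radii_mm)
  rows$energy_at_depth_J <- energy_at_depth(result, rows$depth_mm)
  rows$captured_fraction <- mapply(function(r, d)
    captured_fraction(result, r, d),
    rows$detector_radius_mm, rows$depth_mm)
  rows$captured_energy_J <- rows$energy_at_depth_J * rows$captured_fraction
  pv <- vapply(rows$captured_energy_J, function(e)
    estimate_electric_power(e), numeric(2))
  rows$electric_low_J <- pv["low", ]
  rows$electric_high_J <- pv["high", ]
  rows
}
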