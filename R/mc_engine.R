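# Single-wavelength Monte Carlo transport: run settings, launch/step helpers
# exposed for verification, and the main driver around the compiled kernel.

#' Monte Carlo run settings
#'
#' Defaults reproduce the reference simulation conditions: a flat-top,
#' normally incident circular beam of 10 mm radius, a cylindrical r-z tally
#' grid of 0.05 mm bins extending to r = 80 mm and z = 20 mm (events beyond
#' the grid land in overflow bins), and MCML-standard Russian roulette
#' (threshold 1e-4, survival probability 0.1).
#'
#' @param n_photons number of photon packets to launch.
#' @param seed integer seed for R's RNG; the run is bit-identical for
#'   identical (seed, settings, stack).
#' @param beam_radius_mm beam radius at the surface (mm, flat profile only).
#' @param beam_profile \code{"flat"} (uniform disk, r = R sqrt(u)) or
#'   \code{"pencil"} (all photons on the axis).
#' @param dr_mm,nr radial bin width (mm) and bin count.
#' @param dz_mm,nz depth bin width (mm) and bin count.
#' @param roulette_threshold weight below which Russian roulette is played.
#' @param roulette_survival survival probability in roulette (0 < p < 1).
#' @return An object of class \code{run_settings}.
#' @export
run_settings <- function(n_photons = 10000, seed = 1,
                         beam_radius_mm = 10,
                         beam_profile = c("flat", "pencil"),
                         dr_mm = 0.05, nr = 1600,
                         dz_mm = 0.05, nz = 400,
                         roulette_threshold = 1e-4,
                         roulette_survival = 0.1) {
  beam_profile <- match.arg(beam_profile)
  if (n_photons < 1) stop("n_photons must be >= 1")
  if (beam_radius_mm < 0) stop("beam_radius_mm must be >= 0")
  if (dr_mm <= 0 || dz_mm <= 0 || nr < 1 || nz < 1)
    stop("tally grid must have positive bin widths and counts")
  if (roulette_survival <= 0 || roulette_survival >= 1)
    stop("roulette_survival must lie in (0, 1)")
  structure(list(n_photons = as.integer(n_photons), seed = as.integer(seed),
                 beam_radius_mm = beam_radius_mm, beam_profile = beam_profile,
                 dr_mm = dr_mm, nr = as.integer(nr),
                 dz_mm = dz_mm, nz = as.integer(nz),
                 roulette_threshold = roulette_threshold,
                 roulette_survival = roulette_survival),
            class = "run_settings")
}

#' Specular reflectance at normal incidence
#'
#' @param n1,n2 refractive indices on the two sides of the interface (>= 1).
#' @return \code{((n1 - n2) / (n1 + n2))^2}.
#' @export
#' @examples
#' specular_reflect(1.0, 1.34)  # air / epidermis
specular_reflect <- function(n1, n2) {
  if (any(c(n1, n2) < 1)) stop("refractive indices must be >= 1")
  ((n1 - n2) / (n1 + n2))^2
}

#' Sample free-path step lengths
#'
#' Path lengths between interactions are exponential with mean \code{1/mu_t}:
#' \code{s = -log(u) / mu_t}.
#'
#' @param n number of draws.
#' @param mu_t_per_mm total interaction coefficient (1/mm, > 0).
#' @return Numeric vector of step lengths in mm.
#' @export
sample_step <- function(n, mu_t_per_mm) {
  if (mu_t_per_mm <= 0)
    stop("mu_t must be > 0 (vacuum layers are unsupported)")
  -log(runif(n)) / mu_t_per_mm
}

#' Sample launch radii for a beam profile
#'
#' Flat-top beams sample the radius as \code{R sqrt(u)} (uniform over the
#' disk); pencil beams launch every photon on the axis.
#'
#' @param n number of draws.
#' @param beam_radius_mm beam radius (mm).
#' @param beam_profile \code{"flat"} or \code{"pencil"}.
#' @return Numeric vector of launch radii in mm.
#' @export
launch_radii <- function(n, beam_radius_mm, beam_profile = "flat") {
  if (identical(beam_profile, "pencil")) return(rep(0, n))
  beam_radius_mm * sqrt(runif(n))
}

# internal: sd-of-mean from per-photon sum and sum of squares
.se_mean <- function(s, ss, n) {
  if (n < 2) return(NA_real_)
  v <- (ss - s^2 / n) / (n - 1)
  sqrt(pmax(v, 0) / n)
}

#' Run the Monte Carlo transport at a single wavelength
#'
#' Launches \code{n_photons} packets into the stack at the given wavelength
#' and tallies absorption on a cylindrical r-z grid, per-layer absorbed
#' fractions, radially resolved diffuse reflectance and transmittance,
#' specular reflectance, and the first downward crossing of each tally
#' z-plane.  All tallies are normalized per launched photon; energies scale
#' by \code{incident_energy_J}.
#'
#' @param stack a [tissue_stack()].
#' @param settings a [run_settings()].
#' @param wavelength_nm wavelength (nm); every layer must resolve properties
#'   there.
#' @param incident_energy_J total optical energy incident on the surface (J);
#'   used to scale energy outputs.
#' @return An object of class \code{mc_result}: summary fractions with Monte
#'   Carlo standard errors, normalized tally arrays, and grid coordinates.
#'   The budget identity specular + diffuse + transmitted + absorbed -
#'   roulette residual = 1 holds to floating point.
#' @export
#' @examples
#' res <- run_single_wavelength(default_skin_stack(),
#'                              run_settings(n_photons = 2000, seed = 7,
#'                                           dr_mm = 0.5, nr = 160),
#'                              wavelength_nm = 850)
#' res$absorbed_by_layer
run_single_wavelength <- function(stack, settings, wavelength_nm,
                                  incident_energy_J = 1) {
  stopifnot(inherits(stack, "tissue_stack"), inherits(settings, "run_settings"))
  if (incident_energy_J < 0) stop("incident_energy_J must be >= 0")
  tc <- transport_coefficients(stack, wavelength_nm)
  set.seed(settings$seed)
  raw <- mc_transport(
    mua = tc$mua_mm, mus = tc$mus_mm, g = tc$g, n_idx = tc$n,
    boundaries = tc$boundaries,
    n_above = stack$n_above, n_below = stack$n_below,
    n_photons = settings$n_photons,
    beam_radius = settings$beam_radius_mm,
    pencil = identical(settings$beam_profile, "pencil"),
    dr = settings$dr_mm, nr = settings$nr,
    dz = settings$dz_mm, nz = settings$nz,
    roulette_threshold = settings$roulette_threshold,
    roulette_survival = settings$roulette_survival)
  n <- settings$n_photons
  st <- raw$stats
  absorbed <- setNames(raw$per_layer / n, tc$layer_names)
  se_abs <- setNames(.se_mean(st$dep_sum, st$dep_ss, n), tc$layer_names)
  res <- list(
    wavelength_nm = wavelength_nm,
    n_photons = n,
    seed = settings$seed,
    settings = settings,
    incident_energy_J = incident_energy_J,
    layer_names = tc$layer_names,
    boundaries_mm = tc$boundaries,
    specular_reflectance = raw$specular / n,
    diffuse_reflectance = sum(raw$reflectance_r) / n,
    transmittance = sum(raw$transmittance_r) / n,
    absorbed_by_layer = absorbed,
    roulette_net = raw$roulette_net / n,
    se = list(absorbed_by_layer = se_abs,
              diffuse_reflectance = .se_mean(st$refl_sum, st$refl_ss, n),
              transmittance = .se_mean(st$trans_sum, st$trans_ss, n),
              roulette_net = .se_mean(st$rou_sum, st$rou_ss, n),
              x_moment = .se_mean(st$xdep_sum, st$xdep_ss, n),
              y_moment = .se_mean(st$ydep_sum, st$ydep_ss, n)),
    x_moment = st$xdep_sum / n,
    y_moment = st$ydep_sum / n,
    absorption_rz = raw$absorption / n,
    crossing_rz = raw$crossing / n,
    crossing_z = colSums(raw$crossing) / n,
    reflectance_r = raw$reflectance_r / n,
    transmittance_r = raw$transmittance_r / n,
    r_edges = seq(0, settings$nr) * settings$dr_mm,
    z_edges = seq(0, settings$nz) * settings$dz_mm,
    z_planes = seq(0, settings$nz) * settings$dz_mm,
    r_centers = (seq_len(settings$nr) - 0.5) * settings$dr_mm,
    z_centers = (seq_len(settings$nz) - 0.5) * settings$dz_mm,
    capped = raw$capped)
  class(res) <- "mc_result"
  res
}

#' @export
print.mc_result <- function(x, ...) {
  cat(sprintf("mc_result: %g nm, %d photons (seed %d)\n",
              x$wavelength_nm, x$n_photons, x$seed))
  cat(sprintf("  specular reflectance   %.5f\n", x$specular_reflectance))
  cat(sprintf("  diffuse reflectance    %.5f (se %.1e)\n",
              x$diffuse_reflectance, x$se$diffuse_reflectance))
  cat(sprintf("  transmittance          %.3g\n", x$transmittance))
  for (nm in x$layer_names)
    cat(sprintf("  absorbed (%-9s)    %.5f (se %.1e)\n", nm,
                x$absorbed_by_layer[[nm]], x$se$absorbed_by_layer[[nm]]))
  cat(sprintf("  budget closure         %.3e (roulette residual)\n",
              x$roulette_net))
  invisible(x)
}

#' Energy budget of a run
#'
#' @param result an [run_single_wavelength()] or [run_spectrum()] result.
#' @return data.frame with one row per budget component (fractions of
#'   launched energy) plus the roulette residual; the components minus the
#'   residual sum to 1.
#' @export
energy_budget <- function(result) {
  UseMethod("energy_budget")
}

#' @export
energy_budget.mc_result <- function(result) {
  data.frame(
    component = c("specular_reflectance", "diffuse_reflectance",
                  paste0("absorbed_", result$layer_names),
                  "transmittance", "roulette_residual"),
    fraction = c(result$specular_reflectance, result$diffuse_reflectance,
                 unname(result$absorbed_by_layer),
                 result$transmittance, result$roulette_net))
}

#' Energy-density map of a result
#'
#' Converts the normalized r-z absorption tally into an energy-density map
#' for the result's incident energy.  The areal convention divides each bin's
#' deposited energy by its annular area (J/mm^2); the volumetric convention
#' divides additionally by the depth-bin height (J/mm^3).  Overflow bins are
#' dropped.
#'
#' @param result an \code{mc_result} or \code{spectral_result}.
#' @param convention \code{"areal"} or \code{"volumetric"}.
#' @return Matrix (nr x nz) with attributes \code{r_centers_mm} and
#'   \code{z_centers_mm}.
#' @export
energy_density <- function(result, convention = c("areal", "volumetric")) {
  convention <- match.arg(convention)
  s <- result$settings
  A <- result$absorption_rz[seq_len(s$nr), seq_len(s$nz), drop = FALSE]
  r_out <- seq_len(s$nr) * s$dr_mm
  r_in <- r_out - s$dr_mm
  area <- pi * (r_out^2 - r_in^2)
  dens <- result$incident_energy_J * A / area
  if (convention == "volumetric") dens <- dens / s$dz_mm
  attr(dens, "r_centers_mm") <- result$r_centers
  attr(dens, "z_centers_mm") <- result$z_centers
  dens
}
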