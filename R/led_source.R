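# LED source model: Gaussian spectral proportions discretized to a small set
# of wavelengths, lens/spot geometry, incident power density, and the ICNIRP
# irradiance safety check.

#' Gaussian spectrum model of an LED source
#'
#' The spectral proportion at wavelength lambda is
#' \code{f(lambda) = a1 * exp(-((lambda - b1) / c1)^2)}.  The defaults
#' describe an 850 nm near-infrared LED discretized at five wavelengths
#' spanning 800--900 nm.
#'
#' @param a1 peak proportion (> 0).
#' @param b1 central wavelength (nm).
#' @param c1 Gaussian width (nm, > 0).
#' @param wavelengths_nm discrete wavelengths at which the spectrum is
#'   evaluated and the transport is run.
#' @return An object of class \code{spectrum_model}.
#' @export
#' @examples
#' discretize_spectrum(spectrum_model())
spectrum_model <- function(a1 = 0.5494, b1 = 850, c1 = 24.93,
                           wavelengths_nm = c(800, 825, 850, 875, 900)) {
  if (!is.numeric(a1) || a1 <= 0) stop("a1 must be > 0")
  if (!is.numeric(c1) || c1 <= 0) stop("c1 must be > 0")
  if (!is.numeric(wavelengths_nm) || length(wavelengths_nm) < 1)
    stop("wavelengths_nm must be a non-empty numeric vector")
  if (any(duplicated(wavelengths_nm)))
    stop("wavelengths_nm must not contain duplicates")
  structure(list(a1 = a1, b1 = b1, c1 = c1,
                 wavelengths_nm = sort(wavelengths_nm)),
            class = "spectrum_model")
}

#' Spectral proportion of an LED at a wavelength
#'
#' @param spec a [spectrum_model()].
#' @param wavelength_nm wavelength(s) in nm.
#' @return \code{a1 * exp(-((wavelength - b1) / c1)^2)} (vectorized).
#' @export
#' @examples
#' spectral_proportion(spectrum_model(), 850)  # = a1
spectral_proportion <- function(spec, wavelength_nm) {
  stopifnot(inherits(spec, "spectrum_model"))
  spec$a1 * exp(-((wavelength_nm - spec$b1) / spec$c1)^2)
}

#' Discretize an LED spectrum into per-wavelength weights
#'
#' Raw weights are the Gaussian proportions evaluated at the model's discrete
#' wavelengths; normalized weights divide by their sum so that spectrally
#' combined energies conserve the configured incident energy.
#'
#' @param spec a [spectrum_model()].
#' @return data.frame with columns \code{wavelength_nm}, \code{raw_weight},
#'   \code{weight} (normalized, summing to 1).
#' @export
discretize_spectrum <- function(spec) {
  stopifnot(inherits(spec, "spectrum_model"))
  raw <- spectral_proportion(spec, spec$wavelengths_nm)
  if (sum(raw) <= 0)
    stop("degenerate spectrum: all discrete proportions are zero")
  data.frame(wavelength_nm = spec$wavelengths_nm,
             raw_weight = raw,
             weight = raw / sum(raw))
}

#' Lens and spot geometry of the wearable source
#'
#' The LED is collimated and focused by a planoconvex lens; the skin sits a
#' distance \code{l_mm} beyond the focal point, so the illuminated spot has
#' diameter \code{d = D l / ((n_lens - 1) R)}.
#'
#' @param D_mm lens aperture (mm).
#' @param R_mm lens curvature radius (mm).
#' @param n_lens lens refractive index (> 1).
#' @param l_mm distance between the skin surface and the lens focus (mm).
#' @param divergence_deg LED scattering half-angle (degrees); informational
#'   only, the beam at the skin is modelled as a flat-top spot.
#' @param power_mW total optical power delivered to the spot (mW).
#' @return An object of class \code{source_geometry}.
#' @export
#' @examples
#' spot_diameter(source_geometry())  # 20 mm with the defaults
source_geometry <- function(D_mm = 25, R_mm = 12.5, n_lens = 1.5, l_mm = 5,
                            divergence_deg = 60, power_mW = 10) {
  if (D_mm <= 0 || R_mm <= 0) stop("D_mm and R_mm must be > 0")
  if (n_lens <= 1) stop("n_lens must be > 1")
  if (l_mm < 0) stop("l_mm must be >= 0")
  if (power_mW < 0) stop("power_mW must be >= 0")
  structure(list(D_mm = D_mm, R_mm = R_mm, n_lens = n_lens, l_mm = l_mm,
                 divergence_deg = divergence_deg, power_mW = power_mW),
            class = "source_geometry")
}

#' Spot diameter at the skin surface
#'
#' @param geom a [source_geometry()].
#' @return Spot diameter \code{d = D l / ((n_lens - 1) R)} in mm.
#' @export
spot_diameter <- function(geom) {
  stopifnot(inherits(geom, "source_geometry"))
  geom$D_mm * geom$l_mm / ((geom$n_lens - 1) * geom$R_mm)
}

#' Spot area at the skin surface
#'
#' @param geom a [source_geometry()].
#' @return Spot area \code{pi (d/2)^2} in mm^2.
#' @export
spot_area <- function(geom) {
  d <- spot_diameter(geom)
  pi * (d / 2)^2
}

#' Incident power density on the skin
#'
#' @param power_mW optical power over the spot (mW).
#' @param spot_diameter_mm spot diameter (mm, > 0).
#' @return Power density \code{4 P / (pi d^2)} in mW/mm^2.
#' @export
#' @examples
#' power_density(332, 17.5)  # 1.38 mW/mm^2
power_density <- function(power_mW, spot_diameter_mm) {
  if (power_mW < 0) stop("power_mW must be >= 0")
  if (spot_diameter_mm <= 0)
    stop("spot_diameter_mm must be > 0; move the skin off the focal point ",
         "(l_mm > 0) to obtain a finite spot")
  4 * power_mW / (pi * spot_diameter_mm^2)
}

#' ICNIRP skin-irradiance safety limits
#'
#' For visible and near-infrared light (400--1400 nm) the irradiance on skin
#' should not exceed \code{2.0e3 * C_A} W/m^2, with exposure limited to
#' 8.33 h.  \code{C_A} is the ICNIRP wavelength-dependent correction factor;
#' the conservative default is 1.
#'
#' @param base_limit_W_m2 base irradiance limit (W/m^2).
#' @param C_A wavelength-dependent multiplier (>= 1).
#' @param max_exposure_hours maximum continuous exposure (h).
#' @return An object of class \code{safety_spec}.
#' @export
safety_spec <- function(base_limit_W_m2 = 2000, C_A = 1,
                        max_exposure_hours = 8.33) {
  if (base_limit_W_m2 <= 0) stop("base_limit_W_m2 must be > 0")
  if (C_A < 1) stop("C_A must be >= 1")
  structure(list(base_limit_W_m2 = base_limit_W_m2, C_A = C_A,
                 max_exposure_hours = max_exposure_hours),
            class = "safety_spec")
}

#' Check an incident power density against the ICNIRP limit
#'
#' Converts mW/mm^2 to W/m^2 (factor 1000) and compares against
#' \code{base_limit * C_A}.  The regulatory bound is treated inclusively:
#' an irradiance exactly at the limit passes with margin ratio 1.
#'
#' @param power_density_mW_mm2 incident power density (mW/mm^2).
#' @param safety a [safety_spec()].
#' @return List with \code{pass} (logical), \code{irradiance_W_m2},
#'   \code{limit_W_m2} and \code{margin_ratio} (irradiance / limit).
#' @export
#' @examples
#' check_safety(power_density(332, 17.5))
check_safety <- function(power_density_mW_mm2, safety = safety_spec()) {
  stopifnot(inherits(safety, "safety_spec"))
  if (power_density_mW_mm2 < 0) stop("power density must be >= 0")
  irr <- power_density_mW_mm2 * 1000
  limit <- safety$base_limit_W_m2 * safety$C_A
  list(pass = irr <= limit,
       irradiance_W_m2 = irr,
       limit_W_m2 = limit,
       margin_ratio = irr / limit)
}

#' Recoverable electric power from a photovoltaic cell
#'
#' Applies a flat optical-to-electric efficiency band to the optical power
#' reaching the cell.
#'
#' @param optical_power_mW optical power at the photosensitive surface (mW).
#' @param efficiency_low,efficiency_high conversion-efficiency band,
#'   \code{0 < low <= high <= 1} (defaults 10--20\%, typical of small
#'   photovoltaic cells).
#' @return Named numeric vector \code{c(low = , high = )} in mW.
#' @export
#' @examples
#' estimate_electric_power(34)  # 3.4--6.8 mW
estimate_electric_power <- function(optical_power_mW, efficiency_low = 0.10,
                                    efficiency_high = 0.20) {
  if (optical_power_mW < 0) stop("optical_power_mW must be >= 0")
  if (efficiency_low <= 0 || efficiency_high > 1 ||
      efficiency_low > efficiency_high)
    stop("efficiencies must satisfy 0 < low <= high <= 1")
  c(low = optical_power_mW * efficiency_low,
    high = optical_power_mW * efficiency_high)
}
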