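# Built-in physics validation harness: closed-form oracles for the transport
# engine (Beer-Lambert attenuation, Fresnel reflectance, Henyey-Greenstein
# moments, global energy conservation, seed determinism).

.single_layer_stack <- function(mu_a_percm, mu_s_percm, g, n, thickness_mm,
                                n_above = NULL, n_below = NULL) {
  l <- tissue_layer("slab", thickness_mm,
                    data.frame(wavelength_nm = 850, mu_a_percm = mu_a_percm,
                               mu_s_percm = mu_s_percm, g = g, n = n),
                    wavelength_independent = TRUE)
  tissue_stack(list(l), n_above = if (is.null(n_above)) n else n_above,
               n_below = n_below)
}

#' Run the built-in physics validation suite
#'
#' Executes closed-form checks of the transport engine: Beer-Lambert
#' transmittance of non-scattering slabs, normal-incidence Fresnel
#' reflectance, Henyey-Greenstein mean-cosine moments, global energy-budget
#' closure on the default skin stack, reflectance of a conservative
#' scattering slab, and bit-identical seed determinism.  Stochastic checks
#' use a 3-standard-error tolerance.
#'
#' @param quick if \code{TRUE} (default) uses reduced photon counts suitable
#'   for routine checking; \code{FALSE} uses 1e5 photons per transport check.
#' @param seed RNG seed for the suite.
#' @return data.frame with one row per check: \code{check},
#'   \code{expected}, \code{measured}, \code{tolerance}, \code{pass}.
#' @export
#' @examples
#' run_validation_suite(quick = TRUE)
run_validation_suite <- function(quick = TRUE, seed = 20141103) {
  n_mc <- if (quick) 20000L else 100000L
  n_hg <- if (quick) 200000L else 1000000L
  rows <- list()
  add <- function(check, expected, measured, tolerance)
    rows[[length(rows) + 1L]] <<- data.frame(
      check = check, expected = expected, measured = measured,
      tolerance = tolerance, pass = abs(measured - expected) <= tolerance)

  # Fresnel normal incidence, air onto epidermis (n = 1.34)
  add("fresnel_normal_air_epidermis",
      specular_reflect(1.0, 1.34),
      fresnel_unpolarized(1.0, 1.34, 1.0),
      1e-12)

  # Beer-Lambert: non-scattering, index-matched slabs
  bl <- list(c(mu_a = 1.0, L = 10), c(mu_a = 5.0, L = 3), c(mu_a = 20.0, L = 1))
  for (i in seq_along(bl)) {
    mu_a <- bl[[i]]["mu_a"]  # 1/cm
    L <- bl[[i]]["L"]        # mm
    stack <- .single_layer_stack(mu_a, 0, 0, 1.0, L)
    set <- run_settings(n_photons = n_mc, seed = seed + i,
                        beam_profile = "pencil", dr_mm = 1, nr = 50,
                        dz_mm = L / 50, nz = 50)
    res <- run_single_wavelength(stack, set, 850)
    expected <- exp(-(mu_a / 10) * L)
    se <- sqrt(expected * (1 - expected) / n_mc)
    add(sprintf("beer_lambert_mua%g_L%g", mu_a, L), expected,
        res$transmittance, 3 * se)
  }

  # Henyey-Greenstein mean cosine equals g
  for (g in c(0, 0.62, 0.85)) {
    set.seed(seed + round(100 * g))
    draws <- hg_sample_cos(n_hg, g)
    se <- stats::sd(draws) / sqrt(n_hg)
    add(sprintf("hg_mean_cos_g%g", g), g, mean(draws), 3 * se)
  }

  # Global energy budget on the default stack
  res <- run_single_wavelength(
    default_skin_stack(),
    run_settings(n_photons = n_mc, seed = seed, dr_mm = 0.5, nr = 160,
                 dz_mm = 0.1, nz = 200), 850)
  total <- res$specular_reflectance + res$diffuse_reflectance +
    res$transmittance + sum(res$absorbed_by_layer)
  add("energy_budget_exact_with_residual", 1, total - res$roulette_net, 1e-9)
  add("energy_budget_physical", 1, total,
      max(3 * res$se$roulette_net, 1e-9))

  # Conservative scattering slab: all launched weight re-emerges
  stack <- .single_layer_stack(0, 100, 0, 1.0, 10)
  set <- run_settings(n_photons = max(2000L, n_mc %/% 10), seed = seed,
                      beam_profile = "pencil", dr_mm = 1, nr = 50,
                      dz_mm = 0.2, nz = 50)
  cons <- run_single_wavelength(stack, set, 850)
  add("conservative_slab_budget", 1,
      cons$diffuse_reflectance + cons$transmittance, 1e-9)
  add("conservative_slab_reflectance_dominates", 1,
      as.numeric(cons$diffuse_reflectance > 0.9), 0)

  # Seed determinism: identical seeds give identical tallies
  set <- run_settings(n_photons = 2000, seed = seed, dr_mm = 0.5, nr = 160,
                      dz_mm = 0.1, nz = 200)
  r1 <- run_single_wavelength(default_skin_stack(), set, 850)
  r2 <- run_single_wavelength(default_skin_stack(), set, 850)
  add("seed_determinism", 0,
      max(abs(r1$absorption_rz - r2$absorption_rz),
          abs(r1$crossing_z - r2$crossing_z),
          abs(r1$diffuse_reflectance - r2$diffuse_reflectance)), 0)

  do.call(rbind, rows)
}
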