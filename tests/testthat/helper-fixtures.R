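# Shared fixtures: small stacks and coarse tally settings used across tests.

single_layer_stack <- function(mu_a_percm, mu_s_percm, g, n, thickness_mm,
                               n_above = n, n_below = NULL) {
  layer <- tissue_layer(
    "slab", thickness_mm,
    data.frame(wavelength_nm = 850, mu_a_percm = mu_a_percm,
               mu_s_percm = mu_s_percm, g = g, n = n),
    wavelength_independent = TRUE)
  tissue_stack(list(layer), n_above = n_above, n_below = n_below)
}

# coarse grid keeps small test runs cheap; physics is grid-independent
coarse_settings <- function(n_photons = 5000, seed = 1, ...) {
  run_settings(n_photons = n_photons, seed = seed,
               dr_mm = 0.5, nr = 160, dz_mm = 0.1, nz = 200, ...)
}

table2_printed_proportions <- c(0.0098, 0.2010, 0.5494, 0.2010, 0.0098)
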