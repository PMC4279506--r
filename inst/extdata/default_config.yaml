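# Default simulation configuration: four-layer skin model with tabulated
# optical properties at 800/825/850/875/900 nm (coefficients in 1/cm,
# thicknesses in mm), an 850 nm LED source with a Gaussian spectral model,
# and the reference run settings (flat-top 10 mm beam, 0.05 mm r-z tallies).
tissue:
  n_above: 1.0
  n_below: 1.37
  layers:
    - name: epidermis
      thickness_mm: 0.065
      wavelength_independent: true
      properties:
        - {mu_a_percm: 55.0, mu_s_percm: 450.0, g: 0.8, n_rel: 1.34}
    - name: dermis
      thickness_mm: 1.25
      properties:
        - {wavelength_nm: 800, mu_a_percm: 0.127, mu_s_percm: 19.07, g: 0.86, n_rel: 1.55}
        - {wavelength_nm: 825, mu_a_percm: 0.121, mu_s_percm: 18.24, g: 0.87, n_rel: 1.55}
        - {wavelength_nm: 850, mu_a_percm: 0.122, mu_s_percm: 17.57, g: 0.87, n_rel: 1.55}
        - {wavelength_nm: 875, mu_a_percm: 0.122, mu_s_percm: 16.98, g: 0.88, n_rel: 1.55}
        - {wavelength_nm: 900, mu_a_percm: 0.134, mu_s_percm: 16.30, g: 0.89, n_rel: 1.55}
    - name: fat
      thickness_mm: 12.0
      properties:
        - {wavelength_nm: 800, mu_a_percm: 0.083, mu_s_percm: 11.09, g: 0.64, n_rel: 1.45}
        - {wavelength_nm: 825, mu_a_percm: 0.085, mu_s_percm: 11.12, g: 0.63, n_rel: 1.45}
        - {wavelength_nm: 850, mu_a_percm: 0.086, mu_s_percm: 11.09, g: 0.62, n_rel: 1.45}
        - {wavelength_nm: 875, mu_a_percm: 0.091, mu_s_percm: 10.97, g: 0.60, n_rel: 1.45}
        - {wavelength_nm: 900, mu_a_percm: 0.125, mu_s_percm: 10.88, g: 0.59, n_rel: 1.45}
    - name: muscle
      thickness_mm: 1.0e+8
      properties:
        - {wavelength_nm: 800, mu_a_percm: 0.284, mu_s_percm: 6.60, g: 0.85, n_rel: 1.37}
        - {wavelength_nm: 825, mu_a_percm: 0.309, mu_s_percm: 6.78, g: 0.85, n_rel: 1.37}
        - {wavelength_nm: 850, mu_a_percm: 0.343, mu_s_percm: 6.60, g: 0.85, n_rel: 1.37}
        - {wavelength_nm: 875, mu_a_percm: 0.368, mu_s_percm: 6.43, g: 0.85, n_rel: 1.37}
        - {wavelength_nm: 900, mu_a_percm: 0.393, mu_s_percm: 6.32, g: 0.85, n_rel: 1.37}
source:
  a1: 0.5494
  b1_nm: 850
  c1_nm: 24.93
  wavelengths_nm: [800, 825, 850, 875, 900]
  power_mW: 10
  lens: {D_mm: 25, R_mm: 12.5, n_lens: 1.5}
  l_mm: 5
  divergence_deg: 60
  safety: {base_limit_W_m2: 2000, C_A: 1, max_hours: 8.33}
run:
  n_photons: 100000
  seed: 1
  beam_radius_mm: 10
  beam_profile: flat
  dr_mm: 0.05
  nr: 1600
  dz_mm: 0.05
  nz: 400
  roulette_threshold: 1.0e-04
  roulette_survival: 0.1
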