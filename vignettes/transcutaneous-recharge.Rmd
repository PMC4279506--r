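---
title: "Methods: Monte Carlo transport for transcutaneous optical recharging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Monte Carlo transport for transcutaneous optical recharging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`dermamc` simulates how near-infrared light from a wearable LED propagates
through layered skin, to estimate the optical power that can be harvested by
an implanted photovoltaic cell. This vignette is the package's account of
its model, its tunable parameters, its numerical choices, and the limits of
what its tests demonstrate.

## The transport model

Radiative transfer in strongly scattering tissue is solved by Monte Carlo
simulation in the style that MCML standardized for multi-layered media, the
reference approach in tissue optics. Photon packets carry a statistical
weight rather than being absorbed all-or-nothing, which suppresses variance
at fixed photon count.

For each packet:

1. **Launch.** The packet starts at the surface travelling along +z with
   weight 1. A flat-top beam samples the launch radius as $r = R\sqrt{\xi}$
   (uniform over the disk); a pencil beam launches on the axis. At the
   air–tissue interface the deterministic specular fraction
   $((n_1-n_2)/(n_1+n_2))^2$ is deducted once — for air onto an epidermis
   of $n = 1.34$ that is 0.0211.
2. **Free path.** Step lengths are exponential,
   $s = -\ln\xi / \mu_t$, with $\mu_t = \mu_a + \mu_s$. The dimensionless
   optical depth remaining in a step is preserved across layer boundaries
   and rescaled by the local $\mu_t$, so boundary crossings do not bias the
   path-length distribution.
3. **Interaction.** A fraction $\mu_a/\mu_t$ of the weight is deposited at
   the interaction site (into a cylindrical $r$–$z$ grid and a per-layer
   accumulator) and the packet is deflected by the Henyey–Greenstein phase
   function, whose single parameter $g$ equals the mean deflection cosine;
   $g=0$ is isotropic and tissue values of 0.6–0.9 are strongly
   forward-peaked. The azimuth is uniform.
4. **Boundaries.** When a step reaches a layer interface, the unpolarized
   Fresnel coefficient at the actual incidence angle decides between
   reflection (flip of the z-direction cosine) and transmission with Snell
   refraction. Incidence beyond the critical angle reflects totally —
   important here because the dermis ($n = 1.55$) is optically denser than
   both neighbours, so oblique light is partially waveguided within it.
   Packets transmitted through the top surface tally into radially resolved
   diffuse reflectance; packets leaving the bottom tally as transmittance.
5. **Termination.** Below weight $10^{-4}$ a packet plays Russian roulette:
   it survives with probability 0.1 and weight boosted $\times 10$,
   otherwise it is dropped. Roulette is unbiased in expectation; the kernel
   additionally records the per-run net weight it created or removed (the
   *roulette residual*), so that
   specular + diffuse + transmitted + absorbed − residual = 1 holds to
   floating-point accuracy on every run, and the residual's Monte Carlo
   standard error quantifies the purely statistical part of any budget
   misclosure.

The kernel is compiled (Rcpp) and draws from R's own RNG stream, so any run
is bit-reproducible from `set.seed()`; wrappers seed deterministically from
the settings.

## The tissue model

Tissue is a stack of laterally infinite slabs, each with thickness,
$\mu_a$, $\mu_s$, $g$ and refractive index $n$. The default
`default_skin_stack()` is a four-layer model of human skin over muscle with
properties tabulated at 800, 825, 850, 875 and 900 nm:

* epidermis, 0.065 mm — strongly pigmented
  ($\mu_a = 55\,\mathrm{cm^{-1}}$, $\mu_s = 450\,\mathrm{cm^{-1}}$,
  $g = 0.8$, $n = 1.34$), treated as wavelength-independent over this band;
* dermis, 1.25 mm — weakly absorbing, moderately scattering, $n = 1.55$;
* subcutaneous fat, 12 mm — $n = 1.45$;
* muscle — represented with an enormous printed thickness
  ($10^8$ mm) rather than a special semi-infinite flag; photons never reach
  its lower boundary in practice, and the bottom ambient index is matched
  to muscle so no artificial bottom-interface physics is introduced.

Coefficients are stored in $\mathrm{cm^{-1}}$, the unit in which such
tables are conventionally printed, and converted once to
$\mathrm{mm^{-1}}$ when a run starts; all geometry is in mm. Lookups at a
tabulated wavelength reproduce the table row exactly; non-tabulated
wavelengths interpolate $\mu_a$, $\mu_s$ and $g$ linearly between
bracketing rows (requesting outside the tabulated range is an error, not an
extrapolation). Dispersion is deliberately not modelled: $n$ is constant
per layer. Sources in the literature disagree by an order of magnitude on
some skin-layer thicknesses; the defaults above are the self-consistent
set whose interface depths (0.065 mm, 1.315 mm, 13.315 mm) the rest of the
package assumes, and any alternative can be supplied through the YAML
configuration.

## The source model

The LED spectrum is a Gaussian in wavelength,
$f(\lambda) = a_1 e^{-((\lambda-b_1)/c_1)^2}$, with defaults
$a_1 = 0.5494$, $b_1 = 850$ nm, $c_1 = 24.93$ nm — an 850 nm near-infrared
LED, a band chosen in practice because it penetrates skin comparatively
deeply and matches silicon photovoltaic responsivity. The spectrum is
discretized at five wavelengths (800–900 nm in 25 nm steps). The five raw
proportions sum to 0.971, not 1; energy aggregation therefore uses
*normalized* weights so that the combined run conserves the configured
incident energy, while the raw values remain available from
`discretize_spectrum()`. Each discrete wavelength is simulated
independently (child seeds derived deterministically from the master seed
and the wavelength, recorded in the run manifest) and every tally is
combined as a convex combination — a property the test suite checks
elementwise.

Spatially the source reduces to a flat-top spot at the skin surface:
the lens relation $d = D\,l/((n-1)R)$ sets the spot diameter (default
geometry gives 20 mm, i.e. a 10 mm beam radius) and $I = 4P/(\pi d^2)$ the
power density. The LED's 60° divergence and its reflector are not traced;
the simulated beam enters normally, because the converging optics provide
no angular distribution to sample and oblique incidence at these f-numbers
changes the Fresnel entry loss only in the third decimal. The ICNIRP
skin-irradiance bound $2.0\times10^3\,C_A\ \mathrm{W/m^2}$ is implemented
as an inclusive comparison with the margin reported; $C_A$ defaults to the
conservative value 1 and is configurable.

## Tallies and derived products

Absorption is tallied on a cylindrical grid with defaults
$\Delta r = 0.05$ mm to 80 mm and $\Delta z = 0.05$ mm to 20 mm; events
beyond the grid land in explicit overflow bins so that budgets close
without clipping. Two energy-density conventions are emitted: areal
(deposited energy per annulus area, J/mm²) and volumetric (additionally per
bin height, J/mm³).

"Energy arriving at depth z" is defined by the **first downward crossing**
tally: each packet contributes its current weight to a plane the first time
it crosses that plane going down. This definition satisfies two properties
the package treats as contracts: at the surface it equals
incident × (1 − specular), and it is nonincreasing in depth (a packet
cannot first-cross a deeper plane before a shallower one, and weight only
decreases between crossings, up to the statistically negligible roulette
boosts). An alternative "net flux" definition (incident minus all
reflectance minus absorption above z) is smaller wherever backscattered
light recrosses planes upward; the first-crossing convention was chosen
because it represents the energy a detector at that depth could in
principle intercept, and because it keeps the surface identity exact.
`energy_at_depth()` interpolates linearly between tally planes.
`captured_fraction()` resolves the crossing tally radially: whole bins
inside the detector count fully, the straddled bin is prorated by annular
area, which makes the fraction exactly monotone in detector radius.

## Numerical choices and degenerate inputs

* Roulette threshold $10^{-4}$ and survival 0.1 are the MCML defaults;
  with $10^5$ packets the roulette residual is of order $10^{-6}$ of the
  launched energy.
* Layers with $\mu_t = 0$ (vacuum) are rejected with an error; pure
  absorbers ($\mu_s = 0$) and pure scatterers ($\mu_a = 0$) are valid and
  are used by the validation oracles.
* $g = \pm 1$ is accepted by the sampler (clamped deflection); the default
  tissue values never reach it.
* A spectrum whose discrete proportions all underflow to zero is a
  degenerate-spectrum error rather than a silent all-zero run.
* Spot diameter 0 (skin at the lens focus) makes the power density
  undefined; the error message says how to resolve it ($l > 0$).
* CSV outputs print floats at 17 significant digits so that re-reading
  reproduces arrays bit-for-bit; manifests carry MD5 checksums of every
  file.

## Validation and what it does — and does not — show

`run_validation_suite()` checks the engine against independent oracles:
Beer–Lambert transmittance $e^{-\mu_a L}$ of non-scattering slabs (three
$(\mu_a, L)$ pairs), the closed-form normal-incidence Fresnel coefficient,
Henyey–Greenstein mean cosines at $g \in \{0, 0.62, 0.85\}$, exact budget
closure including the roulette residual, full weight recovery from a
conservative (non-absorbing) scattering slab, and bit-identical reruns
under a fixed seed. Stochastic checks use 3-standard-error tolerances. The
kernel was additionally cross-checked during development against an
independently written reference implementation of the same physics, with
all summary fractions agreeing within Monte Carlo error.

The test suite runs these checks at reduced problem sizes (2–4×10⁴ packets
on coarsened tally grids, chosen because every physics quantity checked is
grid-independent), and the end-to-end statistics at 10⁵ packets per
wavelength, the package's reference resolution.

Passing these tests demonstrates correct radiative transfer *in the model*,
not fidelity of the model to any individual's skin. The model's plane
layers are homogeneous: no melanin heterogeneity, blood vessels, hair
follicles or curvature; the beam is perfectly flat-topped and normally
incident; polarization, coherence and time-of-flight are out of scope
(the source is incoherent by premise); and published optical properties of
human tissue scatter considerably between sources. Absolute absorbed
fractions shift accordingly — e.g. the epidermis share is set almost
entirely by its pigmentation coefficient, and literature values for
layer absorption in this band disagree with what some published property
tables imply, a tension documented in this package's tests rather than
hidden. One secondary effect worth noting: although epidermis properties
are constant over 800–900 nm, its absorbed fraction still varies by ~2%
(relative) across the band, because the deeper layers' wavelength-dependent
absorption modulates how much backscattered light recrosses the epidermis.

## Known limitations

* Plane-parallel geometry only; no lateral heterogeneity or curvature.
* No dispersion ($n$ constant per layer) and no polarization.
* The photovoltaic stage is a flat 10–20% efficiency band applied to the
  captured optical power; spectral responsivity and charge electronics are
  out of scope.
* The reflector/lens train is not ray-traced; the source enters the tissue
  as its equivalent flat-top spot.
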