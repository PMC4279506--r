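# dermamc

Monte Carlo photon transport in layered skin, for assessing transcutaneous
optical power delivery to implanted electronics.

Implantable biosensors need periodic recharging, and one non-invasive route
is to shine near-infrared light from a wearable LED through the skin onto an
implanted photovoltaic cell. Whether that works hinges on radiative
transfer: how much of the incident optical energy survives specular and
diffuse reflection, how much is absorbed in each tissue layer, and how much
reaches the implant depth within the detector's footprint. `dermamc`
answers those questions for a plane-parallel four-layer skin model
(epidermis, dermis, subcutaneous fat, muscle) illuminated by an incoherent
multi-wavelength LED source.

## Model

The transport engine follows the MCML conventions standard in tissue
optics. Photon packets of unit weight are launched normally onto the
surface as a flat-top beam (radius *R*, sampled as *r = R√ξ*) or a pencil
beam. Between interactions, path lengths are exponential with mean
1/μ<sub>t</sub>, μ<sub>t</sub> = μ<sub>a</sub> + μ<sub>s</sub>. At each
interaction a fraction μ<sub>a</sub>/μ<sub>t</sub> of the packet weight is
deposited into a cylindrical *r–z* tally grid and the packet is deflected by
the Henyey–Greenstein phase function with the layer's anisotropy *g*. Layer
boundaries apply unpolarized Fresnel reflection (with total internal
reflection beyond the critical angle) and Snell refraction; the air–tissue
interface additionally removes the deterministic specular fraction
((n₁−n₂)/(n₁+n₂))² at launch. Low-weight packets are terminated by Russian
roulette (threshold 10⁻⁴, survival 0.1) with the net roulette residual
tallied so the energy budget closes to floating-point accuracy.

The LED source is modelled spectrally as a Gaussian,
f(λ) = a₁·exp(−((λ−b₁)/c₁)²) with defaults a₁ = 0.5494, b₁ = 850 nm,
c₁ = 24.93 nm, discretized at 800/825/850/875/900 nm; per-wavelength
transport results are combined as a convex combination with the normalized
spectral weights. Source-side optics reduce to the spot relation
d = D·l/((n−1)·R) and power density I = 4P/(πd²), checked against the
ICNIRP skin-irradiance bound 2.0×10³·C_A W/m².

## Worked example

```r
library(dermamc)

stack    <- default_skin_stack()                      # four-layer model
settings <- run_settings(n_photons = 20000, seed = 42)
sres     <- run_spectrum(stack, spectrum_model(), settings,
                         incident_energy_J = 10)
print(sres)
```

```
spectral_result: 800/825/850/875/900 nm, 20000 photons/wavelength, incident 10 J
  weights: 0.0101 0.2070 0.5658 0.2070 0.0101
  specular 0.02111, diffuse 0.13544, transmittance 0
  absorbed (epidermis) 0.61780
  absorbed (dermis   ) 0.03485
  absorbed (fat      ) 0.11307
  absorbed (muscle   ) 0.07773
```

About 2.1% of the light is lost to specular reflection at the air–epidermis
interface and 13.5% re-emerges as diffuse reflectance; the strongly
pigmented epidermis absorbs the largest share, and roughly 8% of the
launched energy ends up in the muscle layer. Depth-resolved quantities come
from the first-downward-crossing tally:

```r
for (z in stack_boundaries(stack)[2:4])
  cat(sprintf("energy at z = %6.3f mm: %5.2f J\n", z, energy_at_depth(sres, z)))
cat(sprintf("captured by a 5 mm detector at the fat/muscle interface: %.2f\n",
            captured_fraction(sres, 5, 13.315)))
pw <- estimate_electric_power(34)    # photovoltaic band for 34 mW optical
cat(sprintf("electric power from 34 mW optical at 10-20%% efficiency: %.1f-%.1f mW\n",
            pw[1], pw[2]))
```

```
energy at z =  0.065 mm:  5.80 J
energy at z =  1.315 mm:  4.60 J
energy at z = 13.315 mm:  0.89 J
captured by a 5 mm detector at the fat/muscle interface: 0.13
electric power from 34 mW optical at 10-20% efficiency: 3.4-6.8 mW
```

So of 10 J incident, 0.89 J crosses into the muscle layer at 13.315 mm, and
a 5 mm-radius coaxial detector at that depth intercepts 13% of it. A
command-line front end with `simulate`, `spectral-run`, `spectrum`,
`validate` and `safety-check` subcommands is installed under
`inst/scripts/dermamc`, and YAML configurations (see
`default_config_path()`) expose every tissue, source and run parameter.

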