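---
title: "Methods: two-wavelength SWIR spatial-ratio water-fraction estimation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-wavelength SWIR spatial-ratio water-fraction estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(srswater)
```

## The measurement problem

Bulk tissue water content is a clinically useful quantity (edema, fluid
management), and the short-wave infrared offers a convenient handle: liquid
water absorbs strongly near 1450 nm and more weakly near 1650 nm, while the
dominant visible/NIR chromophores fade above ~1300 nm. A compact probe with
four LEDs (two wavelengths x two source-detector separations, 0.45 and
0.70 cm) and one photodetector measures *same-wavelength far/close spatial
ratios*: these cancel unknown multiplicative factors (LED power, coupling,
responsivity) but remain sensitive to the medium's absorption and reduced
scattering through the radial decay of diffuse reflectance.

`srswater` implements the full analysis chain for such a probe, validated
against gelatin-Intralipid phantoms whose *nominal* water fraction is fixed
by the recipe mass balance

$$f_{w,true} = \frac{m_{water} + 0.8\, m_{IL}}{m_{total}},$$

where the 0.8 accounts for solvent water in Intralipid 20% stock
(`il_water_mass_fraction`, a parameter because it is a dominant uncertainty
of the reference). Absorption is assigned by the water-dominant model
$\mu_a(\lambda) = f_w\,\mu_{a,water}(\lambda)$; the packaged constants are
Hale-Querry values, log-interpolated to the band centres
(14.58 cm$^{-1}$ at 1450 nm, 6.34 cm$^{-1}$ at 1650 nm). No spectral
integration over the LED bandwidth is performed; finite bandwidth is a
stated limitation of the approach, not a modelled effect. Note that liquid
water datasets disagree near the sharp 1450 nm peak (the Hale-Querry grid
is coarse there); the constants file records the provenance of each value
and can be swapped via `water_absorption_table(path=)`.

## The two-stage inversion

**Stage 1 - scattering from the Monte Carlo LUT.** A probe-geometry-matched
Monte Carlo model (finite-area LED with generalized-Lambertian divergence,
homogeneous 3.5 x 3.5 x 1.2 cm slab, refractive index 1.33, anisotropy
g = 0.9, absorbing mask with a 4 mm collection aperture, acceptance-cone
filtered detection) is swept over $\mu_s' \in [0.05, 30]$ cm$^{-1}$ at fixed
assigned $\mu_a(\lambda)$, recording the detected fraction `p_det` per
channel. The far/close ratio curve $r^{MC}_\lambda(\mu_s')$ is monotonic
over the operating regime, so a measured corrected ratio inverts by
log-domain linear interpolation between bracketing grid nodes (exact at
nodes; out-of-range is an error, never an extrapolation).

**Stage 2 - water fraction from the diffusion dipole.** With
$\hat\mu_s'(\lambda)$ fixed, candidate water fractions are scored against
the measured ratios using the semi-infinite diffusion-dipole ratio proxy
$$U(\rho) \propto \frac{e^{-\mu_{eff} r_1}}{r_1} -
\frac{e^{-\mu_{eff} r_2}}{r_2}, \qquad
E(f_w) = \sum_k \left[\ln r_k^{corr} - \ln r_k^{model}(f_w)\right]^2,$$
minimised by a dense bounded sweep. Both wavelengths contribute one term
each (K = 2): that is the only construction consistent with forming one
corrected ratio per wavelength, and the 1650 nm band regularises the sweep
against model mismatch at the steep 1450 nm absorption peak.

This is a *consistency-check* estimator: the LUT's $\mu_a$ assignment comes
from the phantom's own nominal water fraction (absorption-consistent mode).
Blind joint $(\mu_a, \mu_s')$ recovery is out of scope by design.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `rho_c`, `rho_f` | 0.45, 0.70 | cm | probe separations |
| `aperture_diameter` | 0.4 | cm | collection aperture of the detector tunnel |
| `tunnel_length` | 0.5 | cm | sets acceptance half-angle atan(0.2/0.5) = 21.8 deg; the physical tunnel length of the reference probe is unknown, so the mechanism (cone from tunnel geometry) is kept and the length exposed |
| `led_emitter_side` | 0.1 | cm | LED package dimensions of the reference probe are unknown; a 1 mm square emitter is typical for SWIR LEDs |
| `divergence_exponent` | 1 | - | generalized-Lambertian exponent; datasheet values are unknown, m = 1 is the Lambertian baseline |
| `g` | 0.9 | - | fixed anisotropy of the phantom model |
| `n_medium` | 1.33 | - | water-dominant first-order boundary index |
| `il_water_mass_fraction` | 0.8 | - | Intralipid stock water content assumption |
| `rr_threshold`, `rr_survive` | 1e-4, 0.1 | - | Russian-roulette variance reduction |
| `min_counts` | 100 | counts | photon-starvation flag on LUT entries |
| `feasible_set`, `sweep_step` | [0.5, 0.95], 0.001 | - | covers the phantom range 0.78-0.88 with margin at a resolution well below observed errors |

## Numerical choices

- **Analytic slab instead of a voxel grid.** For a homogeneous slab,
  voxelisation only discretises geometry; analytic boundary intersections
  are exact and faster. Slab extents are retained as absorbing boundaries;
  only the top surface carries the index mismatch and the mask/aperture.
- **Continuous absorption weighting + Russian roulette** (threshold 1e-4,
  survival 0.1), the standard variance-reduction pairing of MCML-class
  codes. The weight ledger (detected + escaped + mask + cone-rejected +
  absorbed + roulette-killed - roulette-gained) balances the launched weight
  to well below 1e-6 relative, and is tested.
- **Acceptance cone after refraction.** Whether the reference
  probe's calibration filtered before or after refraction is unknown; the cone physically lives in air (the tunnel), so
  the filter is applied to the refracted exit direction.
- **Dipole boundary parameters.** $D = 1/(3(\mu_a+\mu_s'))$,
  $z_0 = 1/(\mu_a+\mu_s')$, $z_b = 2AD$ with $A=(1+R_{eff})/(1-R_{eff})$,
  Groenhuis $R_{eff}(n{=}1.33) \approx 0.472$, and
  $\mu_{eff} = \sqrt{3\mu_a(\mu_a+\mu_s')}$ — the canonical
  extrapolated-boundary construction of the diffuse-optics literature. The
  alternatives (e.g. $z_0 = 1/\mu_s'$, Haskell-style $A$) shift the ratio
  by well under the modelling error discussed below and can be A/B tested
  by swapping the construction.
- **LUT conditioning.** 40 log-spaced grid points by default. Entries that
  come back photon-starved (`detected_count < min_counts`) are rerun once at
  `rerun_factor` (default 10) times the photon budget, then flagged and
  excluded from inversion if still starved. Non-monotonic segments are
  accepted and isotonically projected only when the violation is within 2
  Monte Carlo standard errors of the ratio; larger violations raise an
  error rather than being silently smoothed. The ratio SE uses the
  detected-weight second moment tallied by the engine
  ($\mathrm{SE}(p_{det}) = \sqrt{\sum_i w_i^2}/N$), not a Poisson count
  proxy, because Russian roulette spreads the detected weights. Ties at
  inversion break toward the lower $\mu_s'$; argmin ties in the sweep break
  toward the lower $f_w$.
- **RNG.** xoshiro256** seeded by splitmix64 from (seed, stream); every
  (wavelength, separation, grid point) condition gets its own substream, so
  LUT builds are reproducible bit-for-bit for a fixed master seed.

## What the synthetic generator emulates - and what it does not

`synthetic_scenario()`/`generate_frame()` produce four-channel LED-on/dark
voltage frames from a known $(f_w, \mu_s'(\lambda))$ ground truth through
per-channel gains, dark offsets, multiplicative (CV) and additive noise,
with a flat unit "PTFE" signal (optionally a mismatch factor) as reference.
This spans exactly the structure the correction pipeline claims invariance
to, so a green closed-loop test establishes: dark subtraction, gain
cancellation, reference handling, LUT interpolation and the sweep are
mutually consistent. It does **not** establish hardware realism: no ADC
quantisation or filter dynamics, no contact-pressure or coupling variation,
no phantom inhomogeneity, no LED spectral width. Closed-loop recovery with
the diffusion forward model and a diffusion-engine LUT in matched mode is
self-consistent *by construction*; recovery tests therefore perturb the
loop with noise, gain structure, and (separately) a mismatched fixed-LUT
mode, and the MC engine is cross-checked against the dipole model rather
than against itself.

## Known limitations

- The diffusion dipole is a poor approximation at these millimetre
  separations when $\mu_a \gtrsim 0.1\,\mu_s'$. In the diffusive regime
  ($\mu_a = 1$, $\mu_s' = 10$ cm$^{-1}$) the MC far/close ratio and the
  dipole ratio agree to within ~10%; at the water-dominated SWIR operating
  point ($\mu_a \approx 4.9$ cm$^{-1}$ at 1650 nm for $f_w = 0.78$,
  $\mu_s' = 10$) the MC ratio exceeds the dipole ratio by roughly 30-45%:
  diffusion over-attenuates the long paths that dominate the far channel.
  The two-stage design mitigates this (scattering recovery is MC-based;
  the dipole only drives the relative $f_w$ sweep), but absolute accuracy
  inherits the mismatch.
- At desk-scale photon budgets (1e6-1e7 per condition) the 1450 nm far
  channel starves for $\mu_s' \gtrsim 10$ cm$^{-1}$ at phantom-like
  absorption; entries are flagged and excluded rather than imputed.
  Production LUTs need the 1e9-photon regime.
- The far/close ratio is *not* monotonic in $\mu_s'$ over the full swept
  range: below $\mu_s' \approx 1$ cm$^{-1}$ transport is semi-ballistic and
  measured desk-scale curves zig-zag beyond their MC error bars. Monotonic,
  well-conditioned inversion holds over the operating regime (recovered
  $\hat\mu_s'$ of 1.5-4.5 cm$^{-1}$ sits comfortably inside [1, 10]); LUTs
  intended for inversion should be built there.
- The nominal $f_{w,true}$ reference itself carries uncertainty (stock
  water content, evaporation, scale repeatability); agreement metrics are
  against a *nominal*, not a gold-standard, reference.
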