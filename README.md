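# srswater

Two-wavelength SWIR spatial-ratio estimation of bulk water fraction in
turbid media, for compact diffuse-reflectance probes validated on
gelatin–Intralipid phantoms.

## The problem

Tissue water content tracks clinically relevant state (edema, fluid
balance). In the short-wave infrared, water absorbs strongly near 1450 nm
and more weakly near 1650 nm, so diffuse reflectance at those bands is
hydration-sensitive — but absolute signal levels are confounded by LED
power, coupling and detector gain. A compact probe measuring at two
source–detector separations (ρc = 0.45 cm, ρf = 0.70 cm) instead uses
**same-wavelength far/close spatial ratios**

    r_corr(λ) = [S_far,sample / S_close,sample] · [S_close,ref / S_far,ref]

(dark-subtracted, PTFE-reference-normalized once), which cancel per-channel
multiplicative factors while remaining sensitive to the optical properties
(μa, μs′) through the radial decay of reflectance.

`srswater` implements the full two-stage inversion for this geometry:

1. **Monte Carlo LUT → reduced scattering.** A probe-matched photon
   transport engine (finite LED source, Henyey–Greenstein scattering with
   g = 0.9, Fresnel boundary at n = 1.33, 4 mm aperture- and
   acceptance-cone-limited detection; Rcpp core) is swept over
   μs′ ∈ [0.05, 30] cm⁻¹ at fixed assigned μa(λ) = f_w·μa,water(λ).
   Measured ratios invert to μ̂s′(λ) by log-domain interpolation:
   μ̂s′ = μ1′ + (μ2′−μ1′)·(ln r − ln r1)/(ln r2 − ln r1).
2. **Diffusion-dipole sweep → water fraction.** With μ̂s′(λ) fixed, the
   semi-infinite dipole model U(ρ) ∝ e^(−μeff r1)/r1 − e^(−μeff r2)/r2
   (μeff = √(3μa(μa+μs′)), extrapolated boundary zb = 2AD) predicts the
   ratio for candidate f_w, and E(f_w) = Σλ [ln r_corr − ln r_model(f_w)]²
   is minimized over a bounded sweep — a calibration-anchored consistency
   check, not blind recovery.

Phantom bookkeeping (recipe mass balance
f_w,true = (m_water + 0.8·m_IL)/m_total), a synthetic measurement
generator, and agreement metrics against the packaged phantom-validation
reference tables are included.

## Worked example

```r
library(srswater)
scenario <- synthetic_scenario(
  f_w_true = 0.83,
  mu_s_prime_true = c("1450" = 1.959, "1650" = 1.810),
  channel_gains = c(CH1 = 1.8, CH2 = 0.7, CH3 = 1.2, CH4 = 0.9),
  noise_cv = 0.02, seed = 42)
frames <- generate_frame(scenario, forward = "diffusion")
lut <- build_lut(0.83, config = mc_config(engine = "diffusion"))
run_pipeline(frames$sample, frames$reference, lut,
             inversion_config(fw_nominal_for_lut = 0.83))
#> <inversion_result> f_w_hat = 0.8300; mu_s' = [1450 nm: 2.145, 1650 nm: 1.915] cm^-1

agreement_metrics(table3_fixture()[, c("f_w_true", "f_w_hat", "il_pct")],
                  group = "il_pct")
#> <agreement_metrics> n = 8 | MAPE = 1.55% | max APE = 3.33% | bias = -0.0122 | MAE = 0.0127 | RMSE = 0.0159
#>   group mean APE: 10: 2.36% | 20: 0.74%
```

The first call recovers the generating water fraction (0.830) from noisy
four-channel frames with scrambled per-channel gains: the 2% measurement
noise is absorbed into μ̂s′ (2.145 vs true 1.959 at 1450 nm) while the
self-consistent sweep lands on the nominal f_w. The second call reproduces
the packaged phantom-validation reference table: mean absolute percent error
1.55%, maximum 3.33%, with the 20% Intralipid group (0.74%) outperforming
the 10% group (2.36%).

A command-line interface wraps the same pipeline
(`inst/cli/srswater simulate|build-lut|ratios|forward|invert|synth|report`).

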