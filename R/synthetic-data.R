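# Synthetic measurement frames and packaged table fixtures: known ground
# truth (water fraction, reduced scattering) pushed through a gain/offset/
# noise measurement model so the full pipeline is testable without hardware.

#' Synthetic measurement scenario
#'
#' Ground truth plus the acquisition-chain structure the signal pipeline
#' claims invariance to. Noise model: multiplicative Gaussian
#' (`noise_cv`) on the LED-on signal component plus optional additive
#' Gaussian (`additive_sd`, volts) on both on and dark readings.
#'
#' @param f_w_true true bulk water fraction.
#' @param mu_s_prime_true named numeric: true reduced scattering (cm^-1) per
#'   wavelength, names `"1450"`, `"1650"`.
#' @param channel_gains named positive gains per channel CH1..CH4.
#' @param dark_offsets named dark-offset voltages per channel.
#' @param noise_cv multiplicative noise coefficient of variation (>= 0).
#' @param additive_sd additive noise standard deviation (V, >= 0).
#' @param reference_mismatch multiplicative sample/reference coupling
#'   mismatch factor applied to the reference signal (1 = ideal PTFE).
#' @param seed integer seed making frame generation deterministic.
#' @return list of class `synthetic_scenario`.
#' @export
synthetic_scenario <- function(f_w_true,
                               mu_s_prime_true = c("1450" = 2.0,
                                                   "1650" = 1.7),
                               channel_gains = c(CH1 = 1, CH2 = 1, CH3 = 1,
                                                 CH4 = 1),
                               dark_offsets = c(CH1 = 0.05, CH2 = 0.05,
                                                CH3 = 0.05, CH4 = 0.05),
                               noise_cv = 0, additive_sd = 0,
                               reference_mismatch = 1, seed = 1L) {
  if (f_w_true < 0 || f_w_true > 1)
    stop_srswater("f_w_true must lie in [0, 1]", "srswater_domain_error")
  if (any(channel_gains <= 0))
    stop_srswater("channel gains must be positive", "srswater_domain_error")
  if (noise_cv < 0 || additive_sd < 0)
    stop_srswater("noise parameters must be non-negative",
                  "srswater_domain_error")
  structure(list(f_w_true = f_w_true, mu_s_prime_true = mu_s_prime_true,
                 channel_gains = channel_gains, dark_offsets = dark_offsets,
                 noise_cv = noise_cv, additive_sd = additive_sd,
                 reference_mismatch = reference_mismatch,
                 seed = as.integer(seed)),
            class = "synthetic_scenario")
}

#' Generate a synthetic sample/reference frame pair
#'
#' Per channel (wavelength, separation):
#' `v_on = gain * signal * (1 + eps_mult) + offset + eps_add`,
#' `v_dark = offset + eps_add`, with the forward signal either the
#' diffusion-dipole fluence proxy (`"diffusion"`) or a Monte Carlo detected
#' fraction (`"mc"`). Reference channels carry a flat unit PTFE signal
#' (times `reference_mismatch`) through the same gains and offsets.
#'
#' @param scenario a [synthetic_scenario()].
#' @param forward forward model: `"diffusion"` or `"mc"`.
#' @param geometry a [probe_geometry()].
#' @param mc an [mc_config()] used when `forward = "mc"`.
#' @param g anisotropy for the MC forward model.
#' @return list with elements `sample` and `reference`
#'   ([measurement_frame()]s).
#' @export
generate_frame <- function(scenario, forward = c("diffusion", "mc"),
                           geometry = probe_geometry(),
                           mc = mc_config(), g = 0.9) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  forward <- match.arg(forward)
  cm <- channel_map()
  signal <- numeric(4)
  for (i in seq_len(4)) {
    wl <- cm$wavelength_nm[i]
    rho <- cm$rho_cm[i]
    msp <- scenario$mu_s_prime_true[[as.character(wl)]]
    mu_a <- assign_absorption(scenario$f_w_true, wl)
    if (forward == "diffusion") {
      signal[i] <- as.vector(.dipole_kernel(rho, mu_a, msp,
                                            geometry$n_medium))
    } else {
      props <- optical_properties(mu_a, mus_from_musp(msp, g), g,
                                  geometry$n_medium)
      src <- source_model(rho, geometry$led_emitter_side)
      signal[i] <- simulate_channel(props, geometry, src,
                                    n_photons = mc$n_photons,
                                    seed = derive_seed(scenario$seed, i),
                                    min_counts = mc$min_counts)$p_det
    }
  }
  gains <- scenario$channel_gains[cm$channel]
  offs <- scenario$dark_offsets[cm$channel]
  with_seed(scenario$seed, {
    noisy <- function(sig, role, mismatch = 1) {
      em <- rnorm(4, 0, scenario$noise_cv)
      ea_on <- rnorm(4, 0, scenario$additive_sd)
      ea_dk <- rnorm(4, 0, scenario$additive_sd)
      measurement_frame(
        setNames(gains * sig * mismatch * (1 + em) + offs + ea_on,
                 cm$channel),
        setNames(offs + ea_dk, cm$channel), role = role)
    }
    list(sample = noisy(signal, "sample"),
         reference = noisy(rep(1, 4), "reference",
                           scenario$reference_mismatch))
  })
}

#' Packaged phantom recipe table (eight 15 g batches)
#'
#' The eight gelatin-Intralipid formulations spanning added-water fractions
#' of 62-80\% at two Intralipid 20\% stock loadings (10\% and 20\% of batch
#' mass), together with the printed nominal true water content (percent).
#'
#' @param as_recipes return a list of [phantom_recipe()] objects instead of
#'   the raw table.
#' @return data.frame (default) or list of recipes.
#' @export
table1_fixture <- function(as_recipes = FALSE) {
  f <- system.file("extdata", "table1_recipes.csv", package = "srswater")
  df <- read.csv(f, stringsAsFactors = FALSE, check.names = FALSE)
  if (!as_recipes) return(df)
  lapply(seq_len(nrow(df)), function(i)
    phantom_recipe(df$label[i], df$m_water_g[i], df$m_gelatin_g[i],
                   df$m_il_g[i]))
}

#' Packaged phantom validation reference results
#'
#' The eight reference per-phantom validation results the package is tested
#' against: probe-recovered reduced scattering at both wavelengths, the
#' recipe-defined reference water fraction, the recovered water fraction
#' and its absolute percent error.
#'
#' @return data.frame with columns `gel_id`, `il_pct`, `mu_s_prime_1450`,
#'   `mu_s_prime_1650`, `f_w_true`, `f_w_hat`, `abs_err_pct`.
#' @export
table3_fixture <- function() {
  f <- system.file("extdata", "table3_results.csv", package = "srswater")
  read.csv(f, stringsAsFactors = FALSE)
}
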