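# Shared fixture builders: everything is generated in code at test time.

# hand-made LUT-like data.frame with paired far/close entries
make_lut_entries <- function(mu_s_prime, p_close, p_far,
                             wavelength = 1650, mu_a = 1,
                             counts_close = 1e5, counts_far = 1e4,
                             starved_far = rep(FALSE, length(mu_s_prime))) {
  rbind(
    data.frame(wavelength_nm = wavelength, rho_cm = 0.45,
               separation = "close", mu_a_cm1 = mu_a,
               mu_s_prime_cm1 = mu_s_prime, p_det = p_close,
               detected_count = counts_close, launched = 1e6,
               starved = FALSE),
    data.frame(wavelength_nm = wavelength, rho_cm = 0.70,
               separation = "far", mu_a_cm1 = mu_a,
               mu_s_prime_cm1 = mu_s_prime, p_det = p_far,
               detected_count = counts_far, launched = 1e6,
               starved = starved_far))
}

# strictly monotonic synthetic ratio curve on an arbitrary mu_s' grid,
# generated from the diffusion kernel (decreasing in mu_s' at fixed mu_a)
make_ratio_curve <- function(grid, mu_a = 2, n = 1.33) {
  ratio <- vapply(grid, function(m)
    srswater:::.dipole_kernel(0.70, mu_a, m, n) /
      srswater:::.dipole_kernel(0.45, mu_a, m, n), numeric(1))
  curve <- data.frame(mu_s_prime = grid, ratio = ratio)
  attr(curve, "wavelength") <- 1650
  attr(curve, "mu_a") <- mu_a
  attr(curve, "dropped") <- data.frame()
  attr(curve, "smoothed") <- FALSE
  class(curve) <- c("ratio_curve", "data.frame")
  curve
}

make_frame <- function(v_on, v_dark = rep(0, 4), role = "sample") {
  ch <- c("CH1", "CH2", "CH3", "CH4")
  measurement_frame(setNames(v_on, ch), setNames(v_dark, ch), role = role)
}

# frames where the 1450/1650 nm (far, close) raw signals are set directly
# (zero dark) using the physical channel map
frame_from_signals <- function(s1450_close, s1450_far, s1650_close,
                               s1650_far, role = "sample") {
  make_frame(c(CH1 = s1450_close, CH2 = s1650_far, CH3 = s1450_far,
               CH4 = s1650_close), role = role)
}
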