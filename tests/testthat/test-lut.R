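test_that("build_lut enumerates the sweep and holds mu_a fixed per wavelength", {
  lut <- build_lut(0.78, mu_s_prime_grid = c(1, 2, 4),
                   config = mc_config(engine = "diffusion"))
  expect_s3_class(lut, "srs_lut")
  expect_equal(nrow(lut), 3 * 2 * 2)   # grid x wavelengths x separations
  for (wl in c(1450, 1650))
    expect_equal(unique(lut$mu_a_cm1[lut$wavelength_nm == wl]),
                 assign_absorption(0.78, wl))
  # spatial falloff holds at every grid point
  wide <- merge(lut[lut$separation == "close", ],
                lut[lut$separation == "far", ],
                by = c("wavelength_nm", "mu_s_prime_cm1"))
  expect_true(all(wide$p_det.x > wide$p_det.y))
  expect_equal(attr(lut, "fw_nominal"), 0.78)
  expect_error(build_lut(0.78, mu_s_prime_grid = c(0.01, 1)),
               class = "srswater_domain_error")
  expect_error(build_lut(1.5), class = "srswater_domain_error")
})

test_that("ratio_curve forms far/close ratios and drops starved pairs", {
  e <- make_lut_entries(c(1, 2, 4), p_close = c(1e-4, 2e-4, 4e-4),
                        p_far = c(1e-5, 4e-5, 1.2e-4))
  cv <- ratio_curve(e, 1650)
  expect_equal(cv$ratio, c(0.1, 0.2, 0.3))
  expect_equal(nrow(attr(cv, "dropped")), 0)

  e2 <- make_lut_entries(c(1, 2, 4), p_close = c(1e-4, 2e-4, 4e-4),
                         p_far = c(1e-5, 4e-5, 1.2e-4),
                         starved_far = c(FALSE, TRUE, FALSE))
  cv2 <- ratio_curve(e2, 1650)
  expect_equal(nrow(cv2), 2)
  expect_equal(attr(cv2, "dropped")$reason, "starved")

  # a zero close signal drops the pair rather than dividing by zero
  e3 <- make_lut_entries(c(1, 2), p_close = c(0, 2e-4),
                         p_far = c(1e-5, 4e-5))
  cv3 <- ratio_curve(e3, 1650)
  expect_equal(nrow(cv3), 1)
  expect_equal(attr(cv3, "dropped")$reason, "non_positive_signal")
})

test_that("ratio curves are invariant to global p_det scaling", {
  e <- make_lut_entries(c(1, 2, 4), p_close = c(1e-4, 2e-4, 4e-4),
                        p_far = c(1e-5, 4e-5, 1.2e-4))
  e_scaled <- e
  e_scaled$p_det <- e_scaled$p_det * 7.3   # LED power change
  expect_equal(ratio_curve(e_scaled, 1650)$ratio, ratio_curve(e, 1650)$ratio)
})

test_that("noise-tolerant monotonicity check smooths small violations, raises on large", {
  # small dip within 2 MC standard errors: isotonic projection applied
  e <- make_lut_entries(c(1, 2, 3, 4), p_close = rep(1e-3, 4),
                        p_far = c(1.00e-4, 1.21e-4, 1.19e-4, 1.40e-4),
                        counts_close = 1e5, counts_far = 120)
  cv <- ratio_curve(e, 1650)
  expect_true(attr(cv, "smoothed"))
  expect_true(all(diff(cv$ratio) >= 0))
  # gross violation: error
  e2 <- make_lut_entries(c(1, 2, 3, 4), p_close = rep(1e-3, 4),
                         p_far = c(1.0e-4, 2.5e-4, 0.8e-4, 3.0e-4),
                         counts_close = 1e6, counts_far = 1e6)
  expect_error(ratio_curve(e2, 1650), class = "srswater_nonmonotonic_lut")
})

test_that("invert_ratio is exact at nodes and log-linear between them", {
  cv <- make_ratio_curve(c(0.5, 1, 2, 4, 8))
  for (i in seq_len(nrow(cv)))
    expect_identical(invert_ratio(cv, cv$ratio[i]), cv$mu_s_prime[i])
  # geometric-midpoint ratio maps to the arithmetic midpoint of the bracket
  cv2 <- data.frame(mu_s_prime = c(1, 2), ratio = c(0.10, 0.20))
  attributes(cv2) <- c(attributes(cv2),
                       list(wavelength = 1650, mu_a = 1,
                            dropped = data.frame(), smoothed = FALSE))
  class(cv2) <- c("ratio_curve", "data.frame")
  expect_equal(invert_ratio(cv2, sqrt(0.10 * 0.20)), 1.5)
})

test_that("invert_ratio rejects low-SNR and out-of-range inputs", {
  cv <- make_ratio_curve(c(1, 2, 4))
  expect_error(invert_ratio(cv, 0), class = "srswater_low_snr")
  expect_error(invert_ratio(cv, -1), class = "srswater_low_snr")
  expect_error(invert_ratio(cv, max(cv$ratio) * 1.01),
               class = "srswater_out_of_range")
  expect_error(invert_ratio(cv, min(cv$ratio) * 0.99),
               class = "srswater_out_of_range")
})

test_that("coarse-grid inversion recovers generating mu_s' within one spacing", {
  # oracle: the dense generating curve itself; draw off-grid truths, compute
  # their exact ratios, invert on a coarse grid
  grid <- lut_grid(12, 0.5, 10)
  cv <- make_ratio_curve(grid)
  set.seed(99)
  for (i in 1:50) {
    truth <- runif(1, 0.6, 9)
    r_true <- srswater:::.dipole_kernel(0.70, 2, truth, 1.33) /
      srswater:::.dipole_kernel(0.45, 2, truth, 1.33)
    hat <- invert_ratio(cv, as.vector(r_true))
    j <- findInterval(truth, grid)
    spacing <- grid[min(j + 1, length(grid))] - grid[j]
    expect_lt(abs(hat - truth), spacing + 1e-9)
  }
})

test_that("LUT round-trips through CSV with sidecar metadata", {
  lut <- build_lut(0.83, mu_s_prime_grid = c(1, 2, 4),
                   config = mc_config(engine = "diffusion", seed = 5L))
  path <- withr::local_tempfile(fileext = ".csv")
  write_lut(lut, path)
  expect_true(file.exists(paste0(path, ".json")))
  back <- read_lut(path)
  expect_equal(as.data.frame(back)$p_det, as.data.frame(lut)$p_det)
  expect_equal(attr(back, "fw_nominal"), 0.83)
  expect_equal(attr(back, "engine"), "diffusion")
  # inversion works identically on the re-read LUT
  cv1 <- ratio_curve(lut, 1450)
  cv2 <- ratio_curve(back, 1450)
  expect_equal(invert_ratio(cv2, cv1$ratio[2]), cv1$mu_s_prime[2])
})
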