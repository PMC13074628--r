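test_that("objective is zero at a perfect fit and counts log-squared terms", {
  musp <- c("1450" = 2.0, "1650" = 1.7)
  r_model <- c("1450" = model_ratio(0.83, 2.0, 1450),
               "1650" = model_ratio(0.83, 1.7, 1650))
  expect_equal(objective_fw(0.83, r_model, musp), 0)
  # single term with r_corr = e * r_model gives E = 1 exactly
  expect_equal(objective_fw(0.83, c("1450" = exp(1) * r_model[["1450"]]),
                            musp), 1)
  # independent term-by-term re-evaluation at two candidate fw values
  for (fw in c(0.6, 0.9)) {
    manual <- sum(vapply(names(musp), function(wl)
      (log(r_model[[wl]]) -
         log(model_ratio(fw, musp[[wl]], as.numeric(wl))))^2, numeric(1)))
    expect_equal(objective_fw(fw, r_model, musp), manual)
  }
  expect_error(objective_fw(0.8, setNames(numeric(0), character(0)), musp),
               class = "srswater_domain_error")
})

test_that("sweep recovers a self-consistent water fraction", {
  musp <- c("1450" = 2.0, "1650" = 1.7)
  r_corr <- c("1450" = model_ratio(0.83, 2.0, 1450),
              "1650" = model_ratio(0.83, 1.7, 1650))
  res <- sweep_fw(inversion_config(), r_corr, musp)
  expect_s3_class(res, "inversion_result")
  expect_equal(res$f_w_hat, 0.83, tolerance = 1e-9)
  expect_equal(nrow(res$error_curve), 451)
  expect_equal(min(res$error_curve$E),
               res$error_curve$E[res$error_curve$f_w == res$f_w_hat])
  # degenerate single-point feasible set
  res1 <- sweep_fw(inversion_config(feasible_set = c(0.8, 0.8)),
                   r_corr, musp)
  expect_equal(res1$f_w_hat, 0.8)
})

test_that("full pipeline runs end-to-end on synthetic frames", {
  sc <- synthetic_scenario(0.78, mu_s_prime_true = c("1450" = 2.085,
                                                     "1650" = 1.485),
                           seed = 21)
  fr <- generate_frame(sc, forward = "diffusion")
  lut <- build_lut(0.78, mu_s_prime_grid = lut_grid(25),
                   config = mc_config(engine = "diffusion"))
  res <- run_pipeline(fr$sample, fr$reference, lut,
                      inversion_config(fw_nominal_for_lut = 0.78))
  expect_equal(res$lut_mode, "absorption_consistent")
  # diffusion LUT + diffusion data: mu_s' recovered to interpolation error
  expect_equal(res$mu_s_prime_hat[["1450"]], 2.085, tolerance = 0.02)
  expect_equal(res$mu_s_prime_hat[["1650"]], 1.485, tolerance = 0.02)
  expect_equal(res$f_w_hat, 0.78, tolerance = 0.002)

  lut75 <- build_lut(0.75, mu_s_prime_grid = lut_grid(25),
                     config = mc_config(engine = "diffusion"))
  res75 <- run_pipeline(fr$sample, fr$reference, lut75,
                        inversion_config(fw_nominal_for_lut = 0.78))
  expect_equal(res75$lut_mode, "fixed_nominal")
})

test_that("pipeline fails with reasons when every wavelength is excluded", {
  dead <- make_frame(rep(0, 4))                     # all-zero raw signals
  ref <- make_frame(rep(1, 4), role = "reference")
  lut <- build_lut(0.78, mu_s_prime_grid = c(1, 2, 4),
                   config = mc_config(engine = "diffusion"))
  err <- expect_error(run_pipeline(dead, ref, lut),
                      class = "srswater_pipeline_failure")
  expect_match(conditionMessage(err), "1450")
  expect_match(conditionMessage(err), "1650")
})

test_that("agreement metrics compute percent errors, bias, MAE, RMSE", {
  m0 <- agreement_metrics(data.frame(f_w_true = 0.8, f_w_hat = 0.8))
  expect_equal(m0$mean_abs_pct_err, 0)
  expect_equal(m0$bias, 0)

  m1 <- agreement_metrics(data.frame(f_w_true = 0.780, f_w_hat = 0.754))
  expect_equal(round_half_up(m1$mean_abs_pct_err, 3), 3.333)
  expect_equal(m1$bias, -0.026)
  expect_equal(m1$rmse, 0.026)

  mz <- agreement_metrics(data.frame(f_w_true = c(0, 0.8),
                                     f_w_hat = c(0.1, 0.8)))
  expect_true(is.na(mz$per_pair$abs_pct_err[1]))
  expect_equal(mz$mean_abs_pct_err, 0)   # undefined pair reported, not used

  grp <- agreement_metrics(data.frame(f_w_true = c(0.8, 0.8),
                                      f_w_hat = c(0.84, 0.76),
                                      g = c("a", "b")), group = "g")
  expect_equal(unname(grp$group_means["a"]), 5)
  expect_equal(unname(grp$group_means["b"]), 5)
})
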