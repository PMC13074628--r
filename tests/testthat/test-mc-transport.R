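# Sampler-level checks use independently computed moments (closed form or
# numeric integration) as oracles; engine-level checks use geometry and
# conservation properties at small photon budgets.

test_that("generalized Lambertian launch has the analytic mean cosine", {
  n <- 1e5
  src <- source_model(0.45, emitter_side = 0.1, divergence_exponent = 1)
  lp <- launch_photons(src, n, seed = 7)
  # pdf prop. to cos(t)sin(t): E[cos] = 2/3, Var[cos] = 1/2 - 4/9 = 1/18
  se <- sqrt((1 / 2 - 4 / 9) / n)
  expect_lt(abs(mean(lp$uz) - 2 / 3), 3 * se)
  expect_true(all(lp$uz > 0))          # into the medium
  expect_true(all(abs(lp$x - 0.45) <= 0.05 + 1e-12))
  expect_true(all(abs(lp$y) <= 0.05 + 1e-12))
  expect_true(all(lp$z == 0))
  # point-source limit
  pp <- launch_photons(source_model(0.45, emitter_side = 0), 100, seed = 1)
  expect_true(all(pp$x == 0.45) && all(pp$y == 0))
  # higher divergence exponent concentrates around the normal
  lp8 <- launch_photons(source_model(0.45, divergence_exponent = 8), n, 7)
  expect_gt(mean(lp8$uz), mean(lp$uz))
})

test_that("Henyey-Greenstein sampling has mean cosine g", {
  n <- 1e5
  for (g in c(0, 0.9)) {
    x <- sample_scatter_cosines(n, g, seed = 13)
    # oracle: moments of the HG density by numeric integration
    pdf <- function(mu) 0.5 * (1 - g^2) / (1 + g^2 - 2 * g * mu)^1.5
    m2 <- integrate(function(mu) mu^2 * pdf(mu), -1, 1)$value
    se <- sqrt((m2 - g^2) / n)
    expect_lt(abs(mean(x) - g), 3 * se)
    expect_true(all(x >= -1 & x <= 1))
  }
})

test_that("free-path sampling is exponential with rate mu_t", {
  x <- sample_free_paths(1e5, 5, seed = 3)
  expect_lt(abs(mean(x) - 0.2), 3 * 0.2 / sqrt(1e5))
})

test_that("Fresnel reflectance matches closed form and TIR", {
  expect_equal(fresnel_reflectance(1.33, 1, 1), ((1.33 - 1) / (1.33 + 1))^2)
  # beyond the critical angle (~48.75 deg) everything reflects
  expect_equal(fresnel_reflectance(1.33, 1, cos(60 * pi / 180)), 1)
  expect_true(all(diff(fresnel_reflectance(1.33, 1,
                                           seq(1, 0.05, by = -0.05))) >= 0))
})

test_that("surface interaction applies mask, cone and Fresnel rules", {
  geom <- probe_geometry()  # aperture radius 0.2, half-angle atan(0.4)
  # outside the aperture -> terminated on the mask
  expect_equal(surface_interaction(c(0.3, 0), 1, geom), "terminate_on_mask")
  # on axis at normal incidence, inside the cone -> detected
  expect_equal(surface_interaction(c(0, 0), 1, geom), "detect")
  # inside aperture but refracted outside the acceptance cone -> escape:
  # incidence 20 deg in medium refracts to ~27 deg in air > 21.8 deg
  expect_equal(surface_interaction(c(0, 0), cos(20 * pi / 180), geom),
               "escape")
  # xi below the Fresnel reflectance forces internal reflection
  expect_equal(surface_interaction(c(0, 0), 1, geom, xi = 0),
               "reflect_internally")
})

test_that("simulate_channel is deterministic and spatially decaying", {
  geom <- probe_geometry()
  pr <- optical_properties(0.5, mus_from_musp(8, 0.9), 0.9, 1.33)
  a <- simulate_channel(pr, geom, source_model(0.45), 5e4, seed = 11)
  b <- simulate_channel(pr, geom, source_model(0.45), 5e4, seed = 11)
  expect_identical(a$p_det, b$p_det)
  expect_identical(a$detected_count, b$detected_count)
  c2 <- simulate_channel(pr, geom, source_model(0.45), 5e4, seed = 12)
  expect_false(identical(a$p_det, c2$p_det))
  far <- simulate_channel(pr, geom, source_model(0.70), 5e4, seed = 11)
  expect_gt(a$p_det, far$p_det)       # p_det falls off with separation
  expect_equal(a$p_det, a$detected_weight / a$launched)
})

test_that("weight ledger balances to the launched weight", {
  geom <- probe_geometry()
  for (musp in c(1, 10)) {
    pr <- optical_properties(2, mus_from_musp(musp, 0.9), 0.9, 1.33)
    res <- simulate_channel(pr, geom, source_model(0.45), 2e4, seed = 5)
    expect_lt(weight_balance(res)$relative_error, 1e-6)
  }
})

test_that("photon starvation is flagged in opaque media", {
  geom <- probe_geometry()
  pr <- optical_properties(1e4, mus_from_musp(10, 0.9), 0.9, 1.33)
  res <- simulate_channel(pr, geom, source_model(0.70), 1e5, seed = 9)
  expect_equal(res$detected_count, 0L)
  expect_true(res$starved)
})

test_that("MC far/close ratio matches the dipole model in the diffusive regime", {
  # cross-module oracle at mu_a = 1, mu_s' = 10 cm^-1 (mu_a << mu_s'), with
  # the photon budget scaled down from 1e7 to keep the default run fast; MC
  # noise on the ratio is ~4%, well inside the 15% band
  geom <- probe_geometry()
  pr <- optical_properties(1, mus_from_musp(10, 0.9), 0.9, 1.33)
  rc <- simulate_channel(pr, geom, source_model(geom$rho_c), 5e5,
                         seed = 301, stream = 1)
  rf <- simulate_channel(pr, geom, source_model(geom$rho_f), 5e5,
                         seed = 301, stream = 2)
  fw_equiv <- 1 / water_absorption(1650)   # fw whose assigned mu_a is 1
  dip <- model_ratio(fw_equiv, 10, 1650,
                     aperture_radius = geom$aperture_radius)
  expect_lt(abs(rf$p_det / rc$p_det / dip - 1), 0.15)
})

test_that("zero-size aperture collects nothing", {
  geom <- probe_geometry(aperture_diameter = 0, acceptance_half_angle = 45)
  pr <- optical_properties(0.5, mus_from_musp(8, 0.9), 0.9, 1.33)
  res <- simulate_channel(pr, geom, source_model(0.45), 2e4, seed = 2)
  expect_equal(res$p_det, 0)
})

test_that("mu_s = 0 reduces to straight-line Beer-Lambert transport", {
  geom <- probe_geometry()
  pr <- optical_properties(1, 0, 0.9, 1.33)
  res <- simulate_channel(pr, geom, source_model(0.45), 2e4, seed = 4)
  # downward-launched photons never turn around: nothing detected
  expect_equal(res$detected_count, 0L)
  expect_lt(weight_balance(res)$relative_error, 1e-6)
})
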