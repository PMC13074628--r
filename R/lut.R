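# Lookup tables: build (MC or diffusion-surrogate), condition, store and
# invert probe-matched mu_s' -> far/close ratio curves, conditional on an
# assigned mu_a(lambda).

#' Default reduced-scattering LUT grid
#'
#' Log-spaced over the swept range \[0.05, 30\] cm^-1; 40 points by default.
#'
#' @param n number of grid points.
#' @param lower,upper grid range (cm^-1), within \[0.05, 30\].
#' @return numeric vector of mu_s' values.
#' @export
lut_grid <- function(n = 40, lower = 0.05, upper = 30) {
  stopifnot(n >= 2, lower >= 0.05 - 1e-12, upper <= 30 + 1e-12,
            upper > lower)
  exp(seq(log(lower), log(upper), length.out = n))
}

#' Build a probe-matched lookup table
#'
#' For each wavelength, \eqn{\mu_a} is assigned once from `fw_nominal` via
#' the water-dominant model and held fixed while \eqn{\mu_s'} is swept over
#' the grid at both separations. With the `"mc"` engine each (wavelength,
#' separation, grid point) condition is an independent simulation on its own
#' seed-derived substream; the `"diffusion"` engine records the dipole
#' fluence proxy instead (deterministic surrogate for closed-loop tests).
#' Entries that come back photon-starved are rerun once at
#' `rerun_factor` times the photon budget (the stated conditioning remedy
#' for ill-conditioned LUT regions) and keep their starved flag if still
#' below `min_counts`.
#'
#' @param fw_nominal nominal water fraction conditioning the LUT (in
#'   \[0, 1\]).
#' @param wavelengths wavelengths (nm) to sweep.
#' @param mu_s_prime_grid grid of reduced scattering values (cm^-1) within
#'   \[0.05, 30\].
#' @param config an [mc_config()].
#' @param geometry a [probe_geometry()].
#' @param g scattering anisotropy used to convert mu_s' to mu_s.
#' @return data.frame of class `srs_lut` with one row per (wavelength, rho,
#'   mu_s') and columns `wavelength_nm`, `rho_cm`, `separation`,
#'   `mu_a_cm1`, `mu_s_prime_cm1`, `p_det`, `detected_count`, `launched`,
#'   `starved`; attributes `fw_nominal`, `engine`, `seed`.
#' @export
build_lut <- function(fw_nominal, wavelengths = swir_wavelengths(),
                      mu_s_prime_grid = lut_grid(), config = mc_config(),
                      geometry = probe_geometry(), g = 0.9) {
  if (fw_nominal < 0 || fw_nominal > 1)
    stop_srswater("fw_nominal must lie in [0, 1]", "srswater_domain_error")
  if (any(mu_s_prime_grid < 0.05 - 1e-12 | mu_s_prime_grid > 30 + 1e-12))
    stop_srswater("mu_s_prime grid must lie within [0.05, 30] cm^-1",
                  "srswater_domain_error")
  mu_s_prime_grid <- sort(mu_s_prime_grid)
  seps <- c(close = geometry$rho_c, far = geometry$rho_f)
  combos <- expand.grid(mu_s_prime = mu_s_prime_grid,
                        separation = names(seps),
                        wavelength = wavelengths,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(combos)), function(k) {
    wl <- combos$wavelength[k]
    sep <- combos$separation[k]
    msp <- combos$mu_s_prime[k]
    rho <- unname(seps[sep])
    mu_a <- assign_absorption(fw_nominal, wl)
    if (config$engine == "diffusion") {
      u <- as.vector(.dipole_kernel(rho, mu_a, msp, geometry$n_medium))
      rec <- list(p_det = u, p_det_se = 0, detected_count = NA_integer_,
                  launched = NA_real_, starved = FALSE)
    } else {
      props <- optical_properties(mu_a, mus_from_musp(msp, g), g,
                                  geometry$n_medium)
      src <- source_model(rho, geometry$led_emitter_side)
      sim <- function(np, stream) simulate_channel(
        props, geometry, src, n_photons = np, seed = config$seed,
        stream = stream, min_counts = config$min_counts,
        rr_threshold = config$rr_threshold,
        rr_survive = config$rr_survive, max_steps = config$max_steps)
      res <- sim(config$n_photons, k)
      # conditioning: starved entries get one rerun at a larger budget
      if (res$starved && config$rerun_factor > 1)
        res <- sim(config$n_photons * config$rerun_factor, k + 10000L)
      rec <- list(p_det = res$p_det, p_det_se = res$p_det_se,
                  detected_count = res$detected_count,
                  launched = res$launched, starved = res$starved)
    }
    data.frame(wavelength_nm = wl, rho_cm = rho, separation = sep,
               mu_a_cm1 = mu_a, mu_s_prime_cm1 = msp,
               p_det = rec$p_det, p_det_se = rec$p_det_se,
               detected_count = rec$detected_count,
               launched = rec$launched, starved = rec$starved,
               stringsAsFactors = FALSE)
  })
  lut <- do.call(rbind, rows)
  attr(lut, "fw_nominal") <- fw_nominal
  attr(lut, "engine") <- config$engine
  attr(lut, "seed") <- config$seed
  class(lut) <- c("srs_lut", "data.frame")
  lut
}

#' Far/close ratio curve from LUT entries
#'
#' Pairs far and close entries at each grid \eqn{\mu_s'} and forms
#' \eqn{r^{MC} = p_{det}(\rho_f) / p_{det}(\rho_c)}. Pairs with a starved
#' member or a non-positive close signal are dropped and reported. The curve
#' is then validated for monotonicity: sign violations of the finite
#' differences are tolerated (and removed by isotonic projection) only when
#' they are within two Monte Carlo standard errors of the ratio; larger
#' violations raise an error.
#'
#' @param entries an `srs_lut` (or compatible data.frame).
#' @param wavelength wavelength (nm) to extract.
#' @param smooth apply the noise-tolerant isotonic check (default TRUE).
#' @return data.frame of class `ratio_curve` with columns `mu_s_prime`,
#'   `ratio` (and `ratio_raw` when smoothing changed anything); attributes
#'   `wavelength`, `mu_a`, `dropped` (data.frame of excluded grid points with
#'   reasons), `smoothed`.
#' @export
ratio_curve <- function(entries, wavelength, smooth = TRUE) {
  e <- entries[entries$wavelength_nm == wavelength, , drop = FALSE]
  if (nrow(e) == 0)
    stop_srswater(sprintf("no LUT entries at %g nm", wavelength),
                  "srswater_domain_error")
  far <- e[e$separation == "far", ]
  close <- e[e$separation == "close", ]
  far <- far[order(far$mu_s_prime_cm1), ]
  close <- close[order(close$mu_s_prime_cm1), ]
  if (!identical(far$mu_s_prime_cm1, close$mu_s_prime_cm1))
    stop_srswater("far/close grid points are not paired",
                  "srswater_domain_error")
  bad_starved <- far$starved | close$starved
  bad_zero <- !bad_starved & (close$p_det <= 0 | far$p_det <= 0)
  keep <- !(bad_starved | bad_zero)
  dropped <- data.frame(
    mu_s_prime = far$mu_s_prime_cm1[!keep],
    reason = ifelse(bad_starved[!keep], "starved", "non_positive_signal"),
    stringsAsFactors = FALSE)
  ratio <- far$p_det[keep] / close$p_det[keep]
  curve <- data.frame(mu_s_prime = far$mu_s_prime_cm1[keep], ratio = ratio)
  # MC standard error of each ratio: from the detected-weight second moment
  # when recorded (accounts for roulette weight spread), else the Poisson
  # count proxy; zero for the deterministic diffusion engine
  se <- rep(0, nrow(curve))
  if (nrow(curve) > 0 && "p_det_se" %in% names(far) &&
      any(far$p_det_se[keep] > 0)) {
    se <- ratio * sqrt((far$p_det_se[keep] / far$p_det[keep])^2 +
                         (close$p_det_se[keep] / close$p_det[keep])^2)
  } else if (nrow(curve) > 0 && any(is.finite(far$detected_count[keep]))) {
    cf <- pmax(far$detected_count[keep], 1)
    cc <- pmax(close$detected_count[keep], 1)
    se <- ratio * sqrt(1 / cf + 1 / cc)
  }
  smoothed <- FALSE
  if (smooth && nrow(curve) >= 3) {
    dr <- diff(curve$ratio)
    direction <- if (curve$ratio[nrow(curve)] >= curve$ratio[1]) 1 else -1
    viol <- which(direction * dr < 0)
    if (length(viol) > 0) {
      tol <- 2 * (se[viol] + se[viol + 1])
      if (any(abs(dr[viol]) > tol))
        stop_srswater(paste(
          "ratio curve is non-monotonic beyond 2 MC standard errors at",
          sprintf("mu_s' = %g", curve$mu_s_prime[viol[
            which.max(abs(dr[viol]) - tol)]])),
          "srswater_nonmonotonic_lut")
      iso <- isoreg(curve$mu_s_prime, direction * curve$ratio)
      curve$ratio_raw <- curve$ratio
      curve$ratio <- direction * iso$yf
      smoothed <- TRUE
    }
  }
  attr(curve, "wavelength") <- wavelength
  attr(curve, "mu_a") <- e$mu_a_cm1[1]
  attr(curve, "dropped") <- dropped
  attr(curve, "smoothed") <- smoothed
  class(curve) <- c("ratio_curve", "data.frame")
  curve
}

#' Invert a measured spatial ratio to reduced scattering
#'
#' Log-domain linear interpolation between the bracketing curve nodes:
#' \deqn{\hat\mu_s' = \mu_1' + (\mu_2' - \mu_1')
#'   \frac{\ln r^{corr} - \ln r_1}{\ln r_2 - \ln r_1}}
#' Exact at grid nodes; ties resolved toward the lower \eqn{\mu_s'}; no
#' extrapolation beyond the curve range.
#'
#' @param curve a [ratio_curve()].
#' @param r_corr corrected measured far/close ratio (> 0).
#' @return \eqn{\hat\mu_s'} in cm^-1.
#' @export
invert_ratio <- function(curve, r_corr) {
  stopifnot(inherits(curve, "ratio_curve"))
  if (!is.finite(r_corr) || r_corr <= 0)
    stop_srswater("non-positive ratio: flagged low-SNR and excluded",
                  "srswater_low_snr")
  if (nrow(curve) < 2)
    stop_srswater("ratio curve has fewer than 2 usable points",
                  "srswater_domain_error")
  r <- curve$ratio
  m <- curve$mu_s_prime
  hit <- which(r == r_corr)
  if (length(hit) > 0) return(m[min(hit)])
  if (r_corr < min(r) || r_corr > max(r))
    stop_srswater(sprintf(
      "ratio %.6g outside LUT curve range [%.6g, %.6g]; no extrapolation",
      r_corr, min(r), max(r)), "srswater_out_of_range")
  prod <- (r[-length(r)] - r_corr) * (r[-1] - r_corr)
  i <- which(prod < 0)[1]
  t <- (log(r_corr) - log(r[i])) / (log(r[i + 1]) - log(r[i]))
  m[i] + t * (m[i + 1] - m[i])
}

#' Write a LUT to CSV with a JSON sidecar
#'
#' @param lut an `srs_lut`.
#' @param path CSV output path; the sidecar is written to `paste0(path,
#'   ".json")` and records the nominal water fraction, engine, seed and a
#'   configuration hash.
#' @return invisibly, the CSV path.
#' @export
write_lut <- function(lut, path) {
  write.csv(as.data.frame(lut), path, row.names = FALSE)
  meta <- list(fw_nominal = attr(lut, "fw_nominal"),
               engine = attr(lut, "engine"),
               seed = attr(lut, "seed"),
               config_hash = config_hash(list(
                 fw_nominal = attr(lut, "fw_nominal"),
                 engine = attr(lut, "engine"),
                 seed = attr(lut, "seed"))),
               package_version = as.character(utils::packageVersion("srswater")))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Read a LUT written by [write_lut()]
#'
#' @param path CSV path.
#' @return an `srs_lut` with metadata restored from the sidecar if present.
#' @export
read_lut <- function(path) {
  lut <- read.csv(path, stringsAsFactors = FALSE)
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar)
    attr(lut, "fw_nominal") <- meta$fw_nominal
    attr(lut, "engine") <- meta$engine
    attr(lut, "seed") <- meta$seed
  }
  class(lut) <- c("srs_lut", "data.frame")
  lut
}
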