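# End-to-end consistency-check estimator: LUT-recovered mu_s' per
# wavelength, log-domain objective against the diffusion-model ratio, and
# a bounded dense-grid sweep over candidate water fractions.

#' Inversion configuration
#'
#' @param feasible_set length-2 interval of candidate water fractions within
#'   \[0, 1\]; default \[0.5, 0.95\] covers the phantom range with margin.
#' @param sweep_step sweep grid resolution (default 0.001).
#' @param wavelengths wavelengths entering the objective (K terms; default
#'   both bands, K = 2).
#' @param fw_nominal_for_lut nominal water fraction the LUT is expected to be
#'   conditioned on (absorption-consistent mode); NULL to accept any LUT.
#' @return list of class `inversion_config`.
#' @export
inversion_config <- function(feasible_set = c(0.5, 0.95), sweep_step = 0.001,
                             wavelengths = swir_wavelengths(),
                             fw_nominal_for_lut = NULL) {
  stopifnot(length(feasible_set) == 2, sweep_step > 0,
            feasible_set[1] >= 0, feasible_set[2] <= 1,
            feasible_set[1] <= feasible_set[2])
  structure(list(feasible_set = feasible_set, sweep_step = sweep_step,
                 wavelengths = wavelengths,
                 fw_nominal_for_lut = fw_nominal_for_lut),
            class = "inversion_config")
}

#' Log-domain water-fraction objective
#'
#' \deqn{E(f_w) = \sum_k [\ln r_k^{corr} - \ln r_k^{model}(f_w)]^2}
#' with one term per wavelength, using each wavelength's LUT-recovered
#' \eqn{\hat\mu_s'} inside the model ratio.
#'
#' @param f_w candidate water fraction(s) in \[0, 1\] (vectorized).
#' @param r_corr named numeric of corrected measured ratios by wavelength
#'   (names are wavelengths in nm, values > 0).
#' @param mu_s_prime_hat named numeric of recovered reduced scattering by
#'   wavelength (cm^-1).
#' @param rho_c,rho_f separations (cm).
#' @param n refractive index.
#' @return unitless error, same length as `f_w`.
#' @export
objective_fw <- function(f_w, r_corr, mu_s_prime_hat,
                         rho_c = 0.45, rho_f = 0.70, n = 1.33) {
  wls <- names(r_corr)
  if (length(wls) == 0)
    stop_srswater("objective needs at least one ratio term",
                  "srswater_domain_error")
  if (any(r_corr <= 0))
    stop_srswater("corrected ratios must be positive", "srswater_low_snr")
  E <- numeric(length(f_w))
  for (wl in wls) {
    rm <- model_ratio(f_w, mu_s_prime_hat[[wl]], as.numeric(wl),
                      rho_c, rho_f, n)
    E <- E + (log(r_corr[[wl]]) - log(rm))^2
  }
  E
}

#' Bounded sweep for the water-fraction estimate
#'
#' Dense-grid argmin of [objective_fw()] over the feasible interval; ties
#' break toward the lower water fraction; the full error curve is retained
#' for diagnostics. A flat objective (degenerate inputs) sets a warning flag
#' rather than failing.
#'
#' @param config an [inversion_config()].
#' @param r_corr named numeric of corrected ratios by wavelength.
#' @param mu_s_prime_hat named numeric of recovered mu_s' by wavelength.
#' @param rho_c,rho_f separations (cm).
#' @param n refractive index.
#' @return object of class `inversion_result`: `mu_s_prime_hat`, `f_w_hat`,
#'   `error_curve` (data.frame f_w, E), `flags`.
#' @export
sweep_fw <- function(config, r_corr, mu_s_prime_hat,
                     rho_c = 0.45, rho_f = 0.70, n = 1.33) {
  stopifnot(inherits(config, "inversion_config"))
  use <- intersect(names(r_corr), as.character(config$wavelengths))
  if (length(use) == 0)
    stop_srswater("no usable wavelength terms in the objective",
                  "srswater_pipeline_failure")
  grid <- seq(config$feasible_set[1], config$feasible_set[2],
              by = config$sweep_step)
  if (length(grid) == 0 ||
      grid[length(grid)] < config$feasible_set[2] - 1e-12)
    grid <- unique(c(grid, config$feasible_set[2]))
  E <- objective_fw(grid, r_corr[use], mu_s_prime_hat, rho_c, rho_f, n)
  flags <- character(0)
  if (diff(range(E)) < 1e-14) flags <- c(flags, "flat_objective")
  structure(list(mu_s_prime_hat = mu_s_prime_hat,
                 f_w_hat = grid[which.min(E)],
                 error_curve = data.frame(f_w = grid, E = E),
                 wavelengths_used = as.numeric(use),
                 flags = flags),
            class = "inversion_result")
}

#' @export
print.inversion_result <- function(x, ...) {
  cat(sprintf("<inversion_result> f_w_hat = %.4f", x$f_w_hat))
  if (length(x$mu_s_prime_hat))
    cat(sprintf("; mu_s' = [%s] cm^-1",
                paste(sprintf("%s nm: %.3f", names(x$mu_s_prime_hat),
                              unlist(x$mu_s_prime_hat)), collapse = ", ")))
  if (length(x$flags)) cat(" flags:", paste(x$flags, collapse = ","))
  cat("\n")
  invisible(x)
}

#' Run the full inversion pipeline
#'
#' Chains the signal pipeline (corrected ratios), the LUT inversion (one
#' \eqn{\hat\mu_s'} per wavelength) and the water-fraction sweep. The LUT's
#' nominal conditioning is recorded so absorption-consistent runs (LUT built
#' at the phantom's own nominal water fraction) are distinguishable from
#' fixed-nominal sensitivity runs (a single LUT applied across phantoms).
#'
#' @param frame_sample sample [measurement_frame()].
#' @param frame_reference reference [measurement_frame()].
#' @param lut an `srs_lut` from [build_lut()] (or [read_lut()]).
#' @param config an [inversion_config()].
#' @param geometry a [probe_geometry()].
#' @return an `inversion_result` with extra fields `lut_fw_nominal` and
#'   `lut_mode` ("absorption_consistent" or "fixed_nominal").
#' @export
run_pipeline <- function(frame_sample, frame_reference, lut,
                         config = inversion_config(),
                         geometry = probe_geometry()) {
  cr <- corrected_ratios(frame_sample, frame_reference, config$wavelengths)
  if (length(cr$r_corr) == 0)
    stop_srswater(paste("all wavelengths excluded:",
                        paste(sprintf("[%s nm] %s", names(cr$excluded),
                                      cr$excluded), collapse = "; ")),
                  "srswater_pipeline_failure")
  mu_hat <- list()
  flags <- character(0)
  for (wl in names(cr$r_corr)) {
    curve <- ratio_curve(lut, as.numeric(wl))
    mu_hat[[wl]] <- invert_ratio(curve, cr$r_corr[[wl]])
  }
  res <- sweep_fw(config, cr$r_corr, mu_hat,
                  geometry$rho_c, geometry$rho_f, geometry$n_medium)
  res$flags <- c(res$flags, flags,
                 if (length(cr$excluded))
                   sprintf("excluded_%s", names(cr$excluded)))
  res$lut_fw_nominal <- attr(lut, "fw_nominal")
  nominal <- config$fw_nominal_for_lut
  res$lut_mode <- if (is.null(nominal) ||
                      isTRUE(all.equal(nominal, res$lut_fw_nominal)))
    "absorption_consistent" else "fixed_nominal"
  res
}

#' Agreement metrics between reference and recovered water fractions
#'
#' Per-pair absolute percent error
#' \eqn{|\hat f_w - f_{w,true}| / f_{w,true} \times 100}, group means when a
#' grouping column is present, overall mean and max, bias (recovered minus
#' reference), MAE and RMSE in absolute water-fraction units.
#'
#' @param pairs data.frame with columns `f_w_true`, `f_w_hat` and optionally
#'   a grouping column named by `group`.
#' @param group optional name of the grouping column (e.g. `"il_pct"`).
#' @return list of class `agreement_metrics`: `per_pair` (data.frame with
#'   `abs_pct_err`), `mean_abs_pct_err`, `max_abs_pct_err`, `group_means`
#'   (named numeric or NULL), `bias`, `mae`, `rmse`, `n`.
#' @export
agreement_metrics <- function(pairs, group = NULL) {
  stopifnot(is.data.frame(pairs), nrow(pairs) >= 1,
            all(c("f_w_true", "f_w_hat") %in% names(pairs)))
  err <- pairs$f_w_hat - pairs$f_w_true
  ape <- ifelse(pairs$f_w_true == 0, NA_real_,
                abs(err) / pairs$f_w_true * 100)
  per_pair <- cbind(pairs, abs_pct_err = ape, bias = err)
  grp <- NULL
  if (!is.null(group) && group %in% names(pairs))
    grp <- tapply(ape, pairs[[group]], mean, na.rm = TRUE)
  structure(list(per_pair = per_pair,
                 mean_abs_pct_err = mean(ape, na.rm = TRUE),
                 max_abs_pct_err = if (all(is.na(ape))) NA_real_
                                   else max(ape, na.rm = TRUE),
                 group_means = grp,
                 bias = mean(err), mae = mean(abs(err)),
                 rmse = sqrt(mean(err^2)), n = nrow(pairs)),
            class = "agreement_metrics")
}

#' @export
print.agreement_metrics <- function(x, ...) {
  cat(sprintf(
    "<agreement_metrics> n = %d | MAPE = %.2f%% | max APE = %.2f%% | ",
    x$n, x$mean_abs_pct_err, x$max_abs_pct_err))
  cat(sprintf("bias = %+.4f | MAE = %.4f | RMSE = %.4f\n",
              x$bias, x$mae, x$rmse))
  if (!is.null(x$group_means))
    cat("  group mean APE:",
        paste(sprintf("%s: %.2f%%", names(x$group_means), x$group_means),
              collapse = " | "), "\n")
  invisible(x)
}
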