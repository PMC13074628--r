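# R-facing interface to the compiled Monte Carlo photon-transport engine.

#' Monte Carlo run configuration
#'
#' Desk-scale defaults: `n_photons` of 1e6 resolves the LUT operating region
#' for development and testing; the cluster-scale photon budgets used to
#' build production LUTs (the 2e9 regime) are reached by raising `n_photons`.
#' `min_counts` controls the photon-starvation flag on results. `engine`
#' selects the forward model used by [build_lut()]: `"mc"` (transport
#' simulation) or `"diffusion"` (dipole-model surrogate; deterministic and
#' instantaneous, used for closed-loop testing).
#'
#' @param n_photons photons launched per condition.
#' @param seed master seed; per-channel substreams are derived from it.
#' @param min_counts detected-count threshold below which a result is
#'   flagged `starved`.
#' @param rr_threshold Russian-roulette weight threshold.
#' @param rr_survive Russian-roulette survival probability.
#' @param max_steps per-photon step cap (safety guard).
#' @param engine `"mc"` or `"diffusion"`.
#' @param rerun_factor photon-budget multiplier for one conditioning rerun
#'   of LUT entries that come back starved (set to 1 to disable).
#' @return list of class `mc_config`.
#' @export
mc_config <- function(n_photons = 1e6, seed = 1L, min_counts = 100,
                      rr_threshold = 1e-4, rr_survive = 0.1,
                      max_steps = 1e6, engine = c("mc", "diffusion"),
                      rerun_factor = 10) {
  engine <- match.arg(engine)
  stopifnot(n_photons >= 1, min_counts >= 0, rr_threshold > 0,
            rr_survive > 0, rr_survive <= 1, rerun_factor >= 1)
  structure(list(n_photons = n_photons, seed = as.integer(seed),
                 min_counts = min_counts, rr_threshold = rr_threshold,
                 rr_survive = rr_survive, max_steps = max_steps,
                 engine = engine, rerun_factor = rerun_factor),
            class = "mc_config")
}

#' Simulate one probe channel
#'
#' Transports `n_photons` through a homogeneous slab with the probe-emulated
#' finite LED source at lateral offset `source$center_offset` and
#' aperture/acceptance-cone limited detection on the central axis. Detection
#' uses continuous absorption weighting, so `p_det` is the detected *weight*
#' fraction and `detected_count` the number of detected photon packets.
#'
#' @param props [optical_properties()] of the medium.
#' @param geometry [probe_geometry()].
#' @param source [source_model()]; defaults to the geometry's emitter at the
#'   close separation.
#' @param n_photons number of photons to launch (>= 1).
#' @param seed RNG seed (deterministic results for a fixed seed + config).
#' @param stream substream index (distinct per channel in LUT builds).
#' @param min_counts starvation threshold on `detected_count`.
#' @param rr_threshold,rr_survive Russian-roulette parameters.
#' @param max_steps per-photon step cap.
#' @return object of class `detection_result`: `p_det`, its Monte Carlo
#'   standard error `p_det_se`, `detected_count`, `launched`, `starved`,
#'   plus the full weight ledger (absorbed, escaped, mask-terminated,
#'   cone-rejected, roulette-killed/gained, lost).
#' @export
simulate_channel <- function(props, geometry = probe_geometry(),
                             source = NULL, n_photons = 1e6, seed = 1L,
                             stream = 0L, min_counts = 100,
                             rr_threshold = 1e-4, rr_survive = 0.1,
                             max_steps = 1e6) {
  stopifnot(inherits(props, "optical_properties"),
            inherits(geometry, "probe_geometry"))
  if (n_photons < 1)
    stop_srswater("n_photons must be >= 1", "srswater_domain_error")
  if (is.null(source))
    source <- source_model(geometry$rho_c, geometry$led_emitter_side)
  accept_cos_min <- cos(geometry$acceptance_half_angle * pi / 180)
  res <- mc_run(props$mu_a, props$mu_s, props$g,
                geometry$n_medium, geometry$n_outside,
                source$center_offset, source$emitter_side,
                source$divergence_exponent,
                geometry$aperture_radius, accept_cos_min,
                geometry$slab_x, geometry$slab_y, geometry$slab_z,
                n_photons, as.numeric(seed), as.numeric(stream),
                rr_threshold, rr_survive, max_steps)
  res$detected_count <- as.integer(res$detected_count)
  # MC standard error of p_det from the detected-weight second moment
  res$p_det_se <- sqrt(res$detected_weight_sq) / res$launched
  res$starved <- res$detected_count < min_counts
  class(res) <- "detection_result"
  res
}

#' @export
print.detection_result <- function(x, ...) {
  cat(sprintf(
    "<detection_result> p_det = %.4g (%d / %g photons)%s\n",
    x$p_det, x$detected_count, x$launched,
    if (x$starved) " [STARVED]" else ""))
  invisible(x)
}

#' Weight-ledger balance of a detection result
#'
#' Sum of all terminal weight tallies (detected, escaped, mask, cone,
#' absorbed, roulette-killed, lost) minus the weight injected by roulette
#' survivors; equals the launched weight up to floating-point accumulation.
#'
#' @param result a `detection_result`.
#' @return named list with `total` and `relative_error`.
#' @export
weight_balance <- function(result) {
  total <- result$detected_weight + result$escaped_weight +
    result$mask_weight + result$cone_weight + result$absorbed_weight +
    result$roulette_killed + result$lost_weight - result$roulette_gain
  list(total = total,
       relative_error = abs(total - result$launched) / result$launched)
}

#' Sample photon launch states
#'
#' Positions uniform over the emitter square at the surface, directions from
#' the generalized Lambertian distribution pointing into the medium.
#'
#' @param source a [source_model()].
#' @param n number of draws.
#' @param seed RNG seed.
#' @return data.frame with columns x, y, z, ux, uy, uz.
#' @export
launch_photons <- function(source, n, seed = 1L) {
  stopifnot(inherits(source, "source_model"))
  as.data.frame(mc_sample_launch(n, source$center_offset,
                                 source$emitter_side,
                                 source$divergence_exponent,
                                 as.numeric(seed)))
}

#' Sample Henyey-Greenstein scattering cosines
#'
#' @param n number of draws.
#' @param g anisotropy in (-1, 1); the distribution mean equals g.
#' @param seed RNG seed.
#' @return numeric vector of scattering-angle cosines.
#' @export
sample_scatter_cosines <- function(n, g, seed = 1L) {
  if (g <= -1 || g >= 1)
    stop_srswater("g must lie in (-1, 1)", "srswater_domain_error")
  mc_sample_hg(n, g, as.numeric(seed))
}

#' Sample exponential free path lengths
#'
#' @param n number of draws.
#' @param mu_t total attenuation coefficient (cm^-1, > 0).
#' @param seed RNG seed.
#' @return numeric vector of path lengths (cm).
#' @export
sample_free_paths <- function(n, mu_t, seed = 1L) {
  stopifnot(mu_t > 0)
  mc_sample_free_paths(n, mu_t, as.numeric(seed))
}

#' Unpolarized Fresnel reflectance
#'
#' @param n1 index on the incidence side.
#' @param n2 index on the transmission side.
#' @param cos_incidence cosine(s) of the incidence angle.
#' @return reflectance in \[0, 1\] (1 beyond the critical angle).
#' @export
fresnel_reflectance <- function(n1, n2, cos_incidence) {
  mc_fresnel(n1, n2, as.numeric(cos_incidence))
}

#' Classify a photon's top-surface interaction
#'
#' Applies the same rule as the transport engine: Fresnel
#' reflection/transmission decided by the uniform draw `xi`, transmitted
#' photons landing outside the aperture are mask-terminated, and transmitted
#' photons inside the aperture are detected only if the refracted exit
#' direction lies within the acceptance cone.
#'
#' @param position numeric length-2 (x, y) exit point on the surface (cm).
#' @param cos_incidence cosine of the incidence angle inside the medium.
#' @param geometry a [probe_geometry()].
#' @param xi uniform random number in \[0, 1) deciding the Fresnel branch
#'   (values close to 1 force the transmission branch whenever R < 1).
#' @return one of "reflect_internally", "detect", "terminate_on_mask",
#'   "escape".
#' @export
surface_interaction <- function(position, cos_incidence,
                                geometry = probe_geometry(), xi = 0.999999) {
  accept_cos_min <- cos(geometry$acceptance_half_angle * pi / 180)
  code <- mc_surface_classify(position[1], position[2], cos_incidence,
                              xi, geometry$n_medium, geometry$n_outside,
                              geometry$aperture_radius, accept_cos_min)
  c("reflect_internally", "detect", "terminate_on_mask", "escape")[code + 1L]
}
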