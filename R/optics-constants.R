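# Wavelength/channel definitions, probe geometry and the liquid-water
# absorption constants used to assign mu_a(lambda) from a water fraction.

#' SWIR wavelength bands used by the probe
#'
#' @return integer vector, nanometres.
#' @export
swir_wavelengths <- function() c(1450L, 1650L)

#' Source-detector separations
#'
#' @return named numeric vector (cm): close = 0.45, far = 0.70.
#' @export
separations <- function() c(close = 0.45, far = 0.70)

#' Physical channel map of the four-LED probe
#'
#' The physical LED placement interleaves wavelengths and separations
#' (CH2 is the 1650 nm *far* emitter, CH3 the 1450 nm *far* emitter), so all
#' frame handling goes through this map rather than assuming channel order.
#'
#' @return data.frame with columns `channel`, `wavelength_nm`,
#'   `separation` (label) and `rho_cm`.
#' @export
channel_map <- function() {
  data.frame(
    channel = c("CH1", "CH2", "CH3", "CH4"),
    wavelength_nm = c(1450L, 1650L, 1450L, 1650L),
    separation = c("close", "far", "far", "close"),
    rho_cm = unname(separations()[c("close", "far", "far", "close")]),
    stringsAsFactors = FALSE
  )
}

#' Packaged liquid-water absorption table
#'
#' Hale-Querry liquid-water absorption coefficients (cm^-1, from
#' \eqn{\mu_a = 4\pi k/\lambda}) on the tabulated 1.4-1.7 um grid, plus
#' log-linearly interpolated band values at the two LED centre wavelengths
#' (1450, 1650 nm). Band values are used as-is; no spectral integration over
#' the LED bandwidth is performed.
#'
#' @param path optional path to an alternative CSV with columns
#'   `wavelength_nm`, `mu_a_water_cm1`.
#' @return data.frame with columns `wavelength_nm`, `mu_a_water_cm1`.
#' @export
water_absorption_table <- function(path = NULL) {
  if (is.null(path)) {
    if (is.null(.srswater_env$water_tbl)) {
      f <- system.file("extdata", "water_absorption.csv", package = "srswater")
      .srswater_env$water_tbl <- read.csv(f, stringsAsFactors = FALSE)
    }
    return(.srswater_env$water_tbl)
  }
  tbl <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("wavelength_nm", "mu_a_water_cm1") %in% names(tbl)))
    stop_srswater("water table needs columns wavelength_nm, mu_a_water_cm1",
                  "srswater_parse_error")
  tbl
}

#' Liquid-water absorption coefficient at a tabulated wavelength
#'
#' Exact lookup only: an untabulated wavelength is an error, never silently
#' interpolated.
#'
#' @param lambda wavelength in nm.
#' @param table absorption table, see [water_absorption_table()].
#' @return \eqn{\mu_{a,water}} in cm^-1.
#' @export
water_absorption <- function(lambda, table = water_absorption_table()) {
  stopifnot(length(lambda) == 1, is.finite(lambda))
  i <- which(table$wavelength_nm == lambda)
  if (length(i) != 1)
    stop_srswater(sprintf("no water absorption constant tabulated at %g nm",
                          lambda), "srswater_missing_constant")
  v <- table$mu_a_water_cm1[i]
  if (!is.finite(v) || v <= 0)
    stop_srswater("tabulated water absorption must be positive",
                  "srswater_missing_constant")
  v
}

#' Assign a water-dominant absorption coefficient
#'
#' Water-dominant absorption model: \eqn{\mu_a(\lambda) = f_w \,
#' \mu_{a,water}(\lambda)}. Gelatin and lipid contributions are neglected in
#' the 1450-1650 nm bands.
#'
#' @param f_w bulk water fraction in \[0, 1\] (vectorized).
#' @param lambda wavelength in nm (must be tabulated).
#' @param table absorption table.
#' @return \eqn{\mu_a} in cm^-1.
#' @export
assign_absorption <- function(f_w, lambda, table = water_absorption_table()) {
  if (any(!is.finite(f_w)) || any(f_w < 0) || any(f_w > 1))
    stop_srswater("f_w must lie in [0, 1]", "srswater_domain_error")
  f_w * water_absorption(lambda, table)
}

#' Scattering coefficient from reduced scattering and anisotropy
#'
#' \eqn{\mu_s = \mu_s' / (1 - g)}; the similarity relation used to make
#' \eqn{\mu_s'} the controlled sweep variable with fixed g = 0.9.
#'
#' @param mu_s_prime reduced scattering coefficient, cm^-1.
#' @param g scattering anisotropy, `0 <= g < 1`.
#' @return \eqn{\mu_s} in cm^-1.
#' @export
mus_from_musp <- function(mu_s_prime, g) {
  if (any(g < 0) || any(g >= 1))
    stop_srswater("g must satisfy 0 <= g < 1", "srswater_domain_error")
  if (any(mu_s_prime < 0))
    stop_srswater("mu_s_prime must be non-negative", "srswater_domain_error")
  mu_s_prime / (1 - g)
}

#' Probe geometry description
#'
#' Geometry of the compact probe and the slab phantom it rests on. The
#' acceptance half-angle of the cylindrical collection tunnel is derived from
#' `atan(aperture_radius / tunnel_length)` unless given explicitly.
#'
#' @param rho_c,rho_f close/far source-detector separations (cm).
#' @param aperture_diameter collection aperture diameter (cm).
#' @param tunnel_length collection tunnel length (cm) used to derive the
#'   acceptance half-angle.
#' @param acceptance_half_angle acceptance cone half-angle (degrees),
#'   overriding the tunnel-derived value when non-NULL.
#' @param led_emitter_side emitting-area side length (cm).
#' @param slab_x,slab_y,slab_z phantom slab dimensions (cm).
#' @param n_medium,n_outside refractive indices of medium and air.
#' @return object of class `probe_geometry`.
#' @export
probe_geometry <- function(rho_c = 0.45, rho_f = 0.70,
                           aperture_diameter = 0.4, tunnel_length = 0.5,
                           acceptance_half_angle = NULL,
                           led_emitter_side = 0.1,
                           slab_x = 3.5, slab_y = 3.5, slab_z = 1.2,
                           n_medium = 1.33, n_outside = 1.0) {
  stopifnot(rho_f > rho_c, aperture_diameter >= 0, tunnel_length > 0,
            slab_x > 0, slab_y > 0, slab_z > 0, n_medium >= 1, n_outside >= 1)
  if (is.null(acceptance_half_angle)) {
    if (aperture_diameter == 0)
      stop_srswater(
        "a zero aperture needs an explicit acceptance_half_angle",
        "srswater_domain_error")
    acceptance_half_angle <- atan2(aperture_diameter / 2, tunnel_length) *
      180 / pi
  }
  if (acceptance_half_angle <= 0 || acceptance_half_angle > 90)
    stop_srswater("acceptance_half_angle must lie in (0, 90]",
                  "srswater_domain_error")
  structure(list(rho_c = rho_c, rho_f = rho_f,
                 aperture_diameter = aperture_diameter,
                 aperture_radius = aperture_diameter / 2,
                 tunnel_length = tunnel_length,
                 acceptance_half_angle = acceptance_half_angle,
                 led_emitter_side = led_emitter_side,
                 slab_x = slab_x, slab_y = slab_y, slab_z = slab_z,
                 n_medium = n_medium, n_outside = n_outside),
            class = "probe_geometry")
}

#' Optical properties of a homogeneous medium at one wavelength
#'
#' @param mu_a absorption coefficient (cm^-1).
#' @param mu_s scattering coefficient (cm^-1).
#' @param g scattering anisotropy in (-1, 1).
#' @param n refractive index (>= 1).
#' @return object of class `optical_properties`.
#' @export
optical_properties <- function(mu_a, mu_s, g = 0.9, n = 1.33) {
  if (mu_a < 0 || mu_s < 0 || g <= -1 || g >= 1 || n < 1)
    stop_srswater("invalid optical properties", "srswater_domain_error")
  structure(list(mu_a = mu_a, mu_s = mu_s, g = g, n = n),
            class = "optical_properties")
}

#' Finite LED source model
#'
#' Launch positions uniform over a square emitting area of side
#' `emitter_side` centred at lateral offset `center_offset` from the detector
#' axis; launch directions follow a generalized Lambertian distribution with
#' probability density proportional to \eqn{\cos^m\theta}.
#'
#' @param center_offset lateral offset rho of the emitter centre (cm).
#' @param emitter_side emitting-area side length (cm, >= 0; 0 collapses to a
#'   point source).
#' @param divergence_exponent generalized Lambertian exponent m (>= 1).
#' @return object of class `source_model`.
#' @export
source_model <- function(center_offset, emitter_side = 0.1,
                         divergence_exponent = 1) {
  if (emitter_side < 0 || divergence_exponent < 1)
    stop_srswater("emitter_side must be >= 0 and divergence_exponent >= 1",
                  "srswater_domain_error")
  structure(list(center_offset = center_offset, emitter_side = emitter_side,
                 divergence_exponent = divergence_exponent),
            class = "source_model")
}
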