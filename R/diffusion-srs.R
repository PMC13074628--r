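# Semi-infinite diffusion-dipole forward model for spatially resolved
# reflectance: a real isotropic source at depth z0 and an image source above
# the extrapolated boundary. Used as the parametric spatial-ratio proxy in
# the water-fraction sweep and as an independent oracle for the MC engine.

#' Internal-reflection parameter A(n)
#'
#' Extrapolated-boundary mismatch parameter \eqn{A = (1 + R_{eff}) /
#' (1 - R_{eff})} with the Groenhuis polynomial approximation
#' \eqn{R_{eff} = -1.440 n^{-2} + 0.710 n^{-1} + 0.668 + 0.0636 n}
#' (about 0.472 at n = 1.33). An index-matched boundary (n = 1) has
#' \eqn{R_{eff} = 0} exactly.
#'
#' @param n relative refractive index (medium / outside).
#' @return unitless A >= 1.
#' @export
internal_reflection_A <- function(n) {
  stopifnot(n >= 1)
  if (abs(n - 1) < 1e-12) return(1.0)
  r_eff <- -1.440 / n^2 + 0.710 / n + 0.668 + 0.0636 * n
  (1 + r_eff) / (1 - r_eff)
}

#' Dipole-model parameters
#'
#' Standard construction: \eqn{D = 1/(3(\mu_a + \mu_s'))},
#' \eqn{\mu_{eff} = \sqrt{\mu_a / D} = \sqrt{3 \mu_a (\mu_a + \mu_s')}},
#' source depth \eqn{z_0 = 1/(\mu_a + \mu_s')}, extrapolation distance
#' \eqn{z_b = 2 A(n) D}, and source / image distances
#' \eqn{r_1 = \sqrt{\rho^2 + z_0^2}},
#' \eqn{r_2 = \sqrt{\rho^2 + (z_0 + 2 z_b)^2}}.
#'
#' @param mu_a absorption coefficient (cm^-1, >= 0).
#' @param mu_s_prime reduced scattering coefficient (cm^-1, > 0).
#' @param n refractive index of the medium relative to the outside.
#' @param rho source-detector separation (cm, > 0).
#' @param C coupling constant (cancels in ratios).
#' @return object of class `dipole_params`.
#' @export
dipole_params <- function(mu_a, mu_s_prime, n = 1.33, rho, C = 1) {
  if (any(mu_s_prime <= 0))
    stop_srswater("mu_s_prime must be positive", "srswater_domain_error")
  if (any(mu_a < 0))
    stop_srswater("mu_a must be non-negative", "srswater_domain_error")
  if (any(rho <= 0))
    stop_srswater("rho must be positive", "srswater_domain_error")
  mut_p <- mu_a + mu_s_prime
  D <- 1 / (3 * mut_p)
  z0 <- 1 / mut_p
  zb <- 2 * internal_reflection_A(n) * D
  structure(list(D = D, mu_eff = sqrt(mu_a / D), z0 = z0, zb = zb,
                 r1 = sqrt(rho^2 + z0^2), r2 = sqrt(rho^2 + (z0 + 2 * zb)^2),
                 rho = rho, n = n, C = C),
            class = "dipole_params")
}

#' Dipole fluence-rate proxy
#'
#' \deqn{U(\rho) = \frac{C}{4\pi D}\left[\frac{e^{-\mu_{eff} r_1}}{r_1} -
#'   \frac{e^{-\mu_{eff} r_2}}{r_2}\right]}
#' If `rho` differs from the separation stored in `params`, the dipole
#' distances are recomputed from the stored `z0`/`zb`.
#'
#' @param rho source-detector separation (cm, vectorized).
#' @param params a [dipole_params()] object.
#' @return fluence proxy (arbitrary units, scales with `params$C`).
#' @export
dipole_fluence <- function(rho, params) {
  stopifnot(inherits(params, "dipole_params"))
  r1 <- sqrt(rho^2 + params$z0^2)
  r2 <- sqrt(rho^2 + (params$z0 + 2 * params$zb)^2)
  if (any(r1 <= 0))
    stop_srswater("degenerate dipole geometry (r1 = 0)",
                  "srswater_domain_error")
  params$C / (4 * pi * params$D) *
    (exp(-params$mu_eff * r1) / r1 - exp(-params$mu_eff * r2) / r2)
}

# dipole fluence without the C/(4*pi*D) prefactor, vectorized over mu_a;
# effective separations rho_eff may be a vector (aperture quadrature)
.dipole_kernel <- function(rho_eff, mu_a, mu_s_prime, n) {
  mut_p <- mu_a + mu_s_prime
  z0 <- 1 / mut_p
  zb <- 2 * internal_reflection_A(n) / (3 * mut_p)
  mu_eff <- sqrt(3 * mu_a * mut_p)
  r1 <- sqrt(outer(rho_eff^2, z0^2, `+`))
  r2 <- sqrt(outer(rho_eff^2, (z0 + 2 * zb)^2, `+`))
  exp(-r1 * rep(mu_eff, each = length(rho_eff))) / r1 -
    exp(-r2 * rep(mu_eff, each = length(rho_eff))) / r2
}

# mean dipole kernel over a circular collection aperture of radius `radius`
# centred on the detector axis, source at lateral distance rho. Polar
# midpoint quadrature; vectorized over mu_a (columns).
.aperture_mean_kernel <- function(rho, radius, mu_a, mu_s_prime, n,
                                  n_r = 24, n_phi = 32) {
  r <- (seq_len(n_r) - 0.5) / n_r * radius
  phi <- (seq_len(n_phi) - 0.5) / n_phi * 2 * pi
  gx <- outer(r, cos(phi))
  gy <- outer(r, sin(phi))
  d <- sqrt((rho - gx)^2 + gy^2)
  w <- rep(r, times = n_phi)                # area weight proportional to r
  k <- .dipole_kernel(as.vector(d), mu_a, mu_s_prime, n)
  colSums(k * w) / sum(w)
}

#' Diffusion-model far/close spatial ratio
#'
#' \deqn{r^{model}_\lambda(f_w) = U_\lambda(\rho_f; f_w) /
#'   U_\lambda(\rho_c; f_w)}
#' with \eqn{\mu_a = f_w \mu_{a,water}(\lambda)}. The coupling constant and
#' the \eqn{1/(4\pi D)} prefactor cancel, so the ratio depends only on the
#' separations and the optical properties. With `aperture_radius > 0` the
#' fluence is averaged over the circular collection aperture before the ratio
#' is formed (used when comparing against the aperture-integrating Monte
#' Carlo observable); the default 0 evaluates at the nominal separations, the
#' form used by the inversion sweep.
#'
#' @param f_w candidate bulk water fraction in \[0, 1\] (vectorized).
#' @param mu_s_prime reduced scattering coefficient (cm^-1, scalar).
#' @param lambda wavelength in nm (tabulated).
#' @param rho_c,rho_f close/far separations (cm).
#' @param n refractive index.
#' @param aperture_radius collection-aperture radius (cm); 0 for point
#'   evaluation.
#' @param table water absorption table.
#' @return unitless ratio, same length as `f_w`.
#' @export
model_ratio <- function(f_w, mu_s_prime, lambda, rho_c = 0.45, rho_f = 0.70,
                        n = 1.33, aperture_radius = 0,
                        table = water_absorption_table()) {
  mu_a <- assign_absorption(f_w, lambda, table)
  if (rho_f == rho_c) return(rep(1, length(f_w)))
  if (aperture_radius > 0) {
    uf <- .aperture_mean_kernel(rho_f, aperture_radius, mu_a, mu_s_prime, n)
    uc <- .aperture_mean_kernel(rho_c, aperture_radius, mu_a, mu_s_prime, n)
  } else {
    uf <- as.vector(.dipole_kernel(rho_f, mu_a, mu_s_prime, n))
    uc <- as.vector(.dipole_kernel(rho_c, mu_a, mu_s_prime, n))
  }
  uf / uc
}
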