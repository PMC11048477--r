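# Effective internal reflection coefficient for a tissue/air boundary,
# empirical polynomial in the refractive index.
internal_reflection_param <- function(n) {
  reff <- -1.440 / n^2 + 0.710 / n + 0.668 + 0.0636 * n
  (1 + reff) / (1 - reff)
}

#' Steady-state diffuse reflectance of a semi-infinite medium
#'
#' Continuous-wave diffusion forward model with the extrapolated-boundary
#' condition: two image dipoles at depths z0 = 1/(mu_a + mu_s') and
#' -(z0 + 2 zb), zb = 2 A D with D = 1/(3 (mu_a + mu_s')) and A the
#' internal-reflection parameter of the refractive index;
#' mu_eff = sqrt(3 mu_a (mu_a + mu_s')). Strictly decreasing in both `rho`
#' and `mu_a`. This is the physically realistic generator mode's forward
#' model (the instrument measures backscattered intensity in arbitrary
#' linear units, so only the shape matters downstream).
#'
#' @param mu_a absorption coefficient(s), cm^-1 (vectorised)
#' @param musp reduced scattering coefficient, cm^-1
#' @param rho source-detector distance, cm
#' @param n_ref tissue refractive index (default 1.4)
#' @return reflectance, arbitrary linear units
#' @export
diffusion_reflectance <- function(mu_a, musp, rho, n_ref = 1.4) {
  abort_if(any(mu_a < 0) || any(!is.finite(mu_a)), "mu_a must be >= 0")
  abort_if(any(musp <= 0), "musp must be positive")
  abort_if(any(rho <= 0), "rho must be positive")
  abort_if(n_ref <= 1, "refractive index must exceed 1")
  mut <- mu_a + musp
  z0 <- 1 / mut
  D <- 1 / (3 * mut)
  zb <- 2 * internal_reflection_param(n_ref) * D
  mueff <- sqrt(3 * mu_a * mut)
  r1 <- sqrt(z0^2 + rho^2)
  r2 <- sqrt((z0 + 2 * zb)^2 + rho^2)
  (1 / (4 * pi)) * (z0 * (mueff + 1 / r1) * exp(-mueff * r1) / r1^2 +
                      (z0 + 2 * zb) * (mueff + 1 / r2) * exp(-mueff * r2) / r2^2)
}
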