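#' Seawater density anomaly at atmospheric pressure (sigma-t)
#'
#' EOS-80 one-atmosphere equation of state (Millero & Poisson, 1981):
#' density of seawater at 0 dbar from temperature and practical salinity,
#' returned as the density anomaly sigma = rho - 1000 kg m^-3. For the
#' upper-ocean mixed-layer depth estimation done here, sigma-t is an
#' adequate stand-in for potential density referenced to the surface.
#'
#' @param temperature In-situ temperature, deg C.
#' @param salinity Practical salinity (dimensionless).
#' @return Density anomaly sigma-t in kg m^-3, same length as inputs.
#' @examples
#' sw_sigma_t(10, 35)  # about 26.95
#' @export
sw_sigma_t <- function(temperature, salinity) {
  t <- temperature
  s <- salinity
  stopifnot(is.numeric(t), is.numeric(s))
  # pure-water density (Bigg 1967, as adopted in EOS-80)
  rho_w <- 999.842594 + 6.793952e-2 * t - 9.095290e-3 * t^2 +
    1.001685e-4 * t^3 - 1.120083e-6 * t^4 + 6.536332e-9 * t^5
  a <- 0.824493 - 4.0899e-3 * t + 7.6438e-5 * t^2 -
    8.2467e-7 * t^3 + 5.3875e-9 * t^4
  b <- -5.72466e-3 + 1.0227e-4 * t - 1.6546e-6 * t^2
  c0 <- 4.8314e-4
  rho_w + a * s + b * s^1.5 + c0 * s^2 - 1000
}
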