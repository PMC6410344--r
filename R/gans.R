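# Gans (quasi-static) theory for prolate ellipsoids.

#' Depolarization factors of a prolate spheroid
#'
#' For semiaxes a >= b = c with axis ratio r = a/b and eccentricity
#' e = sqrt(1 - 1/r^2):
#' PA = ((1 - e^2)/e^2) \[ (1/(2e)) log((1+e)/(1-e)) - 1 \],
#' PB = PC = (1 - PA)/2. At r = 1 all three equal 1/3; as r -> Inf,
#' PA -> 0 and PB -> 1/2 (needle limit). PA + PB + PC = 1 exactly.
#'
#' @param r Axis ratio(s) >= 1.
#' @return Tibble with columns `r`, `PA`, `PB`, `PC`.
#' @export
#' @examples
#' depolarization_factors(c(1, 2, 5))
depolarization_factors <- function(r) {
  if (any(r < 1)) {
    abort("axis ratio must be >= 1", class = "nanotherm_domain_error")
  }
  e2 <- 1 - 1 / r^2
  e <- sqrt(e2)
  PA <- ifelse(e < 1e-6,
    # series expansion: PA = 1/3 - 2 e^2 / 15 + O(e^4), avoids 0/0 at r = 1
    1 / 3 - 2 * e2 / 15,
    (1 - e2) / e2 * (log((1 + e) / (1 - e)) / (2 * e) - 1)
  )
  PB <- (1 - PA) / 2
  tibble(r = r, PA = PA, PB = PB, PC = PB)
}

#' Gans absorption cross section of a prolate ellipsoid
#'
#' Quasi-static absorption cross section
#' sigma = (2 pi V eps_m^(3/2) / (3 lambda)) *
#'   sum_j (1/Pj^2) eps2 / \[(eps1 + ((1-Pj)/Pj) eps_m)^2 + eps2^2\]
#' over the three principal axes j in (A, B, C), with PB = PC. V in nm^3 and
#' lambda in nm give the cross section in nm^2. At r = 1 this reduces
#' exactly to the Rayleigh absorption of a small sphere. No retardation
#' correction is applied, so the result is size-accurate only for particles
#' much smaller than the wavelength.
#'
#' @param spec An [ellipsoid_spec()].
#' @param wavelength_nm Vacuum wavelength(s), nm.
#' @return Numeric vector of absorption cross sections, nm^2.
#' @export
#' @examples
#' gans_absorption(ellipsoid_spec(2, volume_nm3 = 4 / 3 * pi * 10^3), 600)
gans_absorption <- function(spec, wavelength_nm) {
  stopifnot(inherits(spec, "ellipsoid_spec"))
  eps <- bulk_dielectric(spec$material, wavelength_nm)
  eps_m <- Re(bulk_dielectric(spec$medium, wavelength_nm))
  P <- depolarization_factors(spec$axis_ratio)
  pj <- c(P$PA, P$PB, P$PC)
  e1 <- Re(eps)
  e2 <- Im(eps)
  terms <- vapply(pj, function(p) {
    (1 / p^2) * e2 / ((e1 + (1 - p) / p * eps_m)^2 + e2^2)
  }, numeric(length(wavelength_nm)))
  if (length(wavelength_nm) == 1L) terms <- matrix(terms, nrow = 1L)
  2 * pi * spec$volume_nm3 * eps_m^(3 / 2) / (3 * wavelength_nm) *
    rowSums(terms)
}
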