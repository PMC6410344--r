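# Mie theory for solid and core-shell spheres.
#
# Riccati-Bessel functions psi_n(z) = z j_n(z), chi_n(z) = -z y_n(z) and
# xi_n(z) = z h_n^(1)(z) = psi_n - i chi_n, evaluated for complex argument.
# psi is obtained by downward recurrence (upward is unstable for complex z),
# chi by upward recurrence (the y_n solution grows, so upward is stable).
# Derivatives use Z'_n = Z_{n-1} - (n/z) Z_n, valid for any solution.

.riccati <- function(nmax, z) {
  stopifnot(nmax >= 1)
  NN <- nmax + 15L + ceiling(Mod(z))
  jj <- complex(NN + 2L)
  jj[NN + 2L] <- 0
  jj[NN + 1L] <- 1e-30
  for (i in seq(NN, 1L)) {
    jj[i] <- (2 * i + 1) / z * jj[i + 1L] - jj[i + 2L]
  }
  jj <- jj * (sin(z) / z) / jj[1L]          # normalise with j_0
  psi <- z * jj[seq_len(nmax + 1L)]         # orders 0..nmax
  yy <- complex(nmax + 1L)
  yy[1L] <- -cos(z) / z
  yy[2L] <- (-cos(z) / z - sin(z)) / z
  if (nmax >= 2) {
    for (i in seq(1L, nmax - 1L)) {
      yy[i + 2L] <- (2 * i + 1) / z * yy[i + 1L] - yy[i]
    }
  }
  chi <- -z * yy
  n <- seq_len(nmax)
  dpsi <- c(NA_complex_, psi[n] - n / z * psi[n + 1L])
  dchi <- c(NA_complex_, chi[n] - n / z * chi[n + 1L])
  list(f = psi, df = dpsi, g = chi, dg = dchi)
}

# relative refractive index with Im >= 0 (absorbing) branch
.rel_index <- function(eps, n_medium) {
  m <- sqrt(eps) / n_medium
  ifelse(Im(m) < 0, -m, m)
}

.wiscombe_nmax <- function(x) {
  max(3L, as.integer(ceiling(x + 4 * x^(1 / 3) + 2)))
}

# Core Mie computation for a (possibly degenerate) coated sphere at one
# wavelength. R1_nm = 0 gives the solid sphere (shell auxiliaries A_n = B_n
# = 0). eps_core/eps_shell are complex relative permittivities, n_medium the
# real medium index. Returns the partial-wave coefficients and efficiencies.
.mie_single <- function(wavelength_nm, R1_nm, R2_nm, eps_core, eps_shell,
                        n_medium, nmax = NULL) {
  x2 <- 2 * pi * R2_nm * n_medium / wavelength_nm
  m2 <- .rel_index(eps_shell, n_medium)
  if (is.null(nmax)) nmax <- .wiscombe_nmax(x2)
  idx <- seq(2L, nmax + 1L)                 # orders 1..nmax
  rb_x2 <- .riccati(nmax, as.complex(x2))
  rb_m2x2 <- .riccati(nmax, m2 * x2)
  xi <- rb_x2$f - 1i * rb_x2$g
  dxi <- rb_x2$df - 1i * rb_x2$dg
  if (R1_nm > 0) {
    m1 <- .rel_index(eps_core, n_medium)
    x1 <- 2 * pi * R1_nm * n_medium / wavelength_nm
    rb_m2x1 <- .riccati(nmax, m2 * x1)
    rb_m1x1 <- .riccati(nmax, m1 * x1)
    An <- (m2 * rb_m2x1$f[idx] * rb_m1x1$df[idx] -
             m1 * rb_m2x1$df[idx] * rb_m1x1$f[idx]) /
          (m2 * rb_m2x1$g[idx] * rb_m1x1$df[idx] -
             m1 * rb_m2x1$dg[idx] * rb_m1x1$f[idx])
    Bn <- (m2 * rb_m1x1$f[idx] * rb_m2x1$df[idx] -
             m1 * rb_m1x1$df[idx] * rb_m2x1$f[idx]) /
          (m2 * rb_m2x1$dg[idx] * rb_m1x1$f[idx] -
             m1 * rb_m2x1$g[idx] * rb_m1x1$df[idx])
  } else {
    An <- Bn <- complex(nmax)
  }
  psi_s <- rb_m2x2$f[idx] - An * rb_m2x2$g[idx]
  dpsi_s <- rb_m2x2$df[idx] - An * rb_m2x2$dg[idx]
  psi_t <- rb_m2x2$f[idx] - Bn * rb_m2x2$g[idx]
  dpsi_t <- rb_m2x2$df[idx] - Bn * rb_m2x2$dg[idx]
  an <- (rb_x2$f[idx] * dpsi_s - m2 * rb_x2$df[idx] * psi_s) /
        (xi[idx] * dpsi_s - m2 * dxi[idx] * psi_s)
  bn <- (m2 * rb_x2$f[idx] * dpsi_t - rb_x2$df[idx] * psi_t) /
        (m2 * xi[idx] * dpsi_t - dxi[idx] * psi_t)
  if (any(!is.finite(an)) || any(!is.finite(bn))) {
    abort(sprintf(
      "Mie series failed to evaluate (x2 = %.3g, nmax = %d)", x2, nmax),
      class = "nanotherm_numeric_error")
  }
  n <- seq_len(nmax)
  w <- 2 * n + 1
  qext <- 2 / x2^2 * sum(w * Re(an + bn))
  qabs <- 2 / x2^2 * sum(w * (Re(an + bn) - Mod(an)^2 - Mod(bn)^2))
  list(order = n, an = an, bn = bn, An = An, Bn = Bn,
       x1 = if (R1_nm > 0) 2 * pi * R1_nm * n_medium / wavelength_nm else 0,
       x2 = x2, qabs = qabs, qext = qext, qsca = qext - qabs)
}

.sphere_dielectric <- function(spec, wavelength_nm, size_correction) {
  R <- spec$diameter_nm / 2
  if (size_correction && identical(spec$material$name, "Au")) {
    size_corrected_dielectric(spec$material, wavelength_nm, L_eff_nm = R)
  } else {
    bulk_dielectric(spec$material, wavelength_nm)
  }
}

.shell_dielectrics <- function(spec, wavelength_nm, size_correction) {
  t_sh <- spec$outer_radius_nm - spec$core_radius_nm
  eps_core <- if (size_correction && identical(spec$core$name, "Au")) {
    size_corrected_dielectric(spec$core, wavelength_nm,
                              L_eff_nm = spec$core_radius_nm)
  } else {
    bulk_dielectric(spec$core, wavelength_nm)
  }
  eps_shell <- if (size_correction && identical(spec$shell$name, "Au")) {
    size_corrected_dielectric(spec$shell, wavelength_nm, L_eff_nm = t_sh)
  } else {
    bulk_dielectric(spec$shell, wavelength_nm)
  }
  list(core = eps_core, shell = eps_shell)
}

#' Mie absorption efficiency of a solid sphere
#'
#' Partial-wave (Mie) absorption efficiency
#' Qabs = (2/x^2) sum (2n+1) (Re\[an+bn\] - |an|^2 - |bn|^2),
#' i.e. the absorption cross section divided by the geometric cross section
#' pi R^2. The series is truncated at the Wiscombe order
#' nmax = ceil(x + 4 x^(1/3) + 2).
#'
#' When `size_correction` is `TRUE` (the default) and the particle is gold,
#' the dielectric is corrected for free-electron surface scattering with
#' `L_eff` equal to the particle radius; see [size_corrected_dielectric()].
#'
#' @param spec A [sphere_spec()].
#' @param wavelength_nm Vacuum wavelength(s), nm.
#' @param size_correction Apply the surface scattering correction to gold?
#' @return Numeric vector of absorption efficiencies (dimensionless).
#' @export
#' @examples
#' qabs_sphere(sphere_spec(40), 532)
qabs_sphere <- function(spec, wavelength_nm, size_correction = TRUE) {
  stopifnot(inherits(spec, "sphere_spec"))
  R <- spec$diameter_nm / 2
  nm <- Re(refractive_index(spec$medium, wavelength_nm))
  eps <- .sphere_dielectric(spec, wavelength_nm, size_correction)
  vapply(seq_along(wavelength_nm), function(i) {
    .mie_single(wavelength_nm[i], 0, R, eps[i], eps[i], nm[i])$qabs
  }, numeric(1))
}

#' Mie absorption efficiency of a core--shell particle
#'
#' Same partial-wave series as [qabs_sphere()] with the shell auxiliaries
#' An, Bn coupling the two layers. With identical core and shell materials it
#' reduces exactly to the solid sphere. With `size_correction = TRUE` a gold
#' shell uses `L_eff` equal to the shell thickness.
#'
#' @param spec A [shell_spec()].
#' @inheritParams qabs_sphere
#' @return Numeric vector of absorption efficiencies.
#' @export
#' @examples
#' qabs_shell(shell_spec(10, 15), 590)
qabs_shell <- function(spec, wavelength_nm, size_correction = TRUE) {
  stopifnot(inherits(spec, "shell_spec"))
  nm <- Re(refractive_index(spec$medium, wavelength_nm))
  eps <- .shell_dielectrics(spec, wavelength_nm, size_correction)
  vapply(seq_along(wavelength_nm), function(i) {
    .mie_single(wavelength_nm[i], spec$core_radius_nm, spec$outer_radius_nm,
                eps$core[i], eps$shell[i], nm[i])$qabs
  }, numeric(1))
}

#' Mie partial-wave coefficients
#'
#' Exposes the scattering coefficients an, bn and (for shells) the layer
#' auxiliaries An, Bn together with the size parameters, mostly for
#' diagnostics and convergence studies.
#'
#' @param spec A [sphere_spec()] or [shell_spec()].
#' @param wavelength_nm A single vacuum wavelength, nm.
#' @param size_correction Apply the gold surface scattering correction?
#' @param nmax Optional series truncation override.
#' @return A tibble with columns `order`, `an`, `bn`, `An`, `Bn` and
#'   attributes `x1`, `x2`, `qabs`, `qext`.
#' @export
mie_coefficients <- function(spec, wavelength_nm, size_correction = TRUE,
                             nmax = NULL) {
  stopifnot(length(wavelength_nm) == 1)
  nm <- Re(refractive_index(spec$medium, wavelength_nm))
  res <- if (inherits(spec, "sphere_spec")) {
    eps <- .sphere_dielectric(spec, wavelength_nm, size_correction)
    .mie_single(wavelength_nm, 0, spec$diameter_nm / 2, eps, eps, nm,
                nmax = nmax)
  } else if (inherits(spec, "shell_spec")) {
    eps <- .shell_dielectrics(spec, wavelength_nm, size_correction)
    .mie_single(wavelength_nm, spec$core_radius_nm, spec$outer_radius_nm,
                eps$core, eps$shell, nm, nmax = nmax)
  } else {
    abort("mie_coefficients needs a sphere_spec or shell_spec",
          class = "nanotherm_error")
  }
  out <- tibble(order = res$order, an = res$an, bn = res$bn,
                An = res$An, Bn = res$Bn)
  attr(out, "x1") <- res$x1
  attr(out, "x2") <- res$x2
  attr(out, "qabs") <- res$qabs
  attr(out, "qext") <- res$qext
  out
}

#' Absorption cross section, nm^2
#'
#' Qabs times the geometric cross section pi R^2 (outer radius for shells).
#' Ellipsoids are delegated to [gans_absorption()], for which the
#' cross section is already the natural output.
#'
#' @inheritParams qabs_sphere
#' @param spec Any `particle_spec`.
#' @return Numeric vector of cross sections in nm^2.
#' @export
absorption_cross_section <- function(spec, wavelength_nm,
                                     size_correction = TRUE) {
  if (inherits(spec, "sphere_spec")) {
    qabs_sphere(spec, wavelength_nm, size_correction) *
      pi * (spec$diameter_nm / 2)^2
  } else if (inherits(spec, "shell_spec")) {
    qabs_shell(spec, wavelength_nm, size_correction) *
      pi * spec$outer_radius_nm^2
  } else if (inherits(spec, "ellipsoid_spec")) {
    gans_absorption(spec, wavelength_nm)
  } else {
    abort("unknown particle spec", class = "nanotherm_error")
  }
}
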