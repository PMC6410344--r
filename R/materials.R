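#' Optical materials
#'
#' Tabulated complex refractive indices for the materials used throughout the
#' optics layer: gold (`"Au"`), fused silica (`"SiO2"`), water (`"water"`) and
#' titania (`"TiO2"`). Each material ships as a plain CSV fixture with columns
#' `wavelength_nm,n,k` covering at least 400--1100 nm. The gold entry is the
#' Brendel--Bormann analytic dispersion model of Rakic et al. (1998) evaluated
#' onto a 1 nm grid; silica follows the Malitson (1965) Sellmeier dispersion;
#' water is the constant n = 1.33; titania is a constant real index of 2.5.
#'
#' Sign conventions: tables store `n` and `k` both non-negative (engineering
#' convention n' - j n''). All dielectric functions returned by the package
#' use the physics convention eps = eps1 + i*eps2 with eps2 >= 0 for
#' absorbing media; the conversion happens in exactly one place,
#' [bulk_dielectric()].
#'
#' @param name Material name, one of `"Au"`, `"SiO2"`, `"water"`, `"TiO2"`
#'   (case insensitive; `"gold"`, `"silica"` also accepted).
#'
#' @return An object of class `optical_material`: a list with `name`, `table`
#'   (tibble `wavelength_nm`, `n`, `k`) and `valid_range` (length-2 numeric,
#'   nm).
#'
#' @references Rakic, A. D., Djurisic, A. B., Elazar, J. M., Majewski, M. L.
#'   (1998) Optical properties of metallic films for vertical-cavity
#'   optoelectronic devices. Applied Optics 37, 5271--5283.
#' @export
#' @examples
#' au <- optical_material("Au")
#' bulk_dielectric(au, 532)
optical_material <- function(name) {
  key <- switch(tolower(name),
    "au" = , "gold" = "gold",
    "sio2" = , "silica" = "silica",
    "water" = "water",
    "tio2" = , "titania" = "tio2",
    abort(paste0("unknown material '", name, "'"), class = "nanotherm_error")
  )
  tab <- .material_cache(key)
  structure(
    list(
      name = switch(key, gold = "Au", silica = "SiO2", water = "water",
                    tio2 = "TiO2"),
      table = tab,
      valid_range = range(tab$wavelength_nm)
    ),
    class = "optical_material"
  )
}

.material_env <- new.env(parent = emptyenv())

.material_cache <- function(key) {
  if (is.null(.material_env[[key]])) {
    path <- system.file("extdata", "optics", paste0(key, ".csv"),
                        package = "nanotherm", mustWork = TRUE)
    tab <- as_tibble(read.csv(path))
    stopifnot(all(diff(tab$wavelength_nm) > 0), all(tab$n > 0), all(tab$k >= 0))
    .material_env[[key]] <- tab
  }
  .material_env[[key]]
}

#' @export
print.optical_material <- function(x, ...) {
  cat("<optical_material> ", x$name, ": ", nrow(x$table), " points, ",
      x$valid_range[1], "-", x$valid_range[2], " nm\n", sep = "")
  invisible(x)
}

.as_material <- function(x) {
  if (inherits(x, "optical_material")) x else optical_material(x)
}

#' Complex refractive index of a material
#'
#' Linear interpolation of the tabulated `n` and `k` (separately, never of the
#' squared dielectric), returned under the physics convention `n + i k`.
#'
#' @param material An [optical_material()] or a material name.
#' @param wavelength_nm Vacuum wavelength(s) in nm, within the material's
#'   tabulated range.
#' @return Complex vector, one value per wavelength.
#' @export
refractive_index <- function(material, wavelength_nm) {
  material <- .as_material(material)
  rng <- material$valid_range
  if (any(wavelength_nm < rng[1] | wavelength_nm > rng[2])) {
    abort(sprintf(
      "wavelength out of range for %s: tabulated over [%g, %g] nm",
      material$name, rng[1], rng[2]), class = "nanotherm_range_error")
  }
  tab <- material$table
  nr <- approx(tab$wavelength_nm, tab$n, xout = wavelength_nm)$y
  ni <- approx(tab$wavelength_nm, tab$k, xout = wavelength_nm)$y
  complex(real = nr, imaginary = ni)
}

#' Bulk complex dielectric function
#'
#' eps = (n + i k)^2 under the internal physics convention (eps2 = 2 n k >= 0
#' for absorbing media). Equivalent to squaring the engineering-convention
#' index n' - j n'' and flipping the sign of the imaginary part.
#'
#' @inheritParams refractive_index
#' @return Complex vector of relative permittivities.
#' @export
#' @examples
#' bulk_dielectric("water", 532)  # (1.33)^2 = 1.7689 + 0i
bulk_dielectric <- function(material, wavelength_nm) {
  refractive_index(material, wavelength_nm)^2
}

#' Free-electron constants for the surface scattering correction
#'
#' Drude-model constants for gold used by [size_corrected_dielectric()]:
#' plasma angular frequency `omega_p` = 1.37e16 rad/s, Fermi velocity `v_F` =
#' 1.4e6 m/s, bulk electron mean free path `L_inf` = 4.2e-8 m and the
#' dimensionless surface scattering constant `A` = 1.
#'
#' @param omega_p Plasma angular frequency, rad/s.
#' @param v_F Fermi velocity, m/s.
#' @param L_inf Bulk mean free path, m.
#' @param A Dimensionless surface-scattering constant.
#' @return A named list of class `drude_constants`.
#' @export
drude_constants <- function(omega_p = 1.37e16, v_F = 1.4e6,
                            L_inf = 4.2e-8, A = 1) {
  vals <- c(omega_p = omega_p, v_F = v_F, L_inf = L_inf, A = A)
  if (any(vals <= 0)) {
    abort("all Drude constants must be strictly positive",
          class = "nanotherm_domain_error")
  }
  structure(as.list(vals), class = "drude_constants")
}

#' Size-corrected metal dielectric function
#'
#' For metal structures smaller than the bulk electron mean free path, surface
#' scattering shortens the free-electron relaxation. The bulk dielectric is
#' corrected by removing the bulk Drude damping and restoring it with the
#' reduced mean free path `L_eff`:
#'
#' eps(omega, L_eff) = eps_bulk(omega)
#'   + omega_p^2 / (omega^2 + i omega v_F / L_inf)
#'   - omega_p^2 / (omega^2 + i omega (v_F / L_inf + A v_F / L_eff))
#'
#' As `L_eff -> Inf` the two added terms cancel and the bulk value is
#' recovered. `L_eff` defaults to the metal layer thickness for shells and to
#' the radius for solid spheres (set by the callers in the Mie layer).
#'
#' @inheritParams refractive_index
#' @param L_eff_nm Reduced mean free path in nm (> 0).
#' @param constants A [drude_constants()] object.
#' @return Complex vector of corrected relative permittivities (eps2 >= 0).
#' @export
#' @examples
#' size_corrected_dielectric("Au", 532, L_eff_nm = 5)
size_corrected_dielectric <- function(material, wavelength_nm, L_eff_nm,
                                      constants = drude_constants()) {
  if (!is.numeric(L_eff_nm) || any(L_eff_nm <= 0)) {
    abort("L_eff_nm must be strictly positive",
          class = "nanotherm_domain_error")
  }
  eps_b <- bulk_dielectric(material, wavelength_nm)
  omega <- 2 * pi * .c0 / (wavelength_nm * 1e-9)
  L_eff <- L_eff_nm * 1e-9
  g_inf <- constants$v_F / constants$L_inf
  g_eff <- g_inf + constants$A * constants$v_F / L_eff
  eps_b +
    constants$omega_p^2 / (omega^2 + 1i * omega * g_inf) -
    constants$omega_p^2 / (omega^2 + 1i * omega * g_eff)
}

#' Dump a material table onto a wavelength grid
#'
#' @inheritParams refractive_index
#' @param wavelength_nm Grid of wavelengths, nm.
#' @return Tibble `wavelength_nm`, `n`, `k`.
#' @export
material_table <- function(material, wavelength_nm) {
  m <- refractive_index(material, wavelength_nm)
  tibble(wavelength_nm = wavelength_nm, n = Re(m), k = Im(m))
}
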