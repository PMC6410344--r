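#' Particle geometry specifications
#'
#' Constructors for the three particle geometries handled by the optics
#' layer: a solid sphere, a concentric core--shell particle and a prolate
#' ellipsoid (semiaxes a >= b = c). Materials may be given as names or as
#' [optical_material()] objects.
#'
#' @param diameter_nm Sphere diameter, nm (> 0).
#' @param material,medium Particle and surrounding-medium materials.
#' @return An object of class `sphere_spec`, `shell_spec` or
#'   `ellipsoid_spec` (all inherit `particle_spec`).
#' @name particle_spec
NULL

#' @rdname particle_spec
#' @export
sphere_spec <- function(diameter_nm, material = "Au", medium = "water") {
  if (!is.numeric(diameter_nm) || diameter_nm <= 0) {
    abort("diameter_nm must be > 0", class = "nanotherm_domain_error")
  }
  structure(
    list(diameter_nm = diameter_nm,
         material = .as_material(material),
         medium = .as_material(medium)),
    class = c("sphere_spec", "particle_spec")
  )
}

#' @rdname particle_spec
#' @param core_radius_nm,outer_radius_nm Inner and outer radii of a
#'   core--shell particle, nm (0 < core < outer).
#' @param core,shell Core and shell materials of a core--shell particle.
#' @export
shell_spec <- function(core_radius_nm, outer_radius_nm,
                       core = "SiO2", shell = "Au", medium = "water") {
  if (!is.numeric(core_radius_nm) || !is.numeric(outer_radius_nm) ||
      core_radius_nm <= 0 || core_radius_nm >= outer_radius_nm) {
    abort("need 0 < core_radius_nm < outer_radius_nm",
          class = "nanotherm_geometry_error")
  }
  structure(
    list(core_radius_nm = core_radius_nm,
         outer_radius_nm = outer_radius_nm,
         core = .as_material(core),
         shell = .as_material(shell),
         medium = .as_material(medium)),
    class = c("shell_spec", "particle_spec")
  )
}

#' @rdname particle_spec
#' @param axis_ratio Ratio r = a/b of the long to short semiaxis (>= 1).
#' @param volume_nm3 Particle volume, nm^3.
#' @export
ellipsoid_spec <- function(axis_ratio, volume_nm3, material = "Au",
                           medium = "water") {
  if (!is.numeric(axis_ratio) || axis_ratio < 1) {
    abort("axis_ratio must be >= 1", class = "nanotherm_domain_error")
  }
  if (!is.numeric(volume_nm3) || volume_nm3 <= 0) {
    abort("volume_nm3 must be > 0", class = "nanotherm_domain_error")
  }
  # V = 4/3 pi a b^2 with a = r b
  b <- (volume_nm3 / (4 / 3 * pi * axis_ratio))^(1 / 3)
  structure(
    list(axis_ratio = axis_ratio, volume_nm3 = volume_nm3,
         semiaxis_a_nm = axis_ratio * b, semiaxis_b_nm = b,
         material = .as_material(material), medium = .as_material(medium)),
    class = c("ellipsoid_spec", "particle_spec")
  )
}

#' @export
print.particle_spec <- function(x, ...) {
  if (inherits(x, "sphere_spec")) {
    cat("<sphere_spec> d =", x$diameter_nm, "nm,", x$material$name,
        "in", x$medium$name, "\n")
  } else if (inherits(x, "shell_spec")) {
    cat("<shell_spec> R1 =", x$core_radius_nm, "nm", x$core$name,
        "core / R2 =", x$outer_radius_nm, "nm", x$shell$name,
        "shell in", x$medium$name, "\n")
  } else {
    cat("<ellipsoid_spec> r =", x$axis_ratio, ", V =", x$volume_nm3,
        "nm^3,", x$material$name, "in", x$medium$name, "\n")
  }
  invisible(x)
}
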