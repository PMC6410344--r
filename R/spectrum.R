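#' Absorption spectrum of a particle
#'
#' Scans the absorption of a particle over a wavelength grid and locates the
#' plasmon peak as the on-grid argmax (no sub-grid interpolation; peak
#' wavelengths are meaningful to the grid spacing, 1 nm by default in the
#' worked examples).
#'
#' @param spec A `particle_spec` (sphere, shell or ellipsoid).
#' @param wavelength_nm Sorted, non-empty wavelength grid, nm.
#' @param kind `"efficiency"` (Qabs, dimensionless; spheres and shells only)
#'   or `"cross_section"` (sigma_abs, nm^2).
#' @param size_correction Apply the gold surface scattering correction
#'   (ignored for ellipsoids).
#' @return A tibble of class `absorption_spectrum` with columns
#'   `wavelength_nm`, `value`, and attributes `kind`, `peak_wavelength_nm`,
#'   `peak_value`.
#' @export
#' @examples
#' sp <- absorption_spectrum(sphere_spec(40), seq(450, 700, 5))
#' peak_wavelength(sp)
absorption_spectrum <- function(spec, wavelength_nm,
                                kind = c("efficiency", "cross_section"),
                                size_correction = TRUE) {
  kind <- match.arg(kind)
  if (length(wavelength_nm) == 0) {
    abort("empty wavelength grid", class = "nanotherm_input_error")
  }
  if (is.unsorted(wavelength_nm, strictly = TRUE)) {
    abort("wavelength grid must be strictly increasing",
          class = "nanotherm_input_error")
  }
  if (inherits(spec, "ellipsoid_spec")) {
    value <- gans_absorption(spec, wavelength_nm)
    kind <- "cross_section"
  } else if (kind == "efficiency") {
    value <- if (inherits(spec, "sphere_spec")) {
      qabs_sphere(spec, wavelength_nm, size_correction)
    } else {
      qabs_shell(spec, wavelength_nm, size_correction)
    }
  } else {
    value <- absorption_cross_section(spec, wavelength_nm, size_correction)
  }
  ipk <- which.max(value)
  out <- tibble(wavelength_nm = wavelength_nm, value = value)
  class(out) <- c("absorption_spectrum", class(out))
  attr(out, "kind") <- kind
  attr(out, "peak_wavelength_nm") <- wavelength_nm[ipk]
  attr(out, "peak_value") <- value[ipk]
  attr(out, "spec") <- spec
  out
}

#' @rdname absorption_spectrum
#' @param x An `absorption_spectrum`.
#' @export
peak_wavelength <- function(x) {
  stopifnot(inherits(x, "absorption_spectrum"))
  attr(x, "peak_wavelength_nm")
}

#' @exportS3Method generics::glance
glance.absorption_spectrum <- function(x, ...) {
  tibble(kind = attr(x, "kind"),
         peak_wavelength_nm = attr(x, "peak_wavelength_nm"),
         peak_value = attr(x, "peak_value"),
         n_wavelengths = nrow(x))
}

#' @exportS3Method ggplot2::autoplot
autoplot.absorption_spectrum <- function(object, ...) {
  ylab <- if (attr(object, "kind") == "efficiency") {
    expression(Q[abs])
  } else {
    expression(sigma[abs] ~ (nm^2))
  }
  ggplot2::ggplot(object, ggplot2::aes(.data$wavelength_nm, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = attr(object, "peak_wavelength_nm"),
                        linetype = "dashed", colour = "grey50") +
    ggplot2::labs(x = "wavelength (nm)", y = ylab)
}

#' Absorption cross section versus sphere diameter
#'
#' Convenience scan used for the size-scaling study: sigma_abs at a fixed
#' wavelength for a set of gold sphere diameters.
#'
#' @param diameters_nm Sphere diameters, nm (default 25 log-spaced points
#'   from 10 to 1000 nm).
#' @param wavelength_nm Fixed wavelength, nm (default 532, the Nd:YAG second
#'   harmonic).
#' @param material,medium Materials.
#' @param size_correction Apply the gold surface scattering correction.
#' @return Tibble `diameter_nm`, `sigma_abs_nm2`.
#' @export
sphere_size_scan <- function(diameters_nm = 10^seq(1, 3, length.out = 25),
                             wavelength_nm = 532, material = "Au",
                             medium = "water", size_correction = TRUE) {
  sigma <- vapply(diameters_nm, function(d) {
    absorption_cross_section(sphere_spec(d, material, medium),
                             wavelength_nm, size_correction)
  }, numeric(1))
  tibble(diameter_nm = diameters_nm, sigma_abs_nm2 = sigma)
}

#' Power-law fit of cross section versus diameter
#'
#' Fits sigma = alpha * d^p by nonlinear least squares on the linear scale
#' (the convention used for the reported size-scaling exponent; the fit is
#' dominated by the largest particles, as when fitting a `y = a*x^b` model to
#' the raw cross sections). An ordinary log-log regression provides the
#' starting values and is available as `scale = "log"`, in which case the
#' exponent reflects all diameters equally.
#'
#' @param data A data frame with the diameters and cross sections (e.g. from
#'   [sphere_size_scan()]).
#' @param diameter,sigma Column names (tidy-eval) holding diameters and
#'   cross sections; defaults match [sphere_size_scan()] output.
#' @param scale `"linear"` (default) or `"log"`.
#' @return An object of class `power_law_fit` with elements `alpha`, `p`,
#'   `scale`, `rms` (residual RMS on the fitted scale) and `data`.
#' @export
#' @examples
#' d <- tibble::tibble(diameter_nm = c(10, 20, 40, 80),
#'                     sigma_abs_nm2 = 2 * c(10, 20, 40, 80)^1.5)
#' fit_power_law(d)$p
fit_power_law <- function(data, diameter = diameter_nm,
                          sigma = sigma_abs_nm2,
                          scale = c("linear", "log")) {
  scale <- match.arg(scale)
  d <- dplyr::pull(data, {{ diameter }})
  s <- dplyr::pull(data, {{ sigma }})
  if (length(d) < 3) {
    abort("need at least 3 points", class = "nanotherm_input_error")
  }
  if (any(d <= 0) || any(s <= 0)) {
    abort("diameters and cross sections must be positive",
          class = "nanotherm_domain_error")
  }
  loglm <- lm(log(s) ~ log(d))
  start <- c(log_alpha = unname(coef(loglm)[1]), p = unname(coef(loglm)[2]))
  if (scale == "log") {
    alpha <- exp(start[["log_alpha"]])
    p <- start[["p"]]
    rms <- sqrt(mean(loglm$residuals^2))
  } else {
    obj <- function(th) {
      pred <- exp(th[1]) * d^th[2]
      sum((pred - s)^2)
    }
    opt <- optim(start, obj, method = "BFGS",
                 control = list(maxit = 1000, reltol = 1e-14))
    alpha <- exp(opt$par[[1]])
    p <- opt$par[[2]]
    rms <- sqrt(opt$value / length(d))
  }
  structure(
    list(alpha = alpha, p = p, scale = scale, rms = rms,
         data = tibble(diameter_nm = d, sigma_abs_nm2 = s)),
    class = "power_law_fit"
  )
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat(sprintf("<power_law_fit> sigma = alpha * d^p: alpha = %.4g, p = %.4g (%s scale, rms %.3g)\n",
              x$alpha, x$p, x$scale, x$rms))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.power_law_fit <- function(x, ...) {
  tibble(term = c("alpha", "p"), estimate = c(x$alpha, x$p))
}

#' @exportS3Method generics::glance
glance.power_law_fit <- function(x, ...) {
  tibble(alpha = x$alpha, p = x$p, scale = x$scale, rms = x$rms,
         nobs = nrow(x$data))
}
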