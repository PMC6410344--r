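# Nanoparticle diffusion and Pennes bioheat transfer on a radially
# symmetric spherical domain (tumor core + surrounding healthy tissue).
#
# Numerics: method-of-lines finite volume on a uniform radial grid; faces at
# cell midpoints, symmetry (zero flux) at r = 0, implicit Euler stepping
# (unconditionally stable) with the constant system matrix factorised once.

#' Thermal and transport properties of tissues
#'
#' Per-tissue Pennes parameters: specific heat capacity `cp` (J/kg/degC),
#' density `rho` (kg/m^3), thermal conductivity `k` (W/m/degC), blood
#' perfusion rate `omega_b` (1/s, volumetric perfusion per tissue volume)
#' and metabolic heat `q_met_W_m3` (W/m^3, used directly as a volumetric
#' source; the tabulated magnitudes, 464--1200, are physical only as
#' volumetric rates -- as per-mass rates they would imply a baseline tissue
#' temperature over a hundred degrees above arterial blood). The
#' nanoparticle diffusivity (6.2e-11 m^2/s, tabulated for epidermis) is
#' adopted as the default diffusivity for all tissues. The tumor and muscle
#' rows share the same values.
#'
#' @return Tibble, one row per tissue.
#' @export
tissue_properties <- function() {
  tibble(
    tissue  = c("blood", "dermis", "epidermis", "fat", "tumor", "muscle"),
    cp      = c(3617, 3300, 3590, 2348, 3421, 3421),
    rho     = c(1050, 1200, 1200, 911, 1090, 1090),
    k       = c(0.52, 0.45, 0.23, 0.21, 0.49, 0.49),
    omega_b = c(NA, 1.25e-3, 0, 1.25e-3, 1.65e-3, 1.65e-3),
    q_met_W_m3 = c(1090, 1200, 1200, 464, 991, 991)
  )
}

#' @rdname tissue_properties
#' @export
blood_reference <- function() {
  list(rho_b = 1050, cp_b = 3617, T_b = 37)
}

#' Default nanoparticle diffusivity in tissue, m^2/s
#' @export
np_diffusivity_default <- function() 6.2e-11

#' Uniform radial grid
#'
#' @param R_max_m Domain radius, m.
#' @param R_tumor_m Tumor radius, m (default 3 mm; must be < `R_max_m`).
#' @param n_nodes Number of nodes including r = 0 and r = R_max (>= 50).
#' @return Object of class `radial_grid`: list with node radii `r_m`,
#'   spacing `dr_m`, `R_tumor_m` and per-node cell volumes `cell_volume_m3`.
#' @export
radial_grid <- function(R_max_m = 9e-3, R_tumor_m = 3e-3, n_nodes = 181) {
  if (R_tumor_m >= R_max_m) {
    abort("R_tumor_m must be < R_max_m", class = "nanotherm_domain_error")
  }
  if (n_nodes < 50) {
    abort("need at least 50 nodes", class = "nanotherm_domain_error")
  }
  r <- seq(0, R_max_m, length.out = n_nodes)
  dr <- r[2] - r[1]
  rf <- c(0, r[-n_nodes] + dr / 2, R_max_m)   # cell faces
  vol <- 4 / 3 * pi * (rf[-1]^3 - rf[-(n_nodes + 1)]^3)
  structure(list(r_m = r, dr_m = dr, R_tumor_m = R_tumor_m,
                 cell_volume_m3 = vol, n = n_nodes),
            class = "radial_grid")
}

# Tridiagonal diffusion operator (negative divergence of k grad, divided by
# cell volume) for a per-node conductivity; harmonic mean at faces.
# Returns face conductances G (length n-1) and cell volumes.
.radial_conductances <- function(grid, k_node) {
  n <- grid$n
  r <- grid$r_m
  dr <- grid$dr_m
  rf <- r[-n] + dr / 2                       # interior faces
  ksum <- k_node[-n] + k_node[-1]
  kf <- ifelse(ksum > 0, 2 * k_node[-n] * k_node[-1] / ksum, 0)
  kf * 4 * pi * rf^2 / dr
}

# Build and factorise the implicit-Euler system matrix
#   (cap/dt + L + sink) x_new = cap/dt x_old + rhs
# cap, sink: per-node (volumetric) coefficients; dirichlet_last: replace the
# outermost row by identity.
.radial_system <- function(grid, cap, k_node, sink, dt, dirichlet_last) {
  n <- grid$n
  G <- .radial_conductances(grid, k_node)
  V <- grid$cell_volume_m3
  lower <- -G / V[-1]
  upper <- -G / V[-n]
  diagv <- cap / dt + sink
  diagv[1] <- diagv[1] + G[1] / V[1]
  if (n > 2) {
    diagv[2:(n - 1)] <- diagv[2:(n - 1)] + (G[-(n - 1)] + G[-1]) / V[2:(n - 1)]
  }
  diagv[n] <- diagv[n] + G[n - 1] / V[n]
  if (dirichlet_last) {
    diagv[n] <- 1
    lower[n - 1] <- 0
    upper[n - 1] <- upper[n - 1]  # upper affects row n-1; leave as is
  }
  A <- Matrix::bandSparse(n, n, k = c(-1, 0, 1),
                          diagonals = list(lower, diagv, upper))
  Matrix::lu(A)
}

#' Solve radial nanoparticle diffusion
#'
#' Transient diffusion dc/dt = div(D grad c) + R_gen on the radial grid,
#' zero flux at r = 0 and an absorbing far boundary (c = 0 at R_max).
#' Implicit Euler stepping; the finite-volume discretisation conserves the
#' total particle number exactly until the diffusion front reaches the
#' outer boundary.
#'
#' @param grid A [radial_grid()].
#' @param c0 Initial concentration: numeric vector (1/m^3, one per node) or
#'   a function of radius.
#' @param D_m2_s Diffusivity, m^2/s (>= 0).
#' @param t_end_s End time, s.
#' @param dt_s Time step, s.
#' @param R_gen Volumetric generation rate, 1/m^3/s (default 0).
#' @param snapshot_every_s Interval between stored profiles (default 10
#'   snapshots across the run).
#' @return Object of class `concentration_field`: tibble `time_s`, `r_m`,
#'   `c_per_m3` with the grid and parameters as attributes.
#' @export
solve_np_diffusion <- function(grid, c0, D_m2_s = np_diffusivity_default(),
                               t_end_s = 3600, dt_s = 5, R_gen = 0,
                               snapshot_every_s = NULL) {
  stopifnot(inherits(grid, "radial_grid"))
  if (D_m2_s < 0) abort("D must be >= 0", class = "nanotherm_domain_error")
  cvec <- if (is.function(c0)) c0(grid$r_m) else c0
  stopifnot(length(cvec) == grid$n)
  if (any(cvec < 0)) {
    abort("initial concentration must be non-negative",
          class = "nanotherm_domain_error")
  }
  nstep <- max(1L, ceiling(t_end_s / dt_s))
  dt <- t_end_s / nstep
  snapshot_every_s <- snapshot_every_s %||% (t_end_s / 10)
  keep_every <- max(1L, round(snapshot_every_s / dt))
  fac <- .radial_system(grid, cap = rep(1, grid$n),
                        k_node = rep(D_m2_s, grid$n),
                        sink = rep(0, grid$n), dt = dt,
                        dirichlet_last = TRUE)
  snaps <- list(`0` = cvec)
  x <- cvec
  for (s in seq_len(nstep)) {
    b <- x / dt + R_gen
    b[grid$n] <- 0                       # Dirichlet c = 0 at R_max
    x <- as.numeric(Matrix::solve(fac, b))
    x[x < 0 & x > -1e-12 * max(abs(x))] <- 0   # clip roundoff undershoot
    if (s %% keep_every == 0 || s == nstep) {
      snaps[[sprintf("%.10g", s * dt)]] <- x
    }
  }
  out <- purrr::imap_dfr(snaps, function(v, tm) {
    tibble(time_s = as.numeric(tm), r_m = grid$r_m, c_per_m3 = v)
  })
  class(out) <- c("concentration_field", class(out))
  attr(out, "grid") <- grid
  attr(out, "D_m2_s") <- D_m2_s
  out
}

#' Total particle count of a concentration profile
#'
#' Integrates c(r) over the spherical cells of the grid.
#'
#' @param field A `concentration_field`.
#' @param time_s Which snapshot (default: all, returned as a tibble).
#' @return Tibble `time_s`, `n_particles`.
#' @export
total_particles <- function(field, time_s = NULL) {
  grid <- attr(field, "grid")
  dat <- if (is.null(time_s)) field else
    dplyr::filter(field, .data$time_s %in% !!time_s)
  dat |>
    dplyr::group_by(.data$time_s) |>
    dplyr::summarise(
      n_particles = sum(.data$c_per_m3 * grid$cell_volume_m3),
      .groups = "drop")
}

#' Gaussian injection bolus
#'
#' Initial nanoparticle profile for a central injection: isotropic Gaussian
#' centred at r = 0 with standard deviation `sigma_m`, scaled so the total
#' particle count equals `total_count`.
#'
#' @param grid A [radial_grid()].
#' @param total_count Total number of particles.
#' @param sigma_m Gaussian width, m (default 0.5 mm).
#' @return Numeric vector of concentrations, 1/m^3.
#' @export
gaussian_bolus <- function(grid, total_count, sigma_m = 0.5e-3) {
  c_raw <- exp(-grid$r_m^2 / (2 * sigma_m^2))
  c_raw * total_count / sum(c_raw * grid$cell_volume_m3)
}

#' Nanoparticle mass concentration to number density
#'
#' Converts a mass concentration (e.g. 40 ug/mL = 0.04 kg/m^3) into a
#' particle number density using the particle mass implied by its geometry:
#' gold density 19300 kg/m^3 and silica density 2200 kg/m^3.
#'
#' @param mass_conc_kg_m3 Mass concentration, kg/m^3 (40 ug/mL = 0.04).
#' @param spec A [sphere_spec()] or [shell_spec()].
#' @return Number density, 1/m^3.
#' @export
#' @examples
#' np_number_density(0.04, sphere_spec(40))
np_number_density <- function(mass_conc_kg_m3, spec) {
  rho <- c(Au = 19300, SiO2 = 2200, water = 1000, TiO2 = 4230)
  vol_nm3 <- function(R) 4 / 3 * pi * R^3
  mass_kg <- if (inherits(spec, "sphere_spec")) {
    rho[[spec$material$name]] * vol_nm3(spec$diameter_nm / 2) * 1e-27
  } else if (inherits(spec, "shell_spec")) {
    (rho[[spec$core$name]] * vol_nm3(spec$core_radius_nm) +
       rho[[spec$shell$name]] * (vol_nm3(spec$outer_radius_nm) -
                                   vol_nm3(spec$core_radius_nm))) * 1e-27
  } else {
    abort("need a sphere_spec or shell_spec", class = "nanotherm_error")
  }
  mass_conc_kg_m3 / mass_kg
}

#' Volumetric heat source from laser-illuminated nanoparticles
#'
#' Q(r) = c(r) * sigma_abs * I: local particle number density times
#' per-particle absorption cross section times irradiance. Beam attenuation
#' through the tissue is neglected (the source is proportional to the local
#' concentration only), so deposited power is an upper bound.
#'
#' @param c_per_m3 Number density profile, 1/m^3.
#' @param sigma_abs_m2 Per-particle absorption cross section, m^2
#'   (1 nm^2 = 1e-18 m^2).
#' @param irradiance_W_m2 Laser irradiance, W/m^2 (default 20 W/cm^2).
#' @return Volumetric power density Q(r), W/m^3.
#' @export
np_heat_source <- function(c_per_m3, sigma_abs_m2,
                           irradiance_W_m2 = 20e4) {
  if (any(c_per_m3 < 0) || sigma_abs_m2 < 0 || irradiance_W_m2 < 0) {
    abort("concentration, cross section and irradiance must be >= 0",
          class = "nanotherm_domain_error")
  }
  c_per_m3 * sigma_abs_m2 * irradiance_W_m2
}

#' Solve the Pennes bioheat equation on the radial grid
#'
#' Transient Pennes equation
#'   rho Cp dT/dt = div(k grad T) + Q + rho_b Cp_b omega_b (T_b - T)
#'                  + q_met,
#' with tumor properties for r <= R_tumor and a configurable healthy tissue
#' outside, symmetry at r = 0 and either a fixed far boundary T = T_b
#' (default) or an insulated (Neumann) far boundary. Time stepping is
#' implicit Euler with a fixed step.
#'
#' @param grid A [radial_grid()].
#' @param Q Volumetric heat source: numeric vector (W/m^3 per node), single
#'   number, or function of radius.
#' @param t_end_s Heating duration, s.
#' @param tumor_tissue,surround_tissue Tissue names from
#'   [tissue_properties()].
#' @param dt_s Time step, s (default 0.1).
#' @param boundary `"dirichlet"` (T = T_b at R_max) or `"neumann"`
#'   (insulated).
#' @param include_metabolism Include the metabolic source term?
#' @param thresholds_C Damage thresholds whose first crossing times are
#'   reported (default 42, 47, 50 degC: hyperthermia range and ablation
#'   onset).
#' @param snapshot_every_s Interval between stored profiles.
#' @param tissues,blood Property tables, overridable for sensitivity runs.
#' @return Object of class `temperature_field`: tibble `time_s`, `r_m`,
#'   `T_C`, with attributes `grid`, `crossings` (tibble `r_m`,
#'   `threshold_C`, `t_first_s`) and `peak` (list: maximum temperature and
#'   where/when).
#' @export
solve_pennes <- function(grid, Q = 0, t_end_s = 600,
                         tumor_tissue = "tumor",
                         surround_tissue = "muscle",
                         dt_s = 0.1,
                         boundary = c("dirichlet", "neumann"),
                         include_metabolism = TRUE,
                         thresholds_C = c(42, 47, 50),
                         snapshot_every_s = NULL,
                         tissues = tissue_properties(),
                         blood = blood_reference()) {
  stopifnot(inherits(grid, "radial_grid"))
  boundary <- match.arg(boundary)
  n <- grid$n
  tumor_row <- tissues[tissues$tissue == tumor_tissue, ]
  sur_row <- tissues[tissues$tissue == surround_tissue, ]
  if (nrow(tumor_row) != 1 || nrow(sur_row) != 1) {
    abort("unknown tissue name", class = "nanotherm_validation_error")
  }
  in_tumor <- grid$r_m <= grid$R_tumor_m
  pick <- function(col) ifelse(in_tumor, tumor_row[[col]], sur_row[[col]])
  rho <- pick("rho"); cp <- pick("cp"); kk <- pick("k")
  wb <- pick("omega_b"); qmet <- pick("q_met_W_m3")
  if (any(!is.finite(c(rho, cp, kk, wb, qmet))) ||
      any(c(rho, cp, kk) <= 0) || any(wb < 0)) {
    abort("non-physical tissue parameters", class = "nanotherm_validation_error")
  }
  Qv <- if (is.function(Q)) Q(grid$r_m) else rep_len(Q, n)
  Tb <- blood$T_b
  cap <- rho * cp
  sink <- blood$rho_b * blood$cp_b * wb
  src <- Qv + sink * Tb + if (include_metabolism) qmet else 0
  nstep <- max(1L, ceiling(t_end_s / dt_s))
  dt <- t_end_s / nstep
  snapshot_every_s <- snapshot_every_s %||% (t_end_s / 10)
  keep_every <- max(1L, round(snapshot_every_s / dt))
  dir_last <- boundary == "dirichlet"
  fac <- .radial_system(grid, cap = cap, k_node = kk, sink = sink, dt = dt,
                        dirichlet_last = dir_last)
  x <- rep(Tb, n)
  snaps <- list(`0` = x)
  t_first <- matrix(NA_real_, nrow = n, ncol = length(thresholds_C))
  for (s in seq_len(nstep)) {
    b <- cap / dt * x + src
    if (dir_last) b[n] <- Tb
    x <- as.numeric(Matrix::solve(fac, b))
    for (j in seq_along(thresholds_C)) {
      hit <- is.na(t_first[, j]) & x >= thresholds_C[j]
      t_first[hit, j] <- s * dt
    }
    if (s %% keep_every == 0 || s == nstep) {
      snaps[[sprintf("%.10g", s * dt)]] <- x
    }
  }
  out <- purrr::imap_dfr(snaps, function(v, tm) {
    tibble(time_s = as.numeric(tm), r_m = grid$r_m, T_C = v)
  })
  class(out) <- c("temperature_field", class(out))
  attr(out, "grid") <- grid
  cross <- tidyr::expand_grid(r_m = grid$r_m, threshold_C = thresholds_C)
  cross$t_first_s <- as.vector(t(t_first))
  attr(out, "crossings") <- as_tibble(cross)
  ipk <- which.max(out$T_C)
  attr(out, "peak") <- list(T_C = out$T_C[ipk], r_m = out$r_m[ipk],
                            time_s = out$time_s[ipk])
  out
}

#' @exportS3Method generics::glance
glance.temperature_field <- function(x, ...) {
  pk <- attr(x, "peak")
  tibble(peak_T_C = pk$T_C, peak_r_m = pk$r_m, peak_time_s = pk$time_s)
}

#' @exportS3Method ggplot2::autoplot
autoplot.temperature_field <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(.data$r_m * 1e3, .data$T_C,
                               colour = .data$time_s,
                               group = .data$time_s)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "radius (mm)", y = "temperature (°C)",
                  colour = "time (s)")
}

#' @exportS3Method ggplot2::autoplot
autoplot.concentration_field <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(.data$r_m * 1e3, .data$c_per_m3,
                               colour = .data$time_s,
                               group = .data$time_s)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "radius (mm)", y = expression(c ~ (m^-3)),
                  colour = "time (s)")
}
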