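# End-to-end pipeline: spectrum -> peak -> injection & diffusion -> bioheat
# -> cell death -> tumor course.

#' Pipeline configuration
#'
#' Assembles and validates the configuration for [run_np_pipeline()]. All
#' stages are derivable from this object; a YAML file with the same field
#' names can be loaded with [read_pipeline_config()].
#'
#' @param particle A `particle_spec` (default the 30 nm silica-core /
#'   gold-shell particle used in the worked example).
#' @param wavelength_nm Spectrum grid, nm.
#' @param mass_conc_kg_m3 Injected nanoparticle mass concentration
#'   (default 0.04 = 40 ug/mL).
#' @param diffusion_time_s Time between injection and heating, s.
#' @param bolus_sigma_m Width of the Gaussian injection bolus, m.
#' @param grid A [radial_grid()].
#' @param surround_tissue Healthy tissue outside the tumor.
#' @param irradiance_W_m2 Laser irradiance (default 20 W/cm^2).
#' @param heat_time_s Laser heating duration, s.
#' @param death A [death_model_params()].
#' @param schedule A [treatment_schedule()].
#' @param growth A [growth_params()].
#' @param V0_mm3 Initial tumor volume, mm^3.
#' @param seed RNG seed recorded in the run summary (the default pipeline
#'   is deterministic; the seed feeds any fitting stages).
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(particle = shell_spec(10, 15),
                            wavelength_nm = seq(450, 800, by = 1),
                            mass_conc_kg_m3 = 0.04,
                            diffusion_time_s = 3600,
                            bolus_sigma_m = 0.5e-3,
                            grid = radial_grid(),
                            surround_tissue = "muscle",
                            irradiance_W_m2 = 20e4,
                            heat_time_s = 600,
                            death = death_model_params("melanoma"),
                            schedule = melanoma_schedule(),
                            growth = growth_params("melanoma"),
                            V0_mm3 = tumor_volume_mm3(3),
                            seed = 1) {
  cfg <- list(particle = particle, wavelength_nm = wavelength_nm,
              mass_conc_kg_m3 = mass_conc_kg_m3,
              diffusion_time_s = diffusion_time_s,
              bolus_sigma_m = bolus_sigma_m, grid = grid,
              surround_tissue = surround_tissue,
              irradiance_W_m2 = irradiance_W_m2, heat_time_s = heat_time_s,
              death = death, schedule = schedule, growth = growth,
              V0_mm3 = V0_mm3, seed = seed)
  stopifnot(inherits(particle, "particle_spec"),
            inherits(grid, "radial_grid"),
            inherits(death, "death_model_params"),
            inherits(schedule, "treatment_schedule"),
            inherits(growth, "growth_params"))
  if (V0_mm3 <= 0 || mass_conc_kg_m3 < 0 || irradiance_W_m2 < 0 ||
      heat_time_s <= 0 || diffusion_time_s < 0) {
    abort("invalid pipeline configuration", class = "nanotherm_validation_error")
  }
  structure(cfg, class = "pipeline_config")
}

#' Load a pipeline configuration from YAML
#'
#' Field names mirror [pipeline_config()]; the particle is given as a list
#' with `type: sphere|shell` and its dimensions, the schedule as
#' `session_days`, `temperature_C`, `heat_min`, `slow_h`, the death and
#' growth models by `cancer_type` / `variant`.
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  # [[ with exact names throughout: $ would partially match, e.g.
  # particle$core against core_radius_nm
  p <- y[["particle"]]
  particle <- if (!is.null(p)) {
    if (identical(p[["type"]], "sphere")) {
      sphere_spec(p[["diameter_nm"]],
                  p[["material"]] %||% "Au",
                  p[["medium"]] %||% "water")
    } else {
      shell_spec(p[["core_radius_nm"]], p[["outer_radius_nm"]],
                 p[["core"]] %||% "SiO2", p[["shell"]] %||% "Au",
                 p[["medium"]] %||% "water")
    }
  } else {
    shell_spec(10, 15)
  }
  g <- y[["grid"]]
  grid <- if (!is.null(g)) {
    radial_grid(g[["R_max_m"]] %||% 9e-3, g[["R_tumor_m"]] %||% 3e-3,
                g[["n_nodes"]] %||% 181)
  } else {
    radial_grid()
  }
  s <- y[["schedule"]]
  schedule <- if (!is.null(s)) {
    treatment_schedule(unlist(s[["session_days"]]),
                       s[["temperature_C"]] %||% 48,
                       s[["heat_min"]] %||% 30,
                       s[["slow_h"]] %||% 48)
  } else {
    melanoma_schedule()
  }
  w <- y[["wavelength_nm"]]
  wl <- if (!is.null(w)) {
    seq(w[["from"]], w[["to"]], by = w[["by"]] %||% 1)
  } else {
    seq(450, 800, by = 1)
  }
  pipeline_config(
    particle = particle, wavelength_nm = wl,
    mass_conc_kg_m3 = y[["mass_conc_kg_m3"]] %||% 0.04,
    diffusion_time_s = y[["diffusion_time_s"]] %||% 3600,
    bolus_sigma_m = y[["bolus_sigma_m"]] %||% 0.5e-3,
    grid = grid,
    surround_tissue = y[["surround_tissue"]] %||% "muscle",
    irradiance_W_m2 = y[["irradiance_W_m2"]] %||% 20e4,
    heat_time_s = y[["heat_time_s"]] %||% 600,
    death = death_model_params(y[["death_cancer_type"]] %||% "melanoma"),
    schedule = schedule,
    growth = growth_params(y[["growth_variant"]] %||% "melanoma"),
    V0_mm3 = y[["V0_mm3"]] %||% tumor_volume_mm3(3),
    seed = y[["seed"]] %||% 1)
}

#' Run the nanoparticle-induced hyperthermia pipeline
#'
#' Executes, in order: (1) absorption spectrum of the configured particle
#' and its plasmon peak; (2) conversion of the injected mass concentration
#' to a particle number density and diffusion of a central Gaussian bolus;
#' (3) the Pennes bioheat solve with the laser/nanoparticle source built
#' from the diffused concentration and the cross section *at the spectrum
#' peak*; (4) the three-state cell death model over the treatment schedule
#' coupled to (5) exponential growth, yielding the tumor-volume trajectory.
#' Stage failures abort with the failing stage named; outputs computed so
#' far are retained in the error condition.
#'
#' @param config A [pipeline_config()].
#' @param output_dir Optional directory; when given, stage outputs are
#'   written as CSV plus a JSON run summary.
#' @return Object of class `pipeline_result`: list with `spectrum`,
#'   `peak_wavelength_nm`, `sigma_abs_m2`, `concentration`, `temperature`,
#'   `course`, `summary` (a one-row tibble) and the resolved `config`.
#' @export
#' @examples
#' \donttest{
#' cfg <- pipeline_config(wavelength_nm = seq(500, 700, by = 5),
#'                        grid = radial_grid(n_nodes = 61),
#'                        heat_time_s = 60, diffusion_time_s = 600)
#' res <- run_np_pipeline(cfg)
#' res$summary
#' }
run_np_pipeline <- function(config = pipeline_config(), output_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  done <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name,
                    conditionMessage(e)),
            class = "nanotherm_pipeline_error", partial = done)
    })
  }
  spectrum <- stage("spectrum", absorption_spectrum(
    config$particle, config$wavelength_nm, kind = "cross_section"))
  done$spectrum <- spectrum
  peak_nm <- peak_wavelength(spectrum)
  sigma_abs_m2 <- attr(spectrum, "peak_value") * 1e-18
  conc <- stage("diffusion", {
    n_dens <- np_number_density(config$mass_conc_kg_m3, config$particle)
    tumor_vol_m3 <- 4 / 3 * pi * config$grid$R_tumor_m^3
    c0 <- gaussian_bolus(config$grid, total_count = n_dens * tumor_vol_m3,
                         sigma_m = config$bolus_sigma_m)
    solve_np_diffusion(config$grid, c0, t_end_s = config$diffusion_time_s)
  })
  done$concentration <- conc
  temperature <- stage("bioheat", {
    c_final <- conc$c_per_m3[conc$time_s == max(conc$time_s)]
    Q <- np_heat_source(c_final, sigma_abs_m2, config$irradiance_W_m2)
    solve_pennes(config$grid, Q = Q, t_end_s = config$heat_time_s,
                 surround_tissue = config$surround_tissue)
  })
  done$temperature <- temperature
  course <- stage("course", simulate_course(
    config$V0_mm3, config$schedule, config$growth, config$death))
  done$course <- course
  ses <- session_summary(course)
  summary <- tibble(
    peak_wavelength_nm = peak_nm,
    sigma_abs_nm2 = attr(spectrum, "peak_value"),
    peak_T_C = attr(temperature, "peak")$T_C,
    mean_kill_fraction = if (nrow(ses)) mean(ses$kill_fraction) else NA_real_,
    final_volume_mm3 = course$volume_mm3[nrow(course)],
    seed = config$seed)
  res <- structure(
    list(spectrum = spectrum, peak_wavelength_nm = peak_nm,
         sigma_abs_m2 = sigma_abs_m2, concentration = conc,
         temperature = temperature, course = course, summary = summary,
         sessions = ses, config = config),
    class = "pipeline_result")
  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(as.data.frame(spectrum),
              file.path(output_dir, "spectrum.csv"), row.names = FALSE)
    write.csv(as.data.frame(conc),
              file.path(output_dir, "concentration.csv"), row.names = FALSE)
    write.csv(as.data.frame(temperature),
              file.path(output_dir, "temperature.csv"), row.names = FALSE)
    write.csv(as.data.frame(course),
              file.path(output_dir, "course.csv"), row.names = FALSE)
    jsonlite::write_json(as.list(summary),
                         file.path(output_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  res
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  print(x$summary)
  invisible(x)
}
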