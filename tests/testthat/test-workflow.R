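# A single small end-to-end run shared by the assertions below.
small_config <- function(schedule = treatment_schedule(c(0, 4), 48,
                                                       heat_min = 30,
                                                       slow_h = 48)) {
  pipeline_config(
    particle = shell_spec(10, 15),
    wavelength_nm = seq(480, 700, by = 2),
    grid = radial_grid(R_max_m = 9e-3, n_nodes = 91),
    diffusion_time_s = 1200,
    heat_time_s = 300,
    schedule = schedule)
}

test_that("the pipeline is deterministic and internally consistent", {
  res1 <- run_np_pipeline(small_config())
  res2 <- run_np_pipeline(small_config())
  expect_identical(res1$summary, res2$summary)
  # the cross section fed to the heat stage is the spectrum's own peak
  expect_equal(res1$sigma_abs_m2,
               max(res1$spectrum$value) * 1e-18, tolerance = 1e-12)
  expect_equal(res1$peak_wavelength_nm,
               res1$spectrum$wavelength_nm[which.max(res1$spectrum$value)])
  # summary fields are all populated
  expect_true(all(is.finite(unlist(res1$summary))))
})

test_that("nanoparticle heating exceeds damage thresholds inside the tumor", {
  res <- run_np_pipeline(small_config())
  temp <- res$temperature
  final <- temp[temp$time_s == max(temp$time_s), ]
  T_tumor_max <- max(final$T_C[final$r_m <= 3e-3])
  T_far <- final$T_C[which.min(abs(final$r_m - 6e-3))]
  expect_gt(T_tumor_max, 47)
  expect_gt(T_tumor_max, T_far)
  # temperature decays toward baseline with radius
  expect_lt(T_far, T_tumor_max)
  expect_gte(min(final$T_C), 37 - 1e-6)
})

test_that("an empty schedule reduces the course to pure growth", {
  cfg <- small_config(schedule = treatment_schedule(numeric(), 48))
  res <- run_np_pipeline(cfg)
  course <- res$course
  t_end <- course$day[nrow(course)]
  expect_equal(res$summary$final_volume_mm3,
               tumor_volume_mm3(3) * exp(0.328 * t_end), tolerance = 1e-10)
})

test_that("pipeline outputs are written when a directory is given", {
  out <- file.path(tempdir(), "nanotherm-run")
  on.exit(unlink(out, recursive = TRUE))
  res <- run_np_pipeline(small_config(
    schedule = treatment_schedule(0, 48)), output_dir = out)
  expect_true(all(file.exists(file.path(
    out, c("spectrum.csv", "concentration.csv", "temperature.csv",
           "course.csv", "summary.json")))))
  js <- jsonlite::read_json(file.path(out, "summary.json"))
  expect_equal(js$final_volume_mm3, res$summary$final_volume_mm3,
               tolerance = 1e-8)
})

test_that("YAML configurations round-trip through the reader", {
  path <- tempfile(fileext = ".yaml")
  on.exit(unlink(path))
  writeLines(c(
    "particle:",
    "  type: sphere",
    "  diameter_nm: 40",
    "wavelength_nm: {from: 450, to: 700, by: 5}",
    "heat_time_s: 120",
    "schedule:",
    "  session_days: [0, 4]",
    "  temperature_C: 48",
    "growth_variant: melanoma_hsp90i",
    "V0_mm3: 100"), path)
  cfg <- read_pipeline_config(path)
  expect_s3_class(cfg$particle, "sphere_spec")
  expect_equal(cfg$particle$diameter_nm, 40)
  expect_equal(cfg$V0_mm3, 100)
  expect_equal(cfg$growth$a0, 0.237)
  expect_equal(range(cfg$wavelength_nm), c(450, 700))
  expect_equal(cfg$schedule$day, c(0, 4))

  # shell config: core/core_radius_nm keys must not be confused
  path2 <- tempfile(fileext = ".yaml")
  on.exit(unlink(path2), add = TRUE)
  writeLines(c(
    "particle:",
    "  type: shell",
    "  core_radius_nm: 10",
    "  outer_radius_nm: 15",
    "grid: {n_nodes: 61}"), path2)
  cfg2 <- read_pipeline_config(path2)
  expect_s3_class(cfg2$particle, "shell_spec")
  expect_equal(cfg2$particle$core_radius_nm, 10)
  expect_equal(cfg2$particle$core$name, "SiO2")
  expect_equal(cfg2$grid$n, 61)
})
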