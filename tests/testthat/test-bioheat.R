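test_that("zero diffusivity leaves the profile unchanged", {
  g <- radial_grid(R_max_m = 5e-3, n_nodes = 81)
  c0 <- gaussian_bolus(g, total_count = 1e9, sigma_m = 0.5e-3)
  res <- solve_np_diffusion(g, c0, D_m2_s = 0, t_end_s = 100, dt_s = 10)
  final <- res$c_per_m3[res$time_s == 100]
  expect_equal(final, c0, tolerance = 1e-12)
})

test_that("diffusion conserves the particle count away from the boundary", {
  g <- radial_grid(R_max_m = 9e-3, n_nodes = 181)
  c0 <- gaussian_bolus(g, total_count = 7e9, sigma_m = 0.5e-3)
  res <- solve_np_diffusion(g, c0, t_end_s = 3600, dt_s = 5)
  tot <- total_particles(res)
  expect_true(all(abs(tot$n_particles / 7e9 - 1) < 1e-3))
})

test_that("a free Gaussian bolus spreads like the heat kernel", {
  g <- radial_grid(R_max_m = 9e-3, n_nodes = 241)
  sigma0 <- 0.5e-3
  N <- 1e10
  D <- np_diffusivity_default()
  c0 <- N / (2 * pi * sigma0^2)^1.5 * exp(-g$r_m^2 / (2 * sigma0^2))
  res <- solve_np_diffusion(g, c0, D_m2_s = D, t_end_s = 3600, dt_s = 2)
  ct <- res$c_per_m3[res$time_s == 3600]
  s2 <- sigma0^2 + 2 * D * 3600
  exact <- N / (2 * pi * s2)^1.5 * exp(-g$r_m^2 / (2 * s2))
  rms <- sqrt(mean((ct - exact)^2)) / max(exact)
  expect_lt(rms, 0.01)
})

test_that("mass-to-number conversion matches the direct formula", {
  # 40 ug/mL of 40 nm gold spheres
  c_direct <- 0.04 / (19300 * 4 / 3 * pi * (20e-9)^3)
  expect_equal(np_number_density(0.04, sphere_spec(40)), c_direct,
               tolerance = 1e-12)
  # shell: silica core + gold layer masses add
  m_shell <- 2200 * 4 / 3 * pi * (10e-9)^3 +
    19300 * 4 / 3 * pi * ((15e-9)^3 - (10e-9)^3)
  expect_equal(np_number_density(0.04, shell_spec(10, 15)), 0.04 / m_shell,
               tolerance = 1e-12)
})

test_that("the laser-nanoparticle source is the direct product", {
  expect_equal(np_heat_source(1e15, 1e-14, 2e5), 2e6)
  expect_equal(np_heat_source(rep(0, 5), 1e-14), rep(0, 5))
  expect_error(np_heat_source(-1, 1e-14), class = "nanotherm_domain_error")
})

test_that("an unheated, non-metabolising domain stays at blood temperature", {
  g <- radial_grid(R_max_m = 6e-3, n_nodes = 61)
  res <- solve_pennes(g, Q = 0, t_end_s = 30, dt_s = 0.5,
                      include_metabolism = FALSE)
  # exact equilibrium up to linear-solver roundoff
  expect_lt(max(abs(res$T_C - 37)), 1e-6)
})

test_that("uniform heating balances perfusion at the analytic steady state", {
  # uniform tissue, insulated boundary: conduction drops out and
  # T_inf = Tb + (Q0 + q_met) / (rho_b cp_b omega_b)
  g <- radial_grid(R_max_m = 6e-3, n_nodes = 61)
  Q0 <- 2e4
  tp <- tissue_properties()
  tumor <- tp[tp$tissue == "tumor", ]
  bl <- blood_reference()
  T_inf <- bl$T_b + (Q0 + tumor$q_met_W_m3) /
    (bl$rho_b * bl$cp_b * tumor$omega_b)
  res <- solve_pennes(g, Q = Q0, t_end_s = 3500, dt_s = 1,
                      surround_tissue = "tumor", boundary = "neumann")
  final <- res$T_C[res$time_s == 3500]
  expect_equal(final, rep(T_inf, g$n), tolerance = 5e-3)
})

test_that("a non-negative source never cools below blood temperature", {
  g <- radial_grid(R_max_m = 6e-3, n_nodes = 81)
  Q <- function(r) 5e5 * exp(-r^2 / (2 * (1e-3)^2))
  res <- solve_pennes(g, Q = Q, t_end_s = 120, dt_s = 0.5)
  expect_true(all(res$T_C >= 37 - 1e-5))
})

test_that("stronger perfusion never raises the peak temperature", {
  g <- radial_grid(R_max_m = 6e-3, n_nodes = 81)
  Q <- function(r) 5e5 * exp(-r^2 / (2 * (1e-3)^2))
  peaks <- vapply(c(1, 2, 4), function(f) {
    tp <- tissue_properties()
    tp$omega_b <- tp$omega_b * f
    res <- solve_pennes(g, Q = Q, t_end_s = 120, dt_s = 0.5, tissues = tp)
    attr(res, "peak")$T_C
  }, numeric(1))
  expect_true(all(diff(peaks) <= 1e-9))
})

test_that("the temperature solution is grid-converged", {
  Q <- function(r) 5e5 * exp(-r^2 / (2 * (1e-3)^2))
  Tc <- vapply(c(81, 161), function(n) {
    g <- radial_grid(R_max_m = 6e-3, n_nodes = n)
    res <- solve_pennes(g, Q = Q, t_end_s = 120, dt_s = 0.5)
    res$T_C[res$time_s == 120 & res$r_m == 0]
  }, numeric(1))
  expect_lt(abs(Tc[2] / Tc[1] - 1), 5e-3)
})

test_that("threshold crossing times are reported where heating is strong", {
  g <- radial_grid(R_max_m = 6e-3, n_nodes = 61)
  Q <- function(r) 2e7 * exp(-r^2 / (2 * (1e-3)^2))
  res <- solve_pennes(g, Q = Q, t_end_s = 300, dt_s = 0.5)
  cr <- attr(res, "crossings")
  center42 <- cr$t_first_s[cr$r_m == 0 & cr$threshold_C == 42]
  expect_false(is.na(center42))
  far42 <- cr$t_first_s[cr$r_m == max(cr$r_m) & cr$threshold_C == 42]
  expect_true(is.na(far42))
})

test_that("grid and parameter validation catches bad setups", {
  expect_error(radial_grid(R_max_m = 2e-3, R_tumor_m = 3e-3),
               class = "nanotherm_domain_error")
  expect_error(radial_grid(n_nodes = 10), class = "nanotherm_domain_error")
  g <- radial_grid(R_max_m = 6e-3, n_nodes = 61)
  expect_error(solve_pennes(g, surround_tissue = "bone"),
               class = "nanotherm_validation_error")
  expect_error(solve_np_diffusion(g, rep(-1, g$n)),
               class = "nanotherm_domain_error")
})
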