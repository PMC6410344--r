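test_that("lossless particles do not absorb", {
  silica <- sphere_spec(100, material = "SiO2")
  expect_true(all(abs(qabs_sphere(silica, c(450, 600, 800))) < 1e-10))
})

test_that("small spheres follow the Rayleigh dipole limit", {
  # closed-form small-particle oracle: Qabs = 4 x Im[(m^2-1)/(m^2+2)]
  for (wl in c(480, 532, 600)) {
    spec <- sphere_spec(2)
    eps <- bulk_dielectric("Au", wl)
    nm <- 1.33
    m2 <- eps / nm^2
    x <- 2 * pi * 1 * nm / wl
    q_ray <- 4 * x * Im((m2 - 1) / (m2 + 2))
    q_mie <- qabs_sphere(spec, wl, size_correction = FALSE)
    expect_equal(q_mie, q_ray, tolerance = 1e-2)
  }
})

test_that("sphere efficiencies match an independent Mie implementation", {
  for (i in seq_len(nrow(mie_sphere_oracle))) {
    q <- qabs_sphere(sphere_spec(mie_sphere_oracle$d[i]),
                     mie_sphere_oracle$lambda[i], size_correction = FALSE)
    expect_equal(q, mie_sphere_oracle$qabs[i], tolerance = 1e-6)
  }
})

test_that("shell efficiency matches the frozen reference", {
  expect_equal(qabs_shell(shell_spec(10, 15), 590), shell_oracle_590,
               tolerance = 1e-6)
})

test_that("a degenerate shell equals the solid sphere", {
  wl <- seq(450, 700, by = 25)
  q_sphere <- qabs_sphere(sphere_spec(40), wl, size_correction = FALSE)
  q_shell <- qabs_shell(shell_spec(10, 20, core = "Au", shell = "Au"),
                        wl, size_correction = FALSE)
  expect_equal(q_shell, q_sphere, tolerance = 1e-8)
  # vanishing core: gold shell around a point core is a solid gold sphere
  q_tiny_core <- qabs_shell(shell_spec(1e-3, 20, core = "Au", shell = "Au"),
                            wl, size_correction = FALSE)
  expect_equal(q_tiny_core, q_sphere, tolerance = 1e-4)
})

test_that("the Mie series is converged at the default truncation", {
  for (d in c(40, 300, 1000)) {
    for (wl in c(450, 700)) {
      spec <- sphere_spec(d)
      c0 <- mie_coefficients(spec, wl)
      x2 <- attr(c0, "x2")
      nmax <- max(c0$order)
      c5 <- mie_coefficients(spec, wl, nmax = nmax + 5L)
      expect_lt(abs(attr(c5, "qabs") - attr(c0, "qabs")), 1e-8)
      expect_lte(x2, 20)
    }
  }
})

test_that("absorption never exceeds extinction", {
  for (d in c(20, 100, 500)) {
    co <- mie_coefficients(sphere_spec(d), 532)
    expect_lte(attr(co, "qabs"), attr(co, "qext") + 1e-12)
    expect_gte(attr(co, "qabs"), 0)
  }
  co <- mie_coefficients(shell_spec(10, 15), 600)
  expect_lte(attr(co, "qabs"), attr(co, "qext") + 1e-12)
})

test_that("solid-sphere coefficients have vanishing shell auxiliaries", {
  co <- mie_coefficients(sphere_spec(40), 532)
  expect_true(all(co$An == 0) && all(co$Bn == 0))
  expect_true(all(is.finite(Mod(co$an))) && all(is.finite(Mod(co$bn))))
})

test_that("spectrum scans find on-grid peaks and validate input", {
  sp <- absorption_spectrum(sphere_spec(40), 532)
  expect_equal(peak_wavelength(sp), 532)
  expect_error(absorption_spectrum(sphere_spec(40), numeric()),
               class = "nanotherm_input_error")
  expect_error(absorption_spectrum(sphere_spec(40), c(500, 480)),
               class = "nanotherm_input_error")
  expect_true(all(sp$value >= -1e-8))
})

test_that("gold sphere absorption stays strongest near 500 nm across sizes", {
  grid <- seq(450, 700, by = 2)
  # distinct plasmon peak for small and intermediate spheres
  for (d in c(10, 50, 100, 200)) {
    pk <- peak_wavelength(absorption_spectrum(sphere_spec(d), grid))
    expect_gte(pk, 480)
    expect_lte(pk, 620)
  }
  # very large spheres lose the distinct resonance (the spectrum decays
  # from the blue edge), but the 500 nm region still dominates the red end
  for (d in c(400, 1000)) {
    sp <- absorption_spectrum(sphere_spec(d), grid)
    q500 <- sp$value[sp$wavelength_nm == 500]
    q700 <- sp$value[sp$wavelength_nm == 700]
    expect_gt(q500, 1.5 * q700)
  }
})

test_that("thinner gold shells are red-shifted", {
  grid <- seq(450, 900, by = 2)
  thick <- c(10, 8, 6, 4, 2)           # 30 nm outer diameter throughout
  peaks <- vapply(thick, function(t) {
    peak_wavelength(absorption_spectrum(shell_spec(15 - t, 15), grid))
  }, numeric(1))
  expect_true(all(diff(peaks) > 0))
})

test_that("geometry validation rejects impossible shells", {
  expect_error(shell_spec(20, 10), class = "nanotherm_geometry_error")
  expect_error(sphere_spec(-5), class = "nanotherm_domain_error")
})
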