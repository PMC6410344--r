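test_that("closed-form growth behaves as expected", {
  g0 <- growth_params(a0 = 0)
  expect_equal(grow(50, g0, c(0, 5, 20)), rep(50, 3))
  mel <- growth_params("melanoma")
  expect_equal(grow(100, mel, log(2) / mel$a0), 200, tolerance = 1e-12)
  expect_equal(log(2) / mel$a0, 2.1133, tolerance = 1e-3)
  expect_error(grow(-1, mel, 1), class = "nanotherm_domain_error")
})

test_that("the reference tumor volume is the 3 mm sphere", {
  expect_equal(tumor_volume_mm3(3), 4 / 3 * pi * 27, tolerance = 1e-12)
})

test_that("session kill composes the fast and slow oracle trajectories", {
  ses <- apply_session(100, death_model_params("melanoma"), 48,
                       heat_min = 30, slow_h = 48)
  expect_equal(ses$D_fast, fast_oracle_melanoma[["D"]], tolerance = 1e-5)
  expect_equal(ses$kill_fraction, slow_oracle_melanoma_session,
               tolerance = 1e-5)
  expect_equal(ses$V_post_mm3, 100 * (1 - ses$kill_fraction),
               tolerance = 1e-12)
})

test_that("an untreated session leaves the volume unchanged", {
  ses <- apply_session(80, death_model_params("melanoma"), 37,
                       heat_min = 0, slow_h = 24,
                       init = c(A = 1, V = 0, D = 0))
  expect_equal(ses$kill_fraction, 0, tolerance = 1e-10)
  expect_equal(ses$V_post_mm3, 80, tolerance = 1e-8)
})

test_that("the viable-fraction floor keeps regrowth defined", {
  ses <- apply_session(100, death_model_params("melanoma"), 48,
                       heat_min = 30, slow_h = 48, viable_floor = 0.5)
  expect_gt(ses$kill_fraction, 0.5)        # floor binds
  expect_equal(ses$V_post_mm3, 50)
})

test_that("an empty schedule reduces to pure exponential growth", {
  sched <- treatment_schedule(numeric(), temperature_C = 48)
  tr <- simulate_course(113.1, sched, growth_params("melanoma"),
                        death_model_params("melanoma"), t_end_day = 10)
  expect_equal(tr$volume_mm3, 113.1 * exp(0.328 * tr$day), tolerance = 1e-12)
})

test_that("between-session segments follow the closed form exactly", {
  tr <- simulate_course(113.1, melanoma_schedule(),
                        growth_params("melanoma"),
                        death_model_params("melanoma"))
  seg <- tr[tr$phase == "growth" & tr$day >= 2 & tr$day <= 4, ]
  expect_equal(seg$volume_mm3,
               seg$volume_mm3[1] * exp(0.328 * (seg$day - seg$day[1])),
               tolerance = 1e-12)
})

test_that("the melanoma course is a sawtooth with net shrinkage", {
  tr <- simulate_course(113.1, melanoma_schedule(),
                        growth_params("melanoma"),
                        death_model_params("melanoma"))
  ses <- session_summary(tr)
  expect_equal(nrow(ses), 7)
  # each session shrinks the tumor, regrowth raises it again
  expect_true(all(ses$V_post_mm3 < ses$V_pre_mm3))
  expect_true(all(ses$V_pre_mm3[-1] > ses$V_post_mm3[-7]))
  # per-session kill exceeds the regrowth balance point, so the course
  # shrinks overall
  expect_lt(tr$volume_mm3[nrow(tr)], 113.1)
  expect_true(all(tr$volume_mm3 > 0))
})

test_that("net shrinkage flips at the kill-regrowth balance point", {
  # fixed kill fraction k* ~ 0.917 per session; growth wins iff
  # 1 - exp(-a0 dt_regrow) exceeds it
  sched <- melanoma_schedule()
  death <- death_model_params("melanoma")
  slow_a <- simulate_course(113.1, sched, growth_params(a0 = 0.05), death)
  expect_lt(slow_a$volume_mm3[nrow(slow_a)], 113.1)
  fast_a <- simulate_course(113.1, sched, growth_params(a0 = 1.6), death)
  expect_gt(fast_a$volume_mm3[nrow(fast_a)], 113.1)
})

test_that("HSP90 inhibition dominates the untreated growth variant", {
  sched <- melanoma_schedule()
  death <- death_model_params("melanoma")
  tr_m <- simulate_course(113.1, sched, growth_params("melanoma"), death)
  tr_h <- simulate_course(113.1, sched, growth_params("melanoma_hsp90i"),
                          death)
  # compare daily envelopes (session days carry both a pre- and a
  # post-treatment volume, which must not be cross-matched)
  env <- function(tr) {
    dplyr::summarise(dplyr::group_by(tr, day),
                     lo = min(volume_mm3), hi = max(volume_mm3),
                     .groups = "drop")
  }
  j <- dplyr::inner_join(env(tr_m), env(tr_h), by = "day",
                         suffix = c("_m", "_h"))
  expect_true(all(j$hi_h <= j$hi_m + 1e-9))
  expect_true(all(j$lo_h <= j$lo_m + 1e-9))
  expect_lt(tr_h$volume_mm3[nrow(tr_h)], tr_m$volume_mm3[nrow(tr_m)])
})

test_that("the prostate schedule truncates the first slow-death window", {
  tr <- simulate_course(113.1, prostate_schedule(),
                        growth_params("prostate"),
                        death_model_params("prostate"))
  ses <- session_summary(tr)
  expect_equal(ses$slow_h, c(48, 48, 48))   # gaps are 2 and 4 days
  expect_equal(nrow(ses), 3)
})

test_that("overlapping windows error when truncation is disabled", {
  sched <- treatment_schedule(c(0, 1), temperature_C = 48)
  expect_error(
    simulate_course(113.1, sched, growth_params("melanoma"),
                    death_model_params("melanoma"),
                    truncate_windows = FALSE),
    class = "nanotherm_schedule_error")
})

test_that("schedule validation rejects unordered sessions", {
  expect_error(treatment_schedule(c(4, 0), 48),
               class = "nanotherm_schedule_error")
  expect_error(treatment_schedule(0, 48, heat_min = -5),
               class = "nanotherm_schedule_error")
})
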