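# Tumor growth and multi-session treatment-course simulation.
#
# Between treatment sessions the tumor grows exponentially, V(t) = V0
# exp(a0 t), evaluated in closed form (no integrator drift). Each session
# applies fast death during heating followed by slow death over a
# post-treatment window, with growth suspended during that window; the
# session multiplies the volume by the surviving viable fraction.
#
# Note on units of the growth rate: the calibrated magnitudes (0.328, 0.237,
# 0.243) are used as per-DAY rates. Taken per second they would imply a
# tumor doubling time of about two seconds, which is incompatible with the
# multi-day growth curves the model was calibrated against.

#' Tumor growth parameters
#'
#' Exponential growth rates per variant: `melanoma` (a0 = 0.328/day),
#' `melanoma_hsp90i` (0.237/day; growth under pharmacological HSP90
#' inhibition, the only place the inhibitor enters the model) and
#' `prostate` (0.243/day).
#'
#' @param variant One of `"melanoma"`, `"melanoma_hsp90i"`, `"prostate"`,
#'   or `NULL` with an explicit `a0`.
#' @param a0 Growth rate, 1/day (>= 0).
#' @return Object of class `growth_params`.
#' @export
#' @examples
#' log(2) / growth_params("melanoma")$a0   # doubling time, days
growth_params <- function(variant = NULL, a0 = NULL) {
  rates <- c(melanoma = 0.328, melanoma_hsp90i = 0.237, prostate = 0.243)
  if (!is.null(variant)) {
    if (!variant %in% names(rates)) {
      abort("unknown growth variant", class = "nanotherm_error")
    }
    a0 <- rates[[variant]]
  } else {
    variant <- "custom"
    if (is.null(a0)) abort("a0 required", class = "nanotherm_input_error")
  }
  if (a0 < 0) abort("a0 must be >= 0", class = "nanotherm_domain_error")
  structure(list(variant = variant, a0 = a0), class = "growth_params")
}

#' Exponential tumor growth, closed form
#'
#' @param V0_mm3 Initial volume, mm^3 (> 0).
#' @param params A [growth_params()] (or a bare rate via `a0`).
#' @param t_days Time(s), days.
#' @return Volume(s), mm^3.
#' @export
grow <- function(V0_mm3, params, t_days) {
  if (any(V0_mm3 <= 0)) {
    abort("V0 must be > 0", class = "nanotherm_domain_error")
  }
  if (any(t_days < 0)) {
    abort("t must be >= 0", class = "nanotherm_domain_error")
  }
  a0 <- if (inherits(params, "growth_params")) params$a0 else params
  V0_mm3 * exp(a0 * t_days)
}

#' Default initial tumor volume, mm^3
#'
#' Volume of the reference spherical tumor of radius 3 mm:
#' 4/3 pi 3^3 = 113.1 mm^3.
#'
#' @param radius_mm Tumor radius, mm.
#' @export
#' @examples
#' tumor_volume_mm3(3)
tumor_volume_mm3 <- function(radius_mm = 3) {
  4 / 3 * pi * radius_mm^3
}

#' Treatment schedule
#'
#' @param session_days Session start days, strictly increasing.
#' @param temperature_C Per-session heating temperature, degC (recycled).
#' @param heat_min Heating duration, minutes (recycled).
#' @param slow_h Post-treatment slow-death window, hours (recycled;
#'   truncated to the inter-session gap when that is shorter).
#' @param cancer_type Label used to pick defaults elsewhere.
#' @return Tibble of class `treatment_schedule`.
#' @export
treatment_schedule <- function(session_days, temperature_C, heat_min = 30,
                               slow_h = 48, cancer_type = "custom") {
  if (length(session_days) && is.unsorted(session_days, strictly = TRUE)) {
    abort("session days must be strictly increasing",
          class = "nanotherm_schedule_error")
  }
  if (any(heat_min <= 0) || any(slow_h < 0)) {
    abort("durations must be positive", class = "nanotherm_schedule_error")
  }
  out <- tibble(day = session_days,
                temperature_C = rep_len(temperature_C,
                                        length(session_days)),
                heat_min = rep_len(heat_min, length(session_days)),
                slow_h = rep_len(slow_h, length(session_days)))
  class(out) <- c("treatment_schedule", class(out))
  attr(out, "cancer_type") <- cancer_type
  out
}

#' @rdname treatment_schedule
#' @details `melanoma_schedule()`: seven sessions every 4 days at 48 degC,
#'   30 min heating, 48 h slow death. `prostate_schedule()`: sessions on
#'   days 0, 2 and 6 at 50 degC, 15 min heating (the 48 h window is
#'   truncated to 2 days between the first two sessions).
#' @export
melanoma_schedule <- function() {
  treatment_schedule(seq(0, 24, by = 4), temperature_C = 48, heat_min = 30,
                     slow_h = 48, cancer_type = "melanoma")
}

#' @rdname treatment_schedule
#' @export
prostate_schedule <- function() {
  treatment_schedule(c(0, 2, 6), temperature_C = 50, heat_min = 15,
                     slow_h = 48, cancer_type = "prostate")
}

#' Apply one hyperthermia session to a tumor volume
#'
#' Runs the fast-death model at the session temperature for the heating
#' duration, continues with slow death over the post-treatment window, and
#' couples the final dead fraction to volume as V_post = V_pre (1 -
#' D_final) (the proportional viable-volume rule; `coupling =
#' "alive_fraction"` uses V_post = V_pre * A_final instead). A small
#' viable-fraction floor keeps regrowth defined when the kill fraction
#' reaches 1.
#'
#' The slow phase has no vulnerable state (cells are either dead or not),
#' so the fraction vulnerable at the end of heating must be assigned: by
#' default (`slow_from = "non_alive"`) vulnerable cells are counted as
#' committed to apoptotic death and the slow phase starts from D0 = 1 -
#' A_fast; `slow_from = "dead_only"` starts from D_fast and lets
#' vulnerable cells recover.
#'
#' @param V_pre_mm3 Pre-session volume, mm^3.
#' @param death_params A [death_model_params()].
#' @param temperature_C Heating temperature, degC.
#' @param heat_min Heating duration, minutes.
#' @param slow_h Slow-death window, hours.
#' @param coupling Volume coupling rule.
#' @param slow_from Hand-off from the fast to the slow phase (see Details).
#' @param viable_floor Minimum surviving fraction (default 1e-6).
#' @param init Initial state for the fast phase.
#' @return List: `V_post_mm3`, `kill_fraction` (D after the slow window),
#'   `D_fast` (D at end of heating), `fast` and `slow` trajectories.
#' @export
apply_session <- function(V_pre_mm3, death_params, temperature_C,
                          heat_min = 30, slow_h = 48,
                          coupling = c("viable_volume", "alive_fraction"),
                          slow_from = c("non_alive", "dead_only"),
                          viable_floor = 1e-6,
                          init = c(A = 1 - 1e-3, V = 1e-3, D = 0)) {
  coupling <- match.arg(coupling)
  slow_from <- match.arg(slow_from)
  if (V_pre_mm3 <= 0) {
    abort("V_pre must be > 0", class = "nanotherm_domain_error")
  }
  if (heat_min > 0) {
    fast <- fast_death(death_params, temperature_C, heat_min, init = init)
    A_f <- fast$A[nrow(fast)]
    D_f <- fast$D[nrow(fast)]
  } else {
    fast <- NULL
    A_f <- init[[1]]
    D_f <- init[[3]]
  }
  D0_slow <- if (slow_from == "non_alive") 1 - A_f else D_f
  if (slow_h > 0) {
    slow <- slow_death(death_params, D0 = D0_slow, t_end_h = slow_h)
    D_end <- slow$D[nrow(slow)]
  } else {
    slow <- NULL
    D_end <- D0_slow
  }
  surviving <- if (coupling == "viable_volume") 1 - D_end else A_f
  surviving <- max(surviving, viable_floor)
  list(V_post_mm3 = V_pre_mm3 * surviving,
       kill_fraction = D_end, D_fast = D_f,
       fast = fast, slow = slow)
}

#' Simulate a multi-session treatment course
#'
#' Alternates closed-form exponential growth with treatment sessions.
#' During each session's slow-death window growth is suspended and the
#' volume declines as V_pre (1 - D(t)); between windows the trajectory
#' follows V exp(a0 t) exactly. Sessions whose slow-death window would
#' overlap the next session are truncated to the inter-session gap.
#'
#' @param V0_mm3 Initial volume, mm^3 (default 113.1, a 3 mm radius
#'   sphere).
#' @param schedule A [treatment_schedule()].
#' @param growth A [growth_params()].
#' @param death A [death_model_params()].
#' @param t_end_day End of the simulated course, days (default: 4 days
#'   after the last session, or 28 for an empty schedule).
#' @param dt_day Output resolution of the daily trajectory, days.
#' @param truncate_windows Truncate a slow-death window that would overlap
#'   the next session to the inter-session gap (default); with `FALSE`
#'   an overlap is a scheduling error.
#' @param ... Passed to [apply_session()].
#' @return Object of class `tumor_trajectory`: tibble `day`, `volume_mm3`,
#'   `phase` (`"growth"` or `"treatment"`), with a per-session summary
#'   tibble (`day`, `V_pre_mm3`, `V_post_mm3`, `kill_fraction`) in
#'   attribute `sessions`.
#' @export
#' @examples
#' tr <- simulate_course(113.1, melanoma_schedule(),
#'                       growth_params("melanoma"),
#'                       death_model_params("melanoma"))
#' glance(tr)
simulate_course <- function(V0_mm3 = tumor_volume_mm3(3), schedule,
                            growth, death, t_end_day = NULL,
                            dt_day = 0.25, truncate_windows = TRUE, ...) {
  stopifnot(inherits(schedule, "treatment_schedule"),
            inherits(growth, "growth_params"))
  if (V0_mm3 <= 0) abort("V0 must be > 0", class = "nanotherm_domain_error")
  nses <- nrow(schedule)
  t_end_day <- t_end_day %||% if (nses) max(schedule$day) + 4 else 28
  grow_seg <- function(t0, V, t1) {
    if (t1 <= t0) return(tibble(day = numeric(), volume_mm3 = numeric(),
                                phase = character()))
    tt <- unique(c(seq(t0, t1, by = dt_day), t1))
    tibble(day = tt, volume_mm3 = grow(V, growth, tt - t0),
           phase = "growth")
  }
  segs <- list()
  sessions <- list()
  t_cur <- 0
  V_cur <- V0_mm3
  for (i in seq_len(nses)) {
    d <- schedule$day[i]
    if (d < t_cur) {
      abort(sprintf(
        "session %d at day %g starts inside the previous slow-death window",
        i, d), class = "nanotherm_schedule_error")
    }
    segs <- c(segs, list(grow_seg(t_cur, V_cur, d)))
    V_pre <- grow(V_cur, growth, d - t_cur)
    gap_h <- if (i < nses) (schedule$day[i + 1] - d) * 24 else Inf
    if (!truncate_windows && schedule$slow_h[i] > gap_h) {
      abort(sprintf(
        "slow-death window of session %d (%g h) overlaps the next session",
        i, schedule$slow_h[i]), class = "nanotherm_schedule_error")
    }
    slow_h <- min(schedule$slow_h[i], gap_h)
    ses <- apply_session(V_pre, death, schedule$temperature_C[i],
                         heat_min = schedule$heat_min[i],
                         slow_h = slow_h, ...)
    # volume during the slow window: V_pre * (1 - D(t)), growth suspended
    if (!is.null(ses$slow)) {
      win <- tibble(day = d + ses$slow$time_h / 24,
                    volume_mm3 = pmax(V_pre * (1 - ses$slow$D),
                                      ses$V_post_mm3),
                    phase = "treatment")
      win$volume_mm3[nrow(win)] <- ses$V_post_mm3
      segs <- c(segs, list(win))
      t_cur <- d + slow_h / 24
    } else {
      t_cur <- d
    }
    V_cur <- ses$V_post_mm3
    sessions <- c(sessions, list(tibble(
      session = i, day = d, V_pre_mm3 = V_pre, V_post_mm3 = ses$V_post_mm3,
      kill_fraction = ses$kill_fraction, slow_h = slow_h)))
  }
  segs <- c(segs, list(grow_seg(t_cur, V_cur, t_end_day)))
  out <- dplyr::bind_rows(segs)
  out <- dplyr::distinct(out, .data$day, .data$volume_mm3, .keep_all = TRUE)
  class(out) <- c("tumor_trajectory", class(out))
  attr(out, "sessions") <- dplyr::bind_rows(sessions)
  attr(out, "growth") <- growth
  attr(out, "V0_mm3") <- V0_mm3
  out
}

#' @rdname simulate_course
#' @param x A `tumor_trajectory`.
#' @export
session_summary <- function(x) {
  stopifnot(inherits(x, "tumor_trajectory"))
  attr(x, "sessions")
}

#' @exportS3Method generics::glance
glance.tumor_trajectory <- function(x, ...) {
  ses <- attr(x, "sessions")
  tibble(V0_mm3 = attr(x, "V0_mm3"),
         final_volume_mm3 = x$volume_mm3[nrow(x)],
         final_day = x$day[nrow(x)],
         n_sessions = if (is.null(ses)) 0L else nrow(ses),
         mean_kill_fraction = if (is.null(ses) || !nrow(ses)) NA_real_
                              else mean(ses$kill_fraction))
}

#' @exportS3Method ggplot2::autoplot
autoplot.tumor_trajectory <- function(object, ...) {
  ses <- attr(object, "sessions")
  p <- ggplot2::ggplot(object,
                       ggplot2::aes(.data$day, .data$volume_mm3)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "day", y = expression(V ~ (mm^3)))
  if (!is.null(ses) && nrow(ses)) {
    p <- p + ggplot2::geom_vline(xintercept = ses$day, linetype = "dotted",
                                 colour = "grey60")
  }
  p
}

#' Growth rate recovery from a volume time series
#'
#' Log-linear least squares: log V = log V0 + a0 t. The natural estimator
#' for multiplicative (log-normal) volume noise.
#'
#' @param data Data frame with columns `day` and `volume_mm3`.
#' @return Object of class `growth_fit` with `a0` (1/day), `V0_mm3` and the
#'   underlying `lm` fit.
#' @export
fit_growth_rate <- function(data) {
  if (any(data$volume_mm3 <= 0)) {
    abort("volumes must be positive", class = "nanotherm_domain_error")
  }
  fit <- lm(log(volume_mm3) ~ day, data = data)
  structure(list(a0 = unname(coef(fit)[2]),
                 V0_mm3 = exp(unname(coef(fit)[1])), lm = fit),
            class = "growth_fit")
}

#' @export
print.growth_fit <- function(x, ...) {
  cat(sprintf("<growth_fit> a0 = %.4g /day, V0 = %.4g mm^3\n",
              x$a0, x$V0_mm3))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.growth_fit <- function(x, ...) {
  tibble(term = c("a0", "V0_mm3"), estimate = c(x$a0, x$V0_mm3))
}

#' @exportS3Method generics::glance
glance.growth_fit <- function(x, ...) {
  s <- summary(x$lm)
  tibble(a0 = x$a0, V0_mm3 = x$V0_mm3, r_squared = s$r.squared,
         sigma = s$sigma, nobs = length(s$residuals))
}
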