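# Three-state (alive / vulnerable / dead) hyperthermic cell-death kinetics.
#
# Fast death (during heating):
#   dA/dt = -kf A + kb (1 - A - D),  dD/dt = kf (1 - A - D),
#   kf = kf_bar * exp(T / Tk) * (1 - A)
# V is recovered algebraically from A + V + D = 1 (never integrated, so
# conservation is exact by construction). Slow death (post-treatment,
# kf = kb = 0):
#   dD/dt = ks (1 - D),  ks = ks_bar * D (1 - D) (D - D_tau)^2
# Temperatures are in degrees Celsius (the exponential scale Tk is tabulated
# in degC); fast-phase rates are per minute, slow-phase rates per hour.

#' Cell-death model parameters
#'
#' Calibrated three-state model parameters per cancer type. Melanoma
#' (calibrated at 48 degC) and prostate (50 degC) fast-phase parameters are
#' literature-calibrated; the prostate slow-phase entries were published
#' without supporting data and are flagged `provenance = "unverified"`.
#'
#' @param cancer_type `"melanoma"` or `"prostate"`, or `NULL` to build a
#'   custom set from the remaining arguments.
#' @param kf_bar Fast-death scaling constant, 1/min.
#' @param kb Backward (recovery) rate, 1/min.
#' @param Tk Exponential temperature scale, degC.
#' @param ks_bar Slow-death scaling constant, 1/h.
#' @param D_tau Slow-death threshold (fraction, in \[0, 1)).
#' @return Object of class `death_model_params`.
#' @export
#' @examples
#' death_model_params("melanoma")
death_model_params <- function(cancer_type = NULL, kf_bar = NULL, kb = NULL,
                               Tk = NULL, ks_bar = NULL, D_tau = NULL) {
  defaults <- list(
    melanoma = list(kf_bar = 0.25481, kb = 0.66477, Tk = 40.1513,
                    ks_bar = 0.59547, D_tau = 0.45003e-3,
                    reference_T_C = 48, provenance = "calibrated"),
    prostate = list(kf_bar = 0.18946, kb = 0.23063, Tk = 39.678,
                    ks_bar = 0.316e-3, D_tau = 0.208,
                    reference_T_C = 50, provenance = "unverified (slow phase)")
  )
  p <- if (!is.null(cancer_type)) {
    if (!cancer_type %in% names(defaults)) {
      abort("cancer_type must be 'melanoma' or 'prostate'",
            class = "nanotherm_error")
    }
    defaults[[cancer_type]]
  } else {
    list(kf_bar = kf_bar, kb = kb, Tk = Tk, ks_bar = ks_bar, D_tau = D_tau,
         reference_T_C = NA_real_, provenance = "user")
  }
  for (f in c("kf_bar", "kb", "Tk", "ks_bar", "D_tau")) {
    if (!is.null(cancer_type)) next
    p[[f]] <- p[[f]] %||% 0
  }
  if (any(unlist(p[c("kf_bar", "kb", "Tk", "ks_bar")]) < 0) ||
      p$D_tau < 0 || p$D_tau >= 1) {
    abort("rates must be >= 0 and D_tau in [0, 1)",
          class = "nanotherm_domain_error")
  }
  p$cancer_type <- cancer_type %||% "custom"
  structure(p, class = "death_model_params")
}

#' @export
print.death_model_params <- function(x, ...) {
  cat(sprintf(
    "<death_model_params> %s: kf_bar = %g /min, kb = %g /min, Tk = %g degC, ks_bar = %g /h, D_tau = %g (%s)\n",
    x$cancer_type, x$kf_bar, x$kb, x$Tk, x$ks_bar, x$D_tau, x$provenance))
  invisible(x)
}

.check_init <- function(init) {
  if (length(init) != 3 || any(init < 0) || any(init > 1) ||
      abs(sum(init) - 1) > 1e-8) {
    abort("initial state (A0, V0, D0) must be fractions summing to 1",
          class = "nanotherm_validation_error")
  }
}

#' Fast (necrotic) cell death during heating
#'
#' Integrates the fast-death equations at a constant temperature or along a
#' supplied temperature history. Because A = 1 is a fixed point of the
#' self-catalytic forward rate kf = kf_bar exp(T/Tk)(1 - A), the default
#' initial state seeds a small vulnerable fraction (A0 = 1 - 1e-3).
#'
#' @param params A [death_model_params()].
#' @param temperature_C Constant temperature (degC) or a function of time
#'   (minutes) returning degC.
#' @param duration_min Heating duration, minutes.
#' @param init Initial state `c(A, V, D)`, fractions summing to 1.
#' @param times_min Output time grid, minutes (default 200 points).
#' @param rtol,atol Integrator tolerances (lsoda).
#' @return Object of class `cell_state_trajectory`: tibble `time_min`, `A`,
#'   `V`, `D` with the parameters and design stored as attributes.
#' @export
#' @examples
#' traj <- fast_death(death_model_params("melanoma"), 48, 30)
#' tail(traj, 1)
fast_death <- function(params, temperature_C, duration_min,
                       init = c(A = 1 - 1e-3, V = 1e-3, D = 0),
                       times_min = NULL, rtol = 1e-10, atol = 1e-12) {
  stopifnot(inherits(params, "death_model_params"))
  .check_init(init)
  Tfun <- if (is.function(temperature_C)) temperature_C else
    function(t) temperature_C
  times <- times_min %||% seq(0, duration_min, length.out = 201)
  deriv <- function(t, y, parms) {
    A <- y[1]; D <- y[2]
    kf <- params$kf_bar * exp(Tfun(t) / params$Tk) * (1 - A)
    V <- 1 - A - D
    list(c(-kf * A + params$kb * V, kf * V))
  }
  sol <- deSolve::ode(y = c(A = init[[1]], D = init[[3]]), times = times,
                      func = deriv, parms = NULL, method = "lsoda",
                      rtol = rtol, atol = atol)
  out <- tibble(time_min = sol[, "time"],
                A = pmin(pmax(sol[, "A"], 0), 1),
                D = pmin(pmax(sol[, "D"], 0), 1))
  out$V <- pmin(pmax(1 - out$A - out$D, 0), 1)
  out <- out[, c("time_min", "A", "V", "D")]
  class(out) <- c("cell_state_trajectory", class(out))
  attr(out, "params") <- params
  attr(out, "mode") <- "fast"
  attr(out, "init") <- init
  attr(out, "temperature_C") <- if (is.function(temperature_C))
    "time-varying" else temperature_C
  out
}

#' Slow (apoptotic) cell death after treatment
#'
#' Integrates dD/dt = ks_bar D (1 - D)^2 (D - D_tau)^2 from the dead
#' fraction left by the fast phase. D = 0 and D = 1 are fixed points; the
#' trajectory is monotone non-decreasing in between.
#'
#' @param params A [death_model_params()].
#' @param D0 Initial dead fraction, in \[0, 1\].
#' @param t_end_h Duration, hours (default 48).
#' @param times_h Output grid, hours.
#' @inheritParams fast_death
#' @return Object of class `cell_state_trajectory`: tibble `time_h`, `A`,
#'   `V`, `D` (with A = 1 - D, V = 0: no vulnerable phase in slow death).
#' @export
slow_death <- function(params, D0, t_end_h = 48, times_h = NULL,
                       rtol = 1e-10, atol = 1e-12) {
  stopifnot(inherits(params, "death_model_params"))
  if (D0 < 0 || D0 > 1) {
    abort("D0 must be in [0, 1]", class = "nanotherm_domain_error")
  }
  times <- times_h %||% seq(0, t_end_h, length.out = 201)
  deriv <- function(t, y, parms) {
    D <- y[1]
    ks <- params$ks_bar * D * (1 - D) * (D - params$D_tau)^2
    list(ks * (1 - D))
  }
  sol <- deSolve::ode(y = c(D = D0), times = times, func = deriv,
                      parms = NULL, method = "lsoda",
                      rtol = rtol, atol = atol)
  D <- pmin(pmax(sol[, "D"], 0), 1)
  out <- tibble(time_h = sol[, "time"], A = 1 - D, V = 0, D = D)
  class(out) <- c("cell_state_trajectory", class(out))
  attr(out, "params") <- params
  attr(out, "mode") <- "slow"
  out
}

#' @exportS3Method ggplot2::autoplot
autoplot.cell_state_trajectory <- function(object, ...) {
  tcol <- if ("time_min" %in% names(object)) "time_min" else "time_h"
  xlab <- if (tcol == "time_min") "time (min)" else "time (h)"
  long <- tidyr::pivot_longer(object, c("A", "V", "D"),
                              names_to = "state", values_to = "fraction")
  ggplot2::ggplot(long, ggplot2::aes(.data[[tcol]], .data$fraction,
                                     colour = .data$state)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = xlab, y = "fraction")
}

# model survival curve evaluated at observation times, for fitting.
# fast mode target: surviving fraction = A(t); slow: 1 - D(t).
.death_model_curve <- function(theta, mode, times, temperature_C,
                               init, rtol) {
  p <- if (mode == "fast") {
    death_model_params(kf_bar = theta[1], kb = theta[2], Tk = theta[3])
  } else {
    death_model_params(ks_bar = theta[1], D_tau = theta[2], Tk = 40)
  }
  if (mode == "fast") {
    tr <- fast_death(p, temperature_C, max(times),
                     init = init, times_min = sort(unique(c(0, times))),
                     rtol = rtol, atol = rtol * 1e-2)
    tr$A[match(times, tr$time_min)]
  } else {
    tr <- slow_death(p, D0 = init, t_end_h = max(times),
                     times_h = sort(unique(c(0, times))),
                     rtol = rtol, atol = rtol * 1e-2)
    1 - tr$D[match(times, tr$time_h)]
  }
}

#' Fit cell-death parameters to viability data
#'
#' Bound-constrained least squares (Levenberg--Marquardt on the residuals,
#' rates on the log scale) between the model survival curve and observed
#' surviving fractions, with multistart initialisation: starting points are
#' drawn log-uniformly within the bounds for rates and uniformly for
#' `D_tau`. Fast mode fits against A(t), slow mode against 1 - D(t).
#'
#' At a single heating temperature the scaling constant and the
#' temperature scale are not separately identifiable -- the data constrain
#' only the effective forward rate b = kf_bar exp(T/Tk). Fast-mode fits on
#' single-temperature data therefore estimate (b, kb) with `Tk` held at
#' `Tk_fixed`, and report kf_bar = b exp(-T/Tk_fixed); when the data span
#' several temperatures all three of (kf_bar, kb, Tk) are free. The fitted
#' curve, not the parameter vector, is the reproducible quantity.
#'
#' @param data Data frame with columns `time` (minutes for fast mode, hours
#'   for slow), `temperature_C` (fast mode) and `survival` (fractions).
#' @param mode `"fast"` or `"slow"`.
#' @param lower,upper Named bounds for the free parameters; defaults:
#'   rates in \[1e-4, 10\], `Tk` in \[30, 60\] degC, `D_tau` in
#'   \[1e-6, 0.999\].
#' @param n_starts Number of multistart draws (default 20).
#' @param seed Seed for the start draws (mandatory for reproducibility).
#' @param init Fast mode: initial state as in [fast_death()]. Slow mode:
#'   initial dead fraction D0 (default 1 - first observed survival).
#' @param Tk_fixed Temperature scale used (and reported) when fitting
#'   single-temperature fast-mode data, degC.
#' @param rtol Integrator tolerance used inside the objective.
#' @return Object of class `death_fit`: list with `params` (best-fit
#'   [death_model_params()]), `objective` (sum of squared residuals),
#'   `mode`, `starts` (per-start tibble), `fitted` (model curve at the
#'   observation times) and `data`.
#' @export
fit_death_params <- function(data, mode = c("fast", "slow"),
                             lower = NULL, upper = NULL,
                             n_starts = 20, seed,
                             init = NULL, Tk_fixed = 40, rtol = 1e-6) {
  mode <- match.arg(mode)
  if (missing(seed)) abort("seed is required", class = "nanotherm_input_error")
  if (nrow(data) == 0) {
    abort("empty dataset", class = "nanotherm_input_error")
  }
  need <- if (mode == "fast") 4 else 3
  if (nrow(data) < need) {
    abort(sprintf("need >= %d observations for %s mode", need, mode),
          class = "nanotherm_input_error")
  }
  times <- data$time
  surv <- data$survival
  stopifnot(all(surv >= 0 & surv <= 1), all(times >= 0), !is.unsorted(times))
  multi_T <- FALSE
  if (mode == "fast") {
    temps <- unique(data$temperature_C)
    multi_T <- length(temps) > 1
    temperature_C <- temps[1]
    init <- init %||% c(A = 1 - 1e-3, V = 1e-3, D = 0)
    lower <- lower %||% if (multi_T) {
      c(kf_bar = 1e-4, kb = 1e-4, Tk = 30)
    } else {
      c(kf_bar = 1e-4, kb = 1e-4)
    }
    upper <- upper %||% if (multi_T) {
      c(kf_bar = 10, kb = 10, Tk = 60)
    } else {
      c(kf_bar = 10, kb = 10)
    }
    is_rate <- c(TRUE, TRUE, FALSE)[seq_along(lower)]
  } else {
    temperature_C <- NA_real_
    init <- init %||% (1 - surv[1])
    lower <- lower %||% c(ks_bar = 1e-4, D_tau = 1e-6)
    upper <- upper %||% c(ks_bar = 10, D_tau = 0.999)
    is_rate <- c(TRUE, FALSE)
  }
  theta_full <- function(th) {
    # th on the natural scale -> (kf_bar, kb, Tk) / (ks_bar, D_tau)
    if (mode == "fast" && !multi_T) c(th, Tk_fixed) else th
  }
  residual <- function(theta) {
    if (mode == "fast" && multi_T) {
      unlist(lapply(temps, function(tc) {
        sel <- data$temperature_C == tc
        .death_model_curve(theta, mode, times[sel], tc, init, rtol) -
          surv[sel]
      }))
    } else {
      .death_model_curve(theta, mode, times, temperature_C, init, rtol) -
        surv
    }
  }
  to_internal <- function(th) ifelse(is_rate, log(th), th)
  to_natural <- function(th) ifelse(is_rate, exp(th), th)
  resid_int <- function(th_int) {
    r <- tryCatch(residual(theta_full(to_natural(th_int))),
                  error = function(e) NULL)
    if (is.null(r) || any(!is.finite(r))) rep(1e3, length(times)) else r
  }
  k <- length(lower)
  # starts are drawn from a moderate rate range (clipped to the bounds):
  # at extreme rates the predicted survival is flat (identically ~1 or
  # ~0), the residual Jacobian vanishes and every local method stalls
  start_lo <- ifelse(is_rate, pmax(lower, 0.02), lower)
  start_hi <- ifelse(is_rate, pmin(upper, 2), upper)
  starts <- .with_seed(seed, purrr::map(seq_len(n_starts), function(i) {
    th <- numeric(k)
    for (j in seq_len(k)) {
      th[j] <- if (is_rate[j]) {
        exp(runif(1, log(start_lo[j]), log(start_hi[j])))
      } else {
        runif(1, start_lo[j], start_hi[j])
      }
    }
    setNames(th, names(lower))
  }))
  runs <- purrr::map_dfr(seq_along(starts), function(i) {
    fit <- tryCatch(
      minpack.lm::nls.lm(
        to_internal(starts[[i]]), fn = resid_int,
        lower = to_internal(lower), upper = to_internal(upper),
        control = minpack.lm::nls.lm.control(maxiter = 300)),
      error = function(e) NULL)
    if (is.null(fit)) {
      return(tibble(start = i, objective = NA_real_,
                    par = list(starts[[i]]), converged = FALSE))
    }
    tibble(start = i, objective = sum(fit$fvec^2),
           par = list(setNames(to_natural(fit$par), names(lower))),
           converged = fit$info %in% 1:4)
  })
  ok <- runs[!is.na(runs$objective), ]
  if (nrow(ok) == 0) {
    abort("all optimisation starts failed", class = "nanotherm_optim_error")
  }
  best <- theta_full(ok$par[[which.min(ok$objective)]])
  params <- if (mode == "fast") {
    death_model_params(kf_bar = best[[1]], kb = best[[2]], Tk = best[[3]])
  } else {
    death_model_params(ks_bar = best[[1]], D_tau = best[[2]])
  }
  fitted <- if (mode == "fast" && multi_T) {
    unlist(lapply(temps, function(tc) {
      sel <- data$temperature_C == tc
      .death_model_curve(best, mode, times[sel], tc, init, rtol = 1e-8)
    }))
  } else {
    .death_model_curve(best, mode, times, temperature_C, init, rtol = 1e-8)
  }
  structure(
    list(params = params, objective = min(ok$objective), mode = mode,
         init = init, temperature_C = if (mode == "fast") temps else
           NA_real_,
         starts = runs, data = as_tibble(data), fitted = fitted),
    class = "death_fit"
  )
}

#' @export
print.death_fit <- function(x, ...) {
  cat(sprintf("<death_fit> %s mode, SSE = %.3g\n", x$mode, x$objective))
  print(x$params)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.death_fit <- function(x, ...) {
  p <- x$params
  if (x$mode == "fast") {
    tibble(term = c("kf_bar", "kb", "Tk"),
           estimate = c(p$kf_bar, p$kb, p$Tk))
  } else {
    tibble(term = c("ks_bar", "D_tau"),
           estimate = c(p$ks_bar, p$D_tau))
  }
}

#' @exportS3Method generics::glance
glance.death_fit <- function(x, ...) {
  tibble(mode = x$mode, objective = x$objective, nobs = nrow(x$data),
         n_starts = nrow(x$starts),
         n_converged = sum(x$starts$converged, na.rm = TRUE))
}
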