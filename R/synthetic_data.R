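# Synthetic viability and tumor-growth datasets.
#
# These generators emulate the *statistical structure* of the external
# experimental datasets the death and growth models are calibrated
# against: cell viability versus time at a fixed heating temperature
# (water-bath / nanoparticle heating assays) and caliper tumor-volume
# growth curves. Viability noise is additive Gaussian on fractions
# (clipped to [0, 1]); volume noise is multiplicative log-normal, since
# growth curves span decades. Every generator takes an explicit seed and
# restores the caller's RNG state.

#' Generate a synthetic viability dataset
#'
#' Survival fractions from the three-state model plus additive Gaussian
#' noise, clipped to \[0, 1\]. Fast mode reports A(t) at a constant heating
#' temperature; slow mode reports 1 - D(t) after treatment.
#'
#' @param params A [death_model_params()].
#' @param mode `"fast"` or `"slow"`.
#' @param times Observation times: minutes for fast mode (default 10 points
#'   over 30 min), hours for slow mode (default 10 points over 48 h).
#' @param temperature_C Heating temperature for fast mode, degC.
#' @param D0 Initial dead fraction for slow mode.
#' @param sd Noise standard deviation (>= 0).
#' @param seed RNG seed (required).
#' @param init Fast-phase initial state.
#' @return Tibble `time`, `temperature_C`, `survival` of class
#'   `viability_dataset`, with generating parameters, mode and seed stored
#'   as attributes.
#' @export
#' @examples
#' gen_viability(death_model_params("melanoma"), seed = 1)
gen_viability <- function(params, mode = c("fast", "slow"),
                          times = NULL, temperature_C = 48, D0 = 0.3,
                          sd = 0.02, seed,
                          init = c(A = 1 - 1e-3, V = 1e-3, D = 0)) {
  mode <- match.arg(mode)
  if (missing(seed)) abort("seed is required", class = "nanotherm_input_error")
  if (sd < 0) abort("sd must be >= 0", class = "nanotherm_domain_error")
  times <- times %||% if (mode == "fast") {
    seq(0, 30, length.out = 10)
  } else {
    seq(0, 48, length.out = 10)
  }
  curve <- if (mode == "fast") {
    tr <- fast_death(params, temperature_C, max(times), init = init,
                     times_min = sort(unique(c(0, times))))
    tr$A[match(times, tr$time_min)]
  } else {
    tr <- slow_death(params, D0 = D0, t_end_h = max(times),
                     times_h = sort(unique(c(0, times))))
    1 - tr$D[match(times, tr$time_h)]
  }
  noisy <- .with_seed(seed, curve + rnorm(length(times), 0, sd))
  out <- tibble(time = times,
                temperature_C = if (mode == "fast") temperature_C
                                else NA_real_,
                survival = pmin(pmax(noisy, 0), 1))
  class(out) <- c("viability_dataset", class(out))
  attr(out, "params") <- params
  attr(out, "mode") <- mode
  attr(out, "true_curve") <- curve
  attr(out, "sd") <- sd
  attr(out, "seed") <- seed
  out
}

#' Generate a synthetic tumor-growth dataset
#'
#' V(t) = V0 exp(a0 t) times log-normal multiplicative noise
#' exp(N(0, sd)).
#'
#' @param params A [growth_params()].
#' @param V0_mm3 Initial volume, mm^3.
#' @param days Observation days (default 8 points over 14 days).
#' @param sd Log-scale noise standard deviation (>= 0).
#' @param seed RNG seed (required).
#' @return Tibble `day`, `volume_mm3` of class `growth_dataset` with
#'   generating parameters and seed as attributes.
#' @export
#' @examples
#' gen_growth(growth_params("melanoma"), seed = 1)
gen_growth <- function(params, V0_mm3 = tumor_volume_mm3(3), days = NULL,
                       sd = 0.05, seed) {
  stopifnot(inherits(params, "growth_params"))
  if (missing(seed)) abort("seed is required", class = "nanotherm_input_error")
  if (sd < 0) abort("sd must be >= 0", class = "nanotherm_domain_error")
  if (V0_mm3 <= 0) abort("V0 must be > 0", class = "nanotherm_domain_error")
  days <- days %||% seq(0, 14, length.out = 8)
  mult <- .with_seed(seed, exp(rnorm(length(days), 0, sd)))
  out <- tibble(day = days,
                volume_mm3 = grow(V0_mm3, params, days) * mult)
  class(out) <- c("growth_dataset", class(out))
  attr(out, "params") <- params
  attr(out, "sd") <- sd
  attr(out, "seed") <- seed
  out
}
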