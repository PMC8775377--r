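# Exogenous inputs: meal glucose appearance d(t), heart-rate-derived
# exercise intensity u(t), the Gaussian MET estimator and the critical
# accumulated-intensity threshold ATH.

# Two-compartment absorption kernel ra*rb/(rb-ra) (e^{-ra t} - e^{-rb t});
# integrates to exactly 1 over [0, Inf), zero for negative lags.
bolus_kernel <- function(tau, ra, rb) {
  k <- ra * rb / (rb - ra) * (exp(-ra * tau) - exp(-rb * tau))
  k[tau < 0] <- 0
  k
}

#' Glucose appearance rate from meals
#'
#' Evaluates the plasma glucose appearance `d(t)` (mg/dL/min) as the
#' superposition, over all meals, of two-compartment absorption kernels:
#' a slow pool with rates `r1`, `r2` and a fast pool with rates `r3`, `r4`.
#' Each kernel has unit time-integral, so one gram of carbohydrate
#' contributes `1000 * bioavailability / VolG` mg/dL of total appearance.
#'
#' @param t time (min from midnight), vectorized.
#' @param meals data frame of meal events (see [meal_event()]).
#' @param params a [model_params()] list (uses `r1..r4`, `VolG`,
#'   `bioavailability`).
#' @return Numeric vector of appearance rates, same length as `t`.
#' @export
#' @examples
#' m <- meal_event(600, DGS = 47.6)
#' meal_rate(c(590, 660), m, model_params())
meal_rate <- function(t, meals, params = model_params()) {
  meals <- as.data.frame(meals)
  d <- numeric(length(t))
  if (!nrow(meals)) return(d)
  scale <- 1000 * params$bioavailability / params$VolG
  for (i in seq_len(nrow(meals))) {
    tau <- t - meals$t0[i]
    d <- d + scale *
      (meals$DGS[i] * bolus_kernel(tau, params$r1, params$r2) +
       meals$DGF[i] * bolus_kernel(tau, params$r3, params$r4))
  }
  d
}

#' Exercise intensity from heart rate
#'
#' Maps heart rate to the percentage intensity scale `u = 100 HR / HRmax`,
#' tolerating up to 5% overshoot of the maximum before erroring and clipping
#' the result to `[0, 100]`.
#'
#' @param hr heart rate (bpm), vectorized.
#' @param hr_max maximum heart rate (bpm), positive scalar.
#' @return Intensity percentage(s) in `[0, 100]`.
#' @export
intensity_from_hr <- function(hr, hr_max) {
  if (!is.numeric(hr_max) || length(hr_max) != 1L || hr_max <= 0)
    stop("hr_max must be a positive scalar")
  if (any(hr < 0)) stop("heart rate must be non-negative")
  if (any(hr > hr_max * 1.05))
    stop("heart rate exceeds hr_max by more than 5%")
  pmin(pmax(100 * hr / hr_max, 0), 100)
}

#' Gaussian MET estimator parameters
#'
#' The metabolic equivalent of task developed at a given heart-rate
#' percentage is modelled as a Gaussian `a * exp(-((u - b)/c)^2)`. The
#' defaults are the fit to the published heart-rate/MET relationship:
#' peak 10.25 MET at 89.26% HR with width 62.36% HR.
#'
#' @param a peak MET value (MET).
#' @param b heart-rate percentage at the peak (%).
#' @param c width (%).
#' @return A named list of class `"met_params"`.
#' @export
met_params <- function(a = 10.25, b = 89.26, c = 62.36) {
  stopifnot(a > 0, c > 0, b > 0, b <= 150)
  structure(list(a = a, b = b, c = c), class = "met_params")
}

#' Metabolic equivalent of task from exercise intensity
#'
#' @param u heart-rate-percentage intensity (%), vectorized, non-negative.
#' @param mp a [met_params()] list.
#' @return MET value(s).
#' @export
#' @examples
#' met_from_intensity(89.26)  # the fitted peak, 10.25 MET
met_from_intensity <- function(u, mp = met_params()) {
  if (any(u < 0)) stop("intensity must be non-negative")
  mp$a * exp(-((u - mp$b) / mp$c)^2)
}

#' Critical threshold of accumulated exercise intensity
#'
#' The glycogenolysis rate starts declining once the integrated intensity A
#' exceeds `ATH(u) = -1.152 u^2 + 87.471 u`, clamped at zero beyond the
#' parabola's positive root (u above ~75.9%, where any accumulation counts
#' as glycogen-depleting).
#'
#' @param u intensity above basal (%), vectorized, non-negative.
#' @return Threshold value(s) in the same %-min units as A.
#' @export
#' @examples
#' ath_threshold(30)  # 1587.33
ath_threshold <- function(u) {
  if (any(u < 0)) stop("intensity must be non-negative")
  pmax(-1.152 * u^2 + 87.471 * u, 0)
}

# Intensity above basal actually driving the exercise subsystem.
effective_intensity <- function(u_abs, params) {
  pmax(u_abs - params$u_basal, 0)
}

#' Build the exogenous input signals for a day
#'
#' Renders a schedule into minute-resolution traces of the absolute
#' intensity `u` (piecewise-constant: `u_basal` between activity events, the
#' event's `hr_pct` within one), the effective intensity above basal
#' `u_eff = max(u - u_basal, 0)`, the meal appearance `d(t)`, and the
#' pancreatic reference clock `t_meal_ref` (minutes since the most recent
#' meal onset, 0 before the first meal).
#'
#' @param schedule a [day_schedule()].
#' @param params a [model_params()] list.
#' @param horizon day length (min).
#' @return A data frame with columns `t`, `u`, `u_eff`, `d`, `t_meal_ref`
#'   on the grid `0:horizon`.
#' @export
build_signals <- function(schedule, params = model_params(),
                          horizon = 1440) {
  stopifnot(inherits(schedule, "day_schedule"))
  t <- seq(0, horizon, by = 1)
  u <- rep(params$u_basal, length(t))
  a <- schedule$activities
  for (i in seq_len(nrow(a))) {
    sel <- t >= a$t0[i] & t < a$t0[i] + a$duration[i]
    u[sel] <- a$hr_pct[i]
  }
  d <- meal_rate(t, schedule$meals, params)
  tm <- schedule$meals$t0
  t_ref <- numeric(length(t))
  for (t0 in tm) t_ref[t >= t0] <- t[t >= t0] - t0
  data.frame(t = t, u = u, u_eff = effective_intensity(u, params),
             d = d, t_meal_ref = t_ref)
}
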