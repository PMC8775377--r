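# Right-hand side of the extended Bergman minimal model.
#
# Nine states: I (plasma insulin, uU/mL), X (remote insulin action, 1/min),
# G (plasma glucose, mg/dL), Gprod and Gup (exercise-induced hepatic glucose
# production / uptake, mg/kg/min), Ie (exercise-induced insulin removal,
# uU/mL/min), PVO2max (% of maximal oxygen consumption above basal),
# A (integrated exercise intensity, %-min), Ggly (glycogenolysis decline,
# mg/kg/min).

.state_names <- c("I", "X", "G", "Gprod", "Gup", "Ie", "PVO2max", "A",
                  "Ggly")

#' Rest-equilibrium model state
#'
#' With no meals and no activity, `(I, X, G) = (Ib, 0, Gb)` with all
#' exercise states at zero is a stationary point of the model (exactly so
#' when the beta-cell threshold `h` equals `Gb`, the default).
#'
#' @param params a [model_params()] list.
#' @return Named numeric vector of the nine model states.
#' @export
rest_state <- function(params = model_params()) {
  setNames(c(params$Ib, 0, params$Gb, 0, 0, 0, 0, 0, 0), .state_names)
}

#' Time derivative of the model state
#'
#' Evaluates the per-minute rates of change of all nine states given the
#' instantaneous exogenous inputs. The glucose equation couples the
#' per-kilogram exercise fluxes through `W/VolG` (mg/kg/min -> mg/dL/min)
#' and the pancreatic release term uses the positive part
#' `gamma * max(G - h, 0) * t_meal_ref`, where `t_meal_ref` is the time
#' since the most recent meal onset.
#'
#' @param state named numeric vector as from [rest_state()].
#' @param input list with elements `u_eff` (intensity above basal, %),
#'   `d` (meal glucose appearance, mg/dL/min) and `t_meal_ref` (min).
#' @param params a [model_params()] list.
#' @return Named numeric vector of derivatives, same layout as `state`.
#' @export
#' @examples
#' model_rhs(rest_state(), list(u_eff = 0, d = 0, t_meal_ref = 0))
model_rhs <- function(state, input, params = model_params()) {
  if (any(!is.finite(state)))
    stop("non-finite model state: integration blow-up")
  s <- as.list(state)
  h <- param_h(params)
  u <- input$u_eff
  dI <- -params$eta * (s$I - params$Ib) +
    params$gamma * max(s$G - h, 0) * input$t_meal_ref - s$Ie
  dX <- -params$p2 * s$X + params$p3 * (s$I - params$Ib)
  wv <- params$W / params$VolG
  dG <- -params$p1 * (s$G - params$Gb) - s$X * s$G +
    wv * (s$Gprod - s$Ggly) - wv * s$Gup + input$d
  dGprod <- params$a1 * s$PVO2max - params$a2 * s$Gprod
  dGup <- params$a3 * s$PVO2max - params$a4 * s$Gup
  dIe <- params$a5 * s$PVO2max - params$a6 * s$Ie
  dPVO2 <- -0.8 * s$PVO2max + 0.8 * u
  dA <- integrated_intensity_change(s$A, u, params$a_reset)
  dGgly <- glycogenolysis_rate_change(s$Ggly, s$A, u, params)
  setNames(c(dI, dX, dG, dGprod, dGup, dIe, dPVO2, dA, dGgly),
           .state_names)
}

#' Rate of change of the glycogenolysis decline
#'
#' During activity (`u > 0`) the decline rate stays flat while the
#' integrated intensity `A` is below its critical threshold `ATH(u)`, and
#' grows at `K` once `A >= ATH(u)` (liver glycogen depleting). At rest
#' (`u = 0`) it recovers toward zero with time constant `T1`.
#'
#' @param Ggly current glycogenolysis decline (mg/kg/min).
#' @param A integrated exercise intensity (%-min).
#' @param u intensity above basal (%).
#' @param params a [model_params()] list (uses `K`, `T1`).
#' @return dGgly/dt (mg/kg/min per min).
#' @export
glycogenolysis_rate_change <- function(Ggly, A, u, params = model_params()) {
  stopifnot(u >= 0, A >= 0)
  if (u > 0) {
    if (A >= ath_threshold(u)) params$K else 0
  } else {
    -Ggly / params$T1
  }
}

#' Rate of change of the integrated exercise intensity
#'
#' `A` accumulates the intensity above basal while activity lasts
#' (`dA/dt = u` for `u > 0`) and is reset rapidly toward zero once activity
#' stops (`dA/dt = -A / a_reset` for `u = 0`), marking the start of the
#' glycogen replenishment period.
#'
#' @param A integrated intensity (%-min).
#' @param u intensity above basal (%).
#' @param a_reset reset time constant (min).
#' @return dA/dt.
#' @export
integrated_intensity_change <- function(A, u, a_reset = 0.001) {
  stopifnot(u >= 0, A >= 0)
  if (u > 0) u else -A / a_reset
}
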