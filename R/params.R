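# Model parameters: rate constants, basal states and input-channel
# coefficients of the extended Bergman minimal model.

.param_units <- c(
  p1 = "1/min", p2 = "1/min", p3 = "(uU/mL)/min^2", eta = "1/min",
  gamma = "(uU/mL)/(min^2 (mg/dL))", h = "mg/dL", Gb = "mg/dL",
  Ib = "uU/mL", W = "kg", VolG = "dL",
  a1 = "mg/kg/min^2", a2 = "1/min", a3 = "mg/kg/min^2", a4 = "1/min",
  a5 = "uU/mL/min", a6 = "1/min",
  T1 = "min", K = "mg/kg/min per min",
  r1 = "1/min", r2 = "1/min", r3 = "1/min", r4 = "1/min",
  u_basal = "%", a_reset = "min", bioavailability = "-"
)

#' Parameter set of the extended Bergman minimal model
#'
#' Builds a validated parameter list for the nine-state model. The defaults
#' are healthy normal-weight adult values: the glucose--insulin core uses
#' minimal-model constants calibrated to normal post-prandial excursions
#' (a 75 g slow-carbohydrate meal peaks about 30 mg/dL above basal), the
#' exercise subsystem uses the Roy--Parker rate constants, and the two-pool
#' carbohydrate absorption rates put the slow-pool and fast-pool appearance
#' peaks near 135 and 41 minutes after intake.
#'
#' @param p1 insulin-independent glucose clearance rate (1/min).
#' @param p2 decay rate of remote insulin action (1/min).
#' @param p3 gain from plasma insulin to remote insulin action
#'   ((uU/mL)/min^2).
#' @param eta first-order plasma insulin decay rate (1/min).
#' @param gamma pancreatic insulin release gain ((uU/mL)/(min^2 (mg/dL))).
#' @param h glucose threshold above which beta cells release insulin
#'   (mg/dL). `NA` (the default) means "use `Gb`", which makes the fasted
#'   rest state an exact equilibrium.
#' @param Gb basal plasma glucose (mg/dL).
#' @param Ib basal plasma insulin (uU/mL).
#' @param W body weight (kg).
#' @param VolG glucose distribution volume (dL).
#' @param a1,a2 gain/decay of exercise-induced hepatic glucose production
#'   (mg/kg/min^2, 1/min).
#' @param a3,a4 gain/decay of exercise-induced glucose uptake
#'   (mg/kg/min^2, 1/min).
#' @param a5,a6 gain/decay of exercise-induced insulin removal
#'   (uU/mL/min, 1/min).
#' @param T1 recovery time constant of the glycogenolysis decline (min).
#' @param K decline rate of the glycogenolysis rate once the integrated
#'   intensity exceeds its critical threshold (mg/kg/min per min).
#' @param r1,r2 slow-carbohydrate absorption rate constants (1/min); must
#'   differ.
#' @param r3,r4 fast-carbohydrate absorption rate constants (1/min); must
#'   differ.
#' @param u_basal resting oxygen-consumption percentage (%); intensities are
#'   measured above this basal level, about 8% of PVO2max at rest.
#' @param a_reset time constant of the integrated-intensity reset once
#'   activity stops (min); the small default makes the reset effectively
#'   instantaneous.
#' @param bioavailability fraction of ingested carbohydrate appearing in
#'   plasma (dimensionless).
#'
#' @return A named list of class `"model_params"`.
#' @seealso [read_params()], [write_params()], [subject_params()]
#' @export
#' @examples
#' p <- model_params()
#' p$Gb
model_params <- function(p1 = 0.0317, p2 = 0.03, p3 = 3e-5,
                         eta = 0.2659, gamma = 0.005, h = NA,
                         Gb = 88, Ib = 15, W = 70, VolG = 117,
                         a1 = 0.00158, a2 = 0.056,
                         a3 = 0.00195, a4 = 0.0485,
                         a5 = 0.00125, a6 = 0.075,
                         T1 = 6, K = 0.0108,
                         r1 = 0.006, r2 = 0.009,
                         r3 = 0.02, r4 = 0.03,
                         u_basal = 8, a_reset = 0.001,
                         bioavailability = 1) {
  p <- list(p1 = p1, p2 = p2, p3 = p3, eta = eta, gamma = gamma, h = h,
            Gb = Gb, Ib = Ib, W = W, VolG = VolG,
            a1 = a1, a2 = a2, a3 = a3, a4 = a4, a5 = a5, a6 = a6,
            T1 = T1, K = K, r1 = r1, r2 = r2, r3 = r3, r4 = r4,
            u_basal = u_basal, a_reset = a_reset,
            bioavailability = bioavailability)
  class(p) <- "model_params"
  validate_params(p)
  p
}

#' Validate a model parameter set
#'
#' Checks positivity of all rate constants, distinctness of the absorption
#' rate pairs (the bolus kernel is singular when r1 = r2 or r3 = r4), and
#' the range of the basal intensity.
#'
#' @param p a `"model_params"` list.
#' @return `p`, invisibly, if valid; otherwise an error is thrown.
#' @export
validate_params <- function(p) {
  num <- vapply(p, function(x)
    length(x) == 1L && (is.numeric(x) || is.na(x)), logical(1))
  if (!all(num))
    stop("all model parameters must be numeric scalars")
  if (is.na(p$h)) p$h <- NA_real_
  pos <- c("p1", "p2", "p3", "eta", "gamma", "Gb", "Ib", "W", "VolG",
           "a1", "a2", "a3", "a4", "a5", "a6", "T1", "K",
           "r1", "r2", "r3", "r4", "a_reset")
  bad <- pos[vapply(pos, function(nm) !(p[[nm]] > 0), logical(1))]
  if (length(bad))
    stop("model parameters must be strictly positive: ",
         paste(bad, collapse = ", "))
  if (p$r1 == p$r2 || p$r3 == p$r4)
    stop("absorption rate pairs must differ (r1 != r2, r3 != r4); ",
         "the bolus kernel is singular otherwise")
  if (!is.na(p$h) && p$h <= 0) stop("h must be positive (or NA for Gb)")
  if (p$u_basal < 0 || p$u_basal >= 100)
    stop("u_basal must lie in [0, 100)")
  if (p$bioavailability <= 0 || p$bioavailability > 1)
    stop("bioavailability must lie in (0, 1]")
  invisible(p)
}

# Effective beta-cell threshold: h defaults to the subject's basal glucose.
param_h <- function(p) if (is.na(p$h)) p$Gb else p$h

#' Read / write a model parameter set as YAML
#'
#' The file is a flat mapping of parameter names to values plus a `units`
#' sidecar mapping. The round trip `read_params(write_params(p))` is
#' lossless.
#'
#' @param p a `"model_params"` list.
#' @param path file path.
#' @return `write_params()` returns `path` invisibly; `read_params()`
#'   returns a `"model_params"` list.
#' @export
write_params <- function(p, path) {
  validate_params(p)
  vals <- unclass(p)
  vals$h <- if (is.na(p$h)) "basal" else p$h
  yaml::write_yaml(list(parameters = vals,
                        units = as.list(.param_units[names(vals)])),
                   path, precision = 15L)
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  doc <- yaml::read_yaml(path)
  vals <- doc$parameters
  if (is.null(vals)) stop("no 'parameters' mapping in ", path)
  if (identical(vals$h, "basal")) vals$h <- NA
  do.call(model_params, vals)
}

#' Specialize model parameters to a subject
#'
#' Overrides the basal glucose, body weight and glucose distribution volume
#' with subject-level values. The distribution volume is scaled with weight
#' at the classical 1.67 dL/kg so that a 70 kg subject keeps the default
#' 117 dL.
#'
#' @param subject a [virtual_patient()] (or any list with `basal_glucose`
#'   and `weight`).
#' @param params base parameter set to specialize.
#' @return A `"model_params"` list.
#' @export
subject_params <- function(subject, params = model_params()) {
  stopifnot(is.list(subject))
  if (!is.null(subject$basal_glucose)) params$Gb <- subject$basal_glucose
  if (!is.null(subject$weight)) {
    params$W <- subject$weight
    params$VolG <- subject$weight * 117 / 70
  }
  validate_params(params)
  params
}
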