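# Monte Carlo virtual-population generation, daily-schedule templating and
# the MET-based active/sedentary lifestyle classifier.

#' A virtual patient
#'
#' Demographic and physiological descriptor of one (virtual) subject.
#' `bmi` must equal `weight / height^2` within rounding; `hr_max` defaults
#' to the classical `220 - age` estimate.
#'
#' @param sex `"male"` or `"female"`.
#' @param lifestyle `"active"` or `"sedentary"`.
#' @param age years.
#' @param height m.
#' @param weight kg.
#' @param basal_glucose mg/dL, in (60, 130).
#' @param cho_total daily carbohydrate intake (g).
#' @param n_meals meals per day (3 or 4), or `NA` to draw at schedule
#'   generation.
#' @param hr_rest resting heart rate (bpm).
#' @param hr_max maximum heart rate (bpm).
#' @param bmi kg/m^2; defaults to `weight / height^2`.
#' @param id optional label.
#' @return A list of class `"virtual_patient"`.
#' @export
virtual_patient <- function(sex, lifestyle, age, height, weight,
                            basal_glucose, cho_total = NA, n_meals = NA,
                            hr_rest = NA, hr_max = 220 - age,
                            bmi = weight / height^2, id = NA) {
  sex <- match.arg(sex, c("male", "female"))
  lifestyle <- match.arg(lifestyle, c("active", "sedentary"))
  stopifnot(age > 0, height > 0, weight > 0)
  if (abs(bmi - weight / height^2) > 0.05)
    stop("bmi is inconsistent with weight/height^2")
  if (basal_glucose <= 60 || basal_glucose >= 130)
    stop("basal glucose must lie in (60, 130) mg/dL")
  if (!is.na(n_meals) && !(n_meals %in% 3:4))
    stop("n_meals must be 3 or 4")
  if (!is.na(hr_rest) && hr_rest >= hr_max)
    stop("resting heart rate must be below hr_max")
  structure(list(id = id, sex = sex, lifestyle = lifestyle, age = age,
                 height = height, weight = weight, bmi = bmi,
                 basal_glucose = basal_glucose, cho_total = cho_total,
                 n_meals = n_meals, hr_rest = hr_rest, hr_max = hr_max),
            class = "virtual_patient")
}

# One truncated-normal draw batch by rejection; sd = 0 degenerates to the
# mean (which must then lie inside the bounds).
rtrunc_norm <- function(n, mean, sd, lower = -Inf, upper = Inf,
                        max_rounds = 1000L) {
  if (lower > upper) stop("truncation bounds are not ordered")
  if (sd == 0) {
    if (mean < lower || mean > upper)
      stop("degenerate (zero-SD) mean lies outside the truncation bounds")
    return(rep(mean, n))
  }
  out <- numeric(0)
  for (round in seq_len(max_rounds)) {
    x <- rnorm(n, mean, sd)
    out <- c(out, x[x >= lower & x <= upper])
    if (length(out) >= n) return(out[seq_len(n)])
  }
  stop("rejection sampling exhausted (", max_rounds,
       " rounds): truncation bounds are too tight for N(", mean, ", ",
       sd, ")")
}

#' Population specification
#'
#' Per-group (sex x lifestyle) mean/SD pairs for the sampled personal
#' factors, plus truncation and conditioning settings for the Monte Carlo
#' generator. [default_population_spec()] returns the published virtual-population
#' parameterization: four groups (active/sedentary x male/female) with
#' group-specific age, basal glucose, BMI, daily carbohydrate quantity and
#' height distributions; resting heart rate is shared across groups.
#'
#' Sampling truncates each factor at `trunc_sd` standard deviations around
#' its mean, intersected with physiological ranges (`age_range`,
#' `glucose_range`). `bmi_slope` shifts the mean of basal glucose /
#' carbohydrate intake by `slope * SD` per standard deviation of the
#' subject's BMI draw; the default slopes of zero reproduce the group
#' marginals exactly.
#'
#' @param groups named list (`active_male`, `active_female`,
#'   `sedentary_male`, `sedentary_female`), each a list of
#'   `c(mean, sd)` pairs for `age`, `basal_glucose`, `bmi`, `cho_total`,
#'   `height`.
#' @param hr_rest `c(mean, sd)` of resting heart rate (bpm).
#' @param trunc_sd truncation half-width in SDs.
#' @param age_range,glucose_range physiological ranges.
#' @param bmi_slope list of per-factor slopes (see above).
#' @return A list of class `"population_spec"`.
#' @export
population_spec <- function(groups, hr_rest = c(75.4, 7.32), trunc_sd = 3,
                            age_range = c(20, 75),
                            glucose_range = c(60, 130),
                            bmi_slope = list(basal_glucose = 0,
                                             cho_total = 0)) {
  need <- c("age", "basal_glucose", "bmi", "cho_total", "height")
  for (g in names(groups)) {
    miss <- setdiff(need, names(groups[[g]]))
    if (length(miss))
      stop("group '", g, "' lacks factors: ", paste(miss, collapse = ", "))
    for (f in need) {
      v <- groups[[g]][[f]]
      if (length(v) != 2L || v[2] < 0)
        stop("group '", g, "', factor '", f,
             "': expected c(mean, sd) with sd >= 0")
    }
  }
  stopifnot(trunc_sd > 0, length(hr_rest) == 2L)
  structure(list(groups = groups, hr_rest = hr_rest, trunc_sd = trunc_sd,
                 age_range = age_range, glucose_range = glucose_range,
                 bmi_slope = bmi_slope),
            class = "population_spec")
}

#' @rdname population_spec
#' @export
default_population_spec <- function() {
  population_spec(groups = list(
    active_male = list(age = c(42, 14), basal_glucose = c(88.06, 5.25),
                       bmi = c(23.59, 2.4), cho_total = c(300, 27),
                       height = c(1.69, 0.06)),
    active_female = list(age = c(41, 12), basal_glucose = c(88.63, 7.35),
                         bmi = c(23.79, 3.12), cho_total = c(279, 34),
                         height = c(1.59, 0.07)),
    sedentary_male = list(age = c(43, 14), basal_glucose = c(89.90, 7.81),
                          bmi = c(25.67, 3.4), cho_total = c(305, 35),
                          height = c(1.69, 0.06)),
    sedentary_female = list(age = c(40, 12), basal_glucose = c(90.02, 7.05),
                            bmi = c(25.03, 3.22), cho_total = c(288, 32),
                            height = c(1.60, 0.06))))
}

trunc_bounds <- function(ms, trunc_sd, floor = -Inf, cap = Inf) {
  c(max(floor, ms[1] - trunc_sd * ms[2]), min(cap, ms[1] + trunc_sd * ms[2]))
}

#' Generate one virtual patient
#'
#' Samples a patient in the generator's dependency order: age and height
#' first, then BMI, from which weight is derived (`weight = BMI * height^2`,
#' so the BMI identity holds exactly), then basal glucose and daily
#' carbohydrate quantity conditioned on the BMI draw through the spec's
#' linear mean shifts. Meal count is drawn uniformly from 3--4 and resting
#' heart rate from the shared spec distribution. Uses the current R random
#' stream; seed via [set.seed()] or [generate_population()].
#'
#' @param sex `"male"` or `"female"`.
#' @param lifestyle `"active"` or `"sedentary"`.
#' @param spec a [population_spec()].
#' @return A [virtual_patient()].
#' @export
generate_patient <- function(sex, lifestyle, spec = default_population_spec()) {
  sex <- match.arg(sex, c("male", "female"))
  lifestyle <- match.arg(lifestyle, c("active", "sedentary"))
  key <- paste(lifestyle, sex, sep = "_")
  g <- spec$groups[[key]]
  if (is.null(g)) stop("spec has no parameters for group '", key, "'")
  k <- spec$trunc_sd

  b <- trunc_bounds(g$age, k, spec$age_range[1], spec$age_range[2])
  age <- rtrunc_norm(1, g$age[1], g$age[2], b[1], b[2])
  b <- trunc_bounds(g$height, k, floor = 1.2)
  height <- rtrunc_norm(1, g$height[1], g$height[2], b[1], b[2])
  b <- trunc_bounds(g$bmi, k, floor = 15)
  bmi <- rtrunc_norm(1, g$bmi[1], g$bmi[2], b[1], b[2])
  weight <- bmi * height^2
  z_bmi <- if (g$bmi[2] > 0) (bmi - g$bmi[1]) / g$bmi[2] else 0

  gl_mean <- g$basal_glucose[1] +
    spec$bmi_slope$basal_glucose * g$basal_glucose[2] * z_bmi
  b <- trunc_bounds(c(gl_mean, g$basal_glucose[2]), k,
                    spec$glucose_range[1] + 1e-9,
                    spec$glucose_range[2] - 1e-9)
  glucose <- rtrunc_norm(1, gl_mean, g$basal_glucose[2], b[1], b[2])

  cho_mean <- g$cho_total[1] + spec$bmi_slope$cho_total * g$cho_total[2] * z_bmi
  b <- trunc_bounds(c(cho_mean, g$cho_total[2]), k, floor = 50)
  cho <- rtrunc_norm(1, cho_mean, g$cho_total[2], b[1], b[2])

  n_meals <- sample(3:4, 1L)
  hr_max <- 220 - age
  b <- trunc_bounds(spec$hr_rest, k, floor = 40, cap = hr_max - 20)
  hr_rest <- rtrunc_norm(1, spec$hr_rest[1], spec$hr_rest[2], b[1], b[2])

  virtual_patient(sex = sex, lifestyle = lifestyle, age = age,
                  height = height, weight = weight, bmi = bmi,
                  basal_glucose = glucose, cho_total = cho,
                  n_meals = n_meals, hr_rest = hr_rest, hr_max = hr_max)
}

#' Generate a virtual-patient deck
#'
#' Draws `counts[group]` patients per group and returns them as one data
#' frame (one row per patient). With the published cohort layout, 200
#' patients split 50/50 active/sedentary and 50/50 male/female within each
#' lifestyle arm.
#'
#' @param counts named integer vector over the group keys
#'   (`active_male`, ...).
#' @param spec a [population_spec()].
#' @param seed optional integer seed for reproducible decks.
#' @return Data frame with one row per patient.
#' @export
#' @examples
#' deck <- generate_population(c(active_male = 5), seed = 1)
#' nrow(deck)
generate_population <- function(counts = c(active_male = 50,
                                           active_female = 50,
                                           sedentary_male = 50,
                                           sedentary_female = 50),
                                spec = default_population_spec(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(names(counts)) || any(!nzchar(names(counts))))
    stop("counts must be a named vector over group keys")
  rows <- vector("list", sum(counts))
  idx <- 0L
  for (key in names(counts)) {
    parts <- strsplit(key, "_", fixed = TRUE)[[1L]]
    if (length(parts) != 2L)
      stop("group key must be '<lifestyle>_<sex>': ", key)
    for (j in seq_len(counts[[key]])) {
      p <- generate_patient(parts[2L], parts[1L], spec)
      idx <- idx + 1L
      p$id <- sprintf("%s_%03d", key, j)
      rows[[idx]] <- as.data.frame(unclass(p), stringsAsFactors = FALSE)
    }
  }
  deck <- do.call(rbind, rows)
  rownames(deck) <- NULL
  deck
}

#' Convert a deck row back to a virtual patient
#'
#' @param row one-row data frame (or list) with the [virtual_patient()]
#'   fields.
#' @return A `"virtual_patient"`.
#' @export
as_patient <- function(row) {
  row <- as.list(row)
  virtual_patient(sex = row$sex, lifestyle = row$lifestyle, age = row$age,
                  height = row$height, weight = row$weight,
                  basal_glucose = row$basal_glucose,
                  cho_total = row$cho_total, n_meals = row$n_meals,
                  hr_rest = row$hr_rest, hr_max = row$hr_max,
                  id = row$id)
}

#' Named-activity intensity table
#'
#' Maps the contemplated daily activities of each lifestyle to heart-rate
#' percentages and duration ranges. Physically active people perform walks
#' (55--100 m/min) and occasional runs (130 m/min); sedentary people
#' perform seated office work and, as their most demanding activity,
#' domestic chores such as sweeping. Intensities are calibrated so that
#' active-day oxygen consumption spans roughly 8--80% of maximum (mostly
#' around 30%) and sedentary days stay within 8--30%.
#'
#' @param lifestyle `"active"` or `"sedentary"`.
#' @return Data frame with columns `name`, `hr_pct`, `weight`, `dur_min`,
#'   `dur_max`.
#' @export
activity_table <- function(lifestyle) {
  lifestyle <- match.arg(lifestyle, c("active", "sedentary"))
  if (lifestyle == "active")
    data.frame(name = c("walk_55m", "walk_75m", "walk_100m", "run_130m"),
               hr_pct = c(25, 35, 45, 80),
               weight = c(0.35, 0.35, 0.25, 0.05),
               dur_min = c(100, 100, 100, 25),
               dur_max = c(160, 160, 160, 45))
  else
    data.frame(name = c("computer_work", "desk_documents", "sweeping"),
               hr_pct = c(12, 15, 28),
               weight = c(0.45, 0.35, 0.20),
               dur_min = c(30, 30, 30),
               dur_max = c(80, 80, 80))
}

.meal_windows <- list(breakfast = c(540, 660), lunch = c(780, 900),
                      snack = c(1020, 1140), dinner = c(1200, 1320))
.meal_alpha <- c(breakfast = 8, lunch = 9, snack = 3, dinner = 8)

#' Generate a random daily schedule for a patient
#'
#' Draws the patient's meals and five physical activities. Meal times fall
#' in breakfast/lunch/dinner windows (plus an afternoon snack window when
#' `n_meals = 4`); the daily carbohydrate total is partitioned across meals
#' by a Dirichlet split (the snack receiving a smaller share) and each
#' meal's slow/fast composition is drawn from a Beta(9, 1) slow fraction.
#' Each activity starts within 3 hours of a meal onset (activities cycling
#' over the meals), has type, intensity and duration drawn from the
#' lifestyle's [activity_table()], never overlaps another activity, and is
#' clipped at midnight. Infeasible placements trigger a full re-draw of the
#' day (up to 100 attempts).
#'
#' @param patient a [virtual_patient()] (or deck row).
#' @param n_activities number of activity events per day.
#' @param slow_beta shape parameters of the slow-fraction Beta draw.
#' @return A [day_schedule()].
#' @export
generate_schedule <- function(patient, n_activities = 5,
                              slow_beta = c(9, 1)) {
  if (!inherits(patient, "virtual_patient")) patient <- as_patient(patient)
  cho <- patient$cho_total
  if (is.na(cho) || cho <= 0)
    stop("patient has no daily carbohydrate total (cho_total)")
  tab <- activity_table(patient$lifestyle)

  for (attempt in seq_len(100L)) {
    n_meals <- if (is.na(patient$n_meals)) sample(3:4, 1L) else
      patient$n_meals
    slots <- if (n_meals == 4L) names(.meal_windows) else
      c("breakfast", "lunch", "dinner")
    t_meals <- vapply(slots, function(s)
      runif(1, .meal_windows[[s]][1], .meal_windows[[s]][2]), numeric(1))
    share <- rgamma(n_meals, shape = .meal_alpha[slots])
    share <- share / sum(share)
    grams <- cho * share
    slow <- rbeta(n_meals, slow_beta[1], slow_beta[2])
    meals <- data.frame(t0 = round(t_meals), DGS = grams * slow,
                        DGF = grams * (1 - slow))

    kinds <- sample(nrow(tab), n_activities, replace = TRUE,
                    prob = tab$weight)
    assigned <- ((seq_len(n_activities) - 1L) %% n_meals) + 1L
    ord <- order(meals$t0[assigned], assigned)
    acts <- data.frame(t0 = numeric(0), duration = numeric(0),
                       hr_pct = numeric(0))
    last_end <- 0
    ok <- TRUE
    for (i in ord) {
      m0 <- meals$t0[assigned[i]]
      dur <- runif(1, tab$dur_min[kinds[i]], tab$dur_max[kinds[i]])
      lb <- max(m0 + 2, last_end + 1)
      ub <- min(m0 + 180, 1435)
      if (lb > ub) { ok <- FALSE; break }
      start <- runif(1, lb, min(ub, lb + 60))
      end <- min(start + dur, 1439)
      if (end - start < 5) { ok <- FALSE; break }
      acts <- rbind(acts, data.frame(t0 = round(start),
                                     duration = round(end - start),
                                     hr_pct = tab$hr_pct[kinds[i]]))
      last_end <- round(end)
    }
    if (ok) return(day_schedule(meals = meals, activities = acts))
  }
  stop("could not place a feasible day after 100 attempts")
}

#' Active/sedentary lifestyle classification
#'
#' A person is physically active when they spend at least 8 hours of the
#' day performing activities above 1.5 MET, and sedentary otherwise (the
#' 8-hour boundary itself classifies as active).
#'
#' @param active_time hours/day above 1.5 MET, in `[0, 24]`; vectorized.
#' @return Character vector, `"active"` or `"sedentary"`.
#' @export
#' @examples
#' classify_lifestyle(c(6.12, 8.16))
classify_lifestyle <- function(active_time) {
  if (any(is.na(active_time)) || any(active_time < 0 | active_time > 24))
    stop("active_time must lie in [0, 24] hours")
  ifelse(active_time >= 8, "active", "sedentary")
}

#' Classify a cohort of activity-time records
#'
#' @param records data frame with an `active_time` column (hours/day above
#'   1.5 MET), e.g. [activity_time_records()].
#' @return A list with `counts` (named: active, sedentary) and `lifestyle`
#'   (per-record classification).
#' @export
#' @examples
#' classify_cohort(activity_time_records())$counts
classify_cohort <- function(records) {
  records <- as.data.frame(records)
  if (!nrow(records)) stop("no records to classify")
  cls <- classify_lifestyle(records$active_time)
  list(counts = c(active = sum(cls == "active"),
                  sedentary = sum(cls == "sedentary")),
       lifestyle = cls)
}

#' Hours above 1.5 MET in an intensity trace
#'
#' Integrates the indicator of the Gaussian MET estimate exceeding the
#' sedentary cutoff over a uniformly sampled intensity trace.
#'
#' @param u intensity trace (%), one value per grid step.
#' @param mp a [met_params()].
#' @param dt grid spacing (min).
#' @param cutoff MET cutoff.
#' @return Hours above the cutoff.
#' @export
met_hours <- function(u, mp = met_params(), dt = 1, cutoff = 1.5) {
  sum(met_from_intensity(u, mp) > cutoff) * dt / 60
}

#' Scheduled activity time above 1.5 MET
#'
#' Sums the durations of a schedule's activity events whose intensity maps
#' above the MET cutoff, counting non-event time as rest. This is the
#' accounting used to classify generated days, mirroring the per-activity
#' bookkeeping of the observed sample.
#'
#' @param schedule a [day_schedule()].
#' @param mp a [met_params()].
#' @param cutoff MET cutoff.
#' @return Hours/day above the cutoff.
#' @export
schedule_active_hours <- function(schedule, mp = met_params(),
                                  cutoff = 1.5) {
  a <- schedule$activities
  if (!nrow(a)) return(0)
  dur <- pmin(a$t0 + a$duration, 1440) - a$t0
  sum(dur[met_from_intensity(a$hr_pct, mp) > cutoff]) / 60
}
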