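# Daily schedules: timed meal and activity events.

#' Meal and activity events
#'
#' A meal event delivers `DGS` grams of slow-absorption and `DGF` grams of
#' fast-absorption carbohydrate at clock time `t0` (minutes from midnight).
#' An activity event holds a constant exercise intensity, expressed as a
#' percentage of the subject's maximum heart rate, over
#' `[t0, t0 + duration)`; either `hr_pct` is given directly or an absolute
#' heart rate `hr` is resolved against `hr_max`.
#'
#' @param t0 event start, minutes from midnight in `[0, 1440)`.
#' @param DGS,DGF slow / fast carbohydrate mass (g), non-negative and not
#'   both zero.
#' @param duration activity duration (min), positive.
#' @param hr_pct heart-rate percentage of maximum during the activity (%).
#' @param hr absolute heart rate (bpm), used with `hr_max` when `hr_pct` is
#'   missing.
#' @param hr_max maximum heart rate (bpm).
#' @return A one-row data frame describing the event.
#' @seealso [day_schedule()], [intensity_from_hr()]
#' @export
#' @examples
#' meal_event(600, DGS = 47.6)
#' activity_event(605, 85, hr_pct = 35)
meal_event <- function(t0, DGS = 0, DGF = 0) {
  stopifnot(DGS >= 0, DGF >= 0)
  if (DGS + DGF <= 0) stop("a meal must contain carbohydrate (DGS + DGF > 0)")
  if (t0 < 0 || t0 >= 1440) stop("meal time must lie in [0, 1440)")
  data.frame(t0 = t0, DGS = DGS, DGF = DGF)
}

#' @rdname meal_event
#' @export
activity_event <- function(t0, duration, hr_pct = NULL, hr = NULL,
                           hr_max = NULL) {
  if (is.null(hr_pct)) {
    if (is.null(hr) || is.null(hr_max))
      stop("give either hr_pct, or hr together with hr_max")
    hr_pct <- intensity_from_hr(hr, hr_max)
  }
  stopifnot(duration > 0)
  if (hr_pct <= 0 || hr_pct > 100)
    stop("hr_pct must lie in (0, 100]")
  if (t0 < 0 || t0 >= 1440) stop("activity start must lie in [0, 1440)")
  data.frame(t0 = t0, duration = duration, hr_pct = hr_pct)
}

#' Assemble a one-day schedule of meals and activities
#'
#' @param meals data frame of meal events (rows from [meal_event()]).
#' @param activities data frame of activity events (rows from
#'   [activity_event()]); activities may not overlap one another.
#' @return A list of class `"day_schedule"` with sorted `meals` and
#'   `activities` data frames.
#' @export
day_schedule <- function(meals = NULL, activities = NULL) {
  meals <- if (is.null(meals) || nrow(as.data.frame(meals)) == 0L)
    data.frame(t0 = numeric(), DGS = numeric(), DGF = numeric())
  else as.data.frame(meals)[c("t0", "DGS", "DGF")]
  activities <- if (is.null(activities) ||
                    nrow(as.data.frame(activities)) == 0L)
    data.frame(t0 = numeric(), duration = numeric(), hr_pct = numeric())
  else as.data.frame(activities)[c("t0", "duration", "hr_pct")]
  meals <- meals[order(meals$t0), , drop = FALSE]
  activities <- activities[order(activities$t0), , drop = FALSE]
  rownames(meals) <- rownames(activities) <- NULL
  if (nrow(activities) > 1L) {
    ends <- activities$t0 + activities$duration
    if (any(activities$t0[-1L] < ends[-nrow(activities)] - 1e-9))
      stop("activity events may not overlap")
  }
  structure(list(meals = meals, activities = activities),
            class = "day_schedule")
}

#' @export
print.day_schedule <- function(x, ...) {
  cat("Day schedule:", nrow(x$meals), "meal(s),",
      nrow(x$activities), "activity event(s)\n")
  if (nrow(x$meals)) {
    cat("meals (t0 min, DGS g, DGF g):\n")
    print(x$meals, row.names = FALSE)
  }
  if (nrow(x$activities)) {
    cat("activities (t0 min, duration min, hr_pct %):\n")
    print(x$activities, row.names = FALSE)
  }
  invisible(x)
}

#' Read and write day schedules as CSV or JSON
#'
#' The CSV dialect has one row per event with columns
#' `kind` (`"meal"` or `"activity"`), `t0`, `duration`, `DGS`, `DGF`,
#' `hr_pct`; fields that do not apply to an event kind are left empty. The
#' JSON dialect is an object with `meals` and `activities` arrays. Both
#' round-trip exactly.
#'
#' @param schedule a [day_schedule()].
#' @param path file path.
#' @return Readers return a `"day_schedule"`; writers return `path`
#'   invisibly.
#' @export
write_schedule_csv <- function(schedule, path) {
  m <- schedule$meals
  a <- schedule$activities
  rows <- rbind(
    if (nrow(m)) data.frame(kind = "meal", t0 = m$t0, duration = NA_real_,
                            DGS = m$DGS, DGF = m$DGF, hr_pct = NA_real_),
    if (nrow(a)) data.frame(kind = "activity", t0 = a$t0,
                            duration = a$duration, DGS = NA_real_,
                            DGF = NA_real_, hr_pct = a$hr_pct))
  if (is.null(rows))
    rows <- data.frame(kind = character(), t0 = numeric(),
                       duration = numeric(), DGS = numeric(),
                       DGF = numeric(), hr_pct = numeric())
  write.csv(rows, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_schedule_csv
#' @export
read_schedule_csv <- function(path) {
  rows <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("kind", "t0")
  if (!all(need %in% names(rows)))
    stop("schedule CSV needs at least columns: ", paste(need, collapse = ", "))
  m <- rows[rows$kind == "meal", , drop = FALSE]
  a <- rows[rows$kind == "activity", , drop = FALSE]
  day_schedule(
    meals = if (nrow(m)) data.frame(t0 = m$t0,
                                    DGS = ifelse(is.na(m$DGS), 0, m$DGS),
                                    DGF = ifelse(is.na(m$DGF), 0, m$DGF)),
    activities = if (nrow(a)) data.frame(t0 = a$t0, duration = a$duration,
                                         hr_pct = a$hr_pct))
}

#' @rdname write_schedule_csv
#' @export
write_schedule_json <- function(schedule, path) {
  jsonlite::write_json(list(meals = schedule$meals,
                            activities = schedule$activities),
                       path, dataframe = "rows", digits = NA)
  invisible(path)
}

#' @rdname write_schedule_csv
#' @export
read_schedule_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  day_schedule(meals = doc$meals, activities = doc$activities)
}
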