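# Bundled example data: the 20-person activity-time records and the
# office-worker example day.

#' Activity-time records of the 20-person sample
#'
#' Occupation and daily hours spent above 1.5 MET for the 20 observed
#' participants, used to demonstrate the active/sedentary sectioning rule
#' (7 of the 20 classify as physically active).
#'
#' @return Data frame with columns `id`, `occupation`, `active_time`
#'   (hours/day above 1.5 MET).
#' @seealso [classify_cohort()]
#' @export
activity_time_records <- function() {
  read.csv(system.file("extdata", "activity_times_20.csv",
                       package = "glucosim"),
           stringsAsFactors = FALSE)
}

#' Example day of a home-office worker
#'
#' The worked single-subject example day: a work-from-home office worker with
#' four meals (47.6 g slow at 10:00, 41 g slow at 14:00, a 16.3 g snack at
#' 18:00, and 39.7 g at 21:00 split 16.8 g slow / 22.9 g fast) and a day of
#' desk work, domestic chores and two walks. The snack's absorption class
#' is ambiguous; it is encoded here as slow-only
#' (an apple and almonds). Activity intensities map the narrated activities
#' through the named-activity table.
#'
#' @return A [day_schedule()].
#' @export
office_worker_schedule <- function() {
  read_schedule_csv(system.file("extdata", "office_worker_day.csv",
                                package = "glucosim"))
}

#' Synthetic subject descriptor for the office-worker example
#'
#' The observed sample does not include this subject's anthropometrics;
#' this synthetic stand-in uses the 20-person sample means (female office
#' worker, 43 y, 1.68 m, 70 kg) with a basal glucose of 85 mg/dL.
#'
#' @return A [virtual_patient()].
#' @export
office_worker_subject <- function() {
  virtual_patient(sex = "female", lifestyle = "sedentary", age = 43,
                  height = 1.68, weight = 70, basal_glucose = 85,
                  cho_total = 144.6, n_meals = 4, hr_rest = 75,
                  id = "office_worker")
}
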