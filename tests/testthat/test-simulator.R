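test_that("an input-free day preserves the rest equilibrium to machine precision", {
  r <- simulate_day(day_schedule())
  expect_lt(max(abs(r$trace$G - r$params$Gb)), 1e-9)
  expect_lt(max(abs(r$trace$I - r$params$Ib)), 1e-9)
  for (nm in c("X", "Gprod", "Gup", "Ie", "PVO2max", "A", "Ggly"))
    expect_lt(max(abs(r$trace[[nm]])), 1e-9)
})

test_that("a single meal raises glucose transiently and returns toward basal", {
  sched <- day_schedule(meals = meal_event(600, DGS = 75))
  r <- simulate_day(sched)
  g <- r$trace$G
  expect_gt(max(g), r$params$Gb + 10)
  expect_gt(r$trace$t[which.max(g)], 600)
  expect_lt(abs(g[length(g)] - r$params$Gb), 5)
  expect_true(all(g > 0))
})

test_that("disabling exercise reduces the model to the three-state core", {
  sched <- office_worker_schedule()
  subj <- office_worker_subject()
  p <- subject_params(subj)
  r <- simulate_day(sched, params = p,
                    control = sim_control(no_exercise = TRUE))
  # exercise states stay identically zero
  for (nm in c("Gprod", "Gup", "Ie", "PVO2max", "A", "Ggly"))
    expect_lt(max(abs(r$trace[[nm]])), 1e-12)
  # and (I, X, G) match an independent fixed-step integration of the core
  ref <- bergman3_reference(sched, p)
  expect_lt(max(abs(r$trace$G - ref$G)), 0.01)
  expect_lt(max(abs(r$trace$I - ref$I)), 0.05)
})

test_that("the oxygen-consumption filter matches its step-response closed form", {
  p <- model_params()
  sched <- day_schedule(meals = meal_event(10, DGS = 1),
                        activities = activity_event(300, 120, hr_pct = 48))
  r <- simulate_day(sched, params = p)
  u_eff <- 48 - p$u_basal
  inside <- r$trace$t >= 300 & r$trace$t <= 420
  expected <- u_eff * (1 - exp(-0.8 * (r$trace$t[inside] - 300)))
  expect_lt(max(abs(r$trace$PVO2max[inside] - expected)), 1e-4)
  # and decays exponentially once the activity stops
  after <- r$trace$t > 420
  p_end <- u_eff * (1 - exp(-0.8 * 120))
  expect_lt(max(abs(r$trace$PVO2max[after] -
                    p_end * exp(-0.8 * (r$trace$t[after] - 420)))), 1e-4)
})

test_that("all exercise states relax to zero after activity ends", {
  sched <- day_schedule(meals = meal_event(600, DGS = 40),
                        activities = activity_event(610, 90, hr_pct = 45))
  r <- simulate_day(sched)
  last <- r$trace[nrow(r$trace), ]
  for (nm in c("Gprod", "Gup", "Ie", "PVO2max", "A", "Ggly"))
    expect_lt(abs(last[[nm]]), 1e-3)
})

test_that("the solution is insensitive to tightening solver tolerances", {
  sched <- office_worker_schedule()
  subj <- office_worker_subject()
  a <- simulate_day(sched, subject = subj,
                    control = sim_control(rtol = 1e-6, atol = 1e-6))
  b <- simulate_day(sched, subject = subj,
                    control = sim_control(rtol = 1e-9, atol = 1e-9))
  expect_lt(max(abs(a$trace$G - b$trace$G)), 0.1)
})

test_that("stronger exercise-induced insulin removal lowers insulin under load", {
  sched <- office_worker_schedule()
  subj <- office_worker_subject()
  # with the pancreatic release gain isolated off, the removal pathway is
  # the only force on insulin and doubling its gain can never raise I;
  # in closed loop the glucose-dependent release reshuffles the ordering
  lo <- simulate_day(sched, subject = subj,
                     params = model_params(gamma = 1e-15))
  hi <- simulate_day(sched, subject = subj,
                     params = model_params(gamma = 1e-15, a5 = 2 * 0.00125))
  expect_true(all(hi$trace$I <= lo$trace$I + 1e-9))
  expect_lt(min(hi$trace$I - lo$trace$I), -0.01)   # and it genuinely bites
})

test_that("peak glucose is monotone in the scheduled carbohydrate load", {
  set.seed(3)
  ctrl <- sim_control(no_exercise = TRUE)
  for (rep in 1:3) {
    t0 <- sort(round(runif(3, 480, 1200)))
    base <- data.frame(t0 = t0, DGS = runif(3, 20, 70),
                       DGF = runif(3, 0, 20))
    peaks <- vapply(c(1, 1.5, 2), function(f) {
      m <- base; m$DGS <- m$DGS * f; m$DGF <- m$DGF * f
      simulate_day(day_schedule(meals = m), control = ctrl)$summary$g_max
    }, numeric(1))
    expect_true(all(diff(peaks) > 0))
  }
})

test_that("glycemic summaries follow the counting contracts", {
  fake <- structure(list(
    trace = data.frame(t = 0:1440, G = 85, met = 1),
    control = sim_control()), class = "sim_result")
  s <- glycemic_summary(fake)
  expect_equal(s$g_min, 85)
  expect_equal(s$g_max, 85)
  expect_equal(s$g_mean, 85)
  expect_equal(s$time_below_70, 0)
  expect_equal(s$time_in_80_120, 1440)
  expect_equal(s$active_hours, 0)

  g <- rep(90, 1441); g[101:110] <- 65       # exactly 10 grid minutes low
  fake$trace$G <- g
  expect_equal(glycemic_summary(fake)$time_below_70, 10)

  # a basal-intensity day scores ~1.88 MET, above the 1.5 MET cutoff:
  # trace-based active hours read the full 24 h
  r <- simulate_day(day_schedule(), control = sim_control())
  expect_equal(r$summary$active_hours, 24)
})

test_that("simulation results serialize to tidy CSV plus JSON summary", {
  r <- simulate_day(day_schedule(meals = meal_event(600, DGS = 30)))
  stem <- withr::local_tempfile()
  paths <- write_sim_result(r, stem)
  tr <- read.csv(paths[["trace"]])
  expect_equal(nrow(tr), nrow(r$trace))
  expect_true(all(c("t", "I", "X", "G", "u", "d", "met") %in% names(tr)))
  s <- jsonlite::read_json(paths[["summary"]])
  expect_equal(s$g_max, r$summary$g_max)
})
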