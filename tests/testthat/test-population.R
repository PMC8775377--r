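test_that("generated patients respect bounds and identities", {
  set.seed(11)
  spec <- default_population_spec()
  for (key in names(spec$groups)) {
    parts <- strsplit(key, "_")[[1]]
    g <- spec$groups[[key]]
    for (i in 1:12) {
      p <- generate_patient(parts[2], parts[1], spec)
      expect_equal(p$bmi, p$weight / p$height^2, tolerance = 1e-12)
      expect_true(p$age >= 20 && p$age <= 75)
      expect_true(abs(p$age - g$age[1]) <= 3 * g$age[2])
      expect_true(abs(p$basal_glucose - g$basal_glucose[1]) <=
                    3 * g$basal_glucose[2])
      expect_true(p$basal_glucose > 60 && p$basal_glucose < 130)
      expect_true(abs(p$height - g$height[1]) <= 3 * g$height[2])
      expect_true(abs(p$cho_total - g$cho_total[1]) <= 3 * g$cho_total[2])
      expect_true(p$n_meals %in% 3:4)
      expect_lt(p$hr_rest, p$hr_max)
      expect_equal(p$hr_max, 220 - p$age)
    }
  }
})

test_that("a zero-variance spec degenerates to the configured group means", {
  spec <- default_population_spec()
  for (key in names(spec$groups))
    spec$groups[[key]] <- lapply(spec$groups[[key]],
                                 function(v) c(v[1], 0))
  spec$hr_rest <- c(75.4, 0)
  p <- generate_patient("male", "active", spec)
  g <- default_population_spec()$groups$active_male
  expect_identical(p$age, g$age[1])
  expect_identical(p$height, g$height[1])
  expect_identical(p$bmi, g$bmi[1])
  expect_identical(p$basal_glucose, g$basal_glucose[1])
  expect_identical(p$cho_total, g$cho_total[1])
  expect_equal(p$weight, g$bmi[1] * g$height[1]^2)
})

test_that("sample moments recover the configured distributions", {
  set.seed(202)
  deck <- generate_population(c(active_male = 2000))
  g <- default_population_spec()$groups$active_male
  n <- nrow(deck)
  for (f in c("age", "basal_glucose", "bmi", "cho_total", "height")) {
    # compare against the closed-form truncated-normal moments implied by
    # the generator's bounds (age's floor at 20 y truncates asymmetrically)
    b <- generator_bounds(f, g[[f]])
    mo <- tnorm_moments(g[[f]][1], g[[f]][2], b[1], b[2])
    expect_lt(abs(mean(deck[[f]]) - mo["mean"]), 3 * mo["sd"] / sqrt(n))
    expect_lt(abs(sd(deck[[f]]) - mo["sd"]) / mo["sd"], 0.05)
  }
})

test_that("identical seeds reproduce the deck bit for bit", {
  a <- generate_population(c(active_female = 25, sedentary_male = 25),
                           seed = 77)
  b <- generate_population(c(active_female = 25, sedentary_male = 25),
                           seed = 77)
  expect_identical(a, b)
})

test_that("rejection sampling reports exhausted truncation bounds", {
  expect_error(glucosim:::rtrunc_norm(5, 0, 1, 50, 51),
               "exhausted")
  expect_error(glucosim:::rtrunc_norm(1, 0, 0, 2, 3), "outside")
})

test_that("generated schedules honor the meal and activity contracts", {
  set.seed(31)
  deck <- generate_population(c(active_male = 4, sedentary_female = 4),
                              seed = 31)
  for (i in seq_len(nrow(deck))) {
    p <- as_patient(deck[i, , drop = FALSE])
    s <- generate_schedule(p)
    expect_equal(nrow(s$meals), p$n_meals)
    expect_equal(sum(s$meals$DGS + s$meals$DGF), p$cho_total,
                 tolerance = 1e-8)
    expect_equal(nrow(s$activities), 5)
    # every activity starts within 3 h after some meal onset
    for (t0 in s$activities$t0) {
      lag <- t0 - s$meals$t0
      expect_true(any(lag >= 0 & lag <= 180))
    }
    # no overlap (already enforced by day_schedule, asserted explicitly)
    ends <- s$activities$t0 + s$activities$duration
    expect_true(all(s$activities$t0[-1] >= ends[-5]))
  }
})

test_that("sedentary schedules keep oxygen consumption in the 8-30% band", {
  set.seed(53)
  p <- generate_patient("female", "sedentary")
  minutes_in <- 0; minutes_tot <- 0
  for (i in 1:50) {
    s <- generate_schedule(p)
    minutes_tot <- minutes_tot + sum(s$activities$duration)
    sel <- s$activities$hr_pct >= 8 & s$activities$hr_pct <= 30
    minutes_in <- minutes_in + sum(s$activities$duration[sel])
  }
  expect_gte(minutes_in / minutes_tot, 0.95)
})

test_that("the 8-hour rule classifies the documented boundary cases", {
  expect_equal(classify_lifestyle(14.78), "active")
  expect_equal(classify_lifestyle(6.12), "sedentary")
  expect_equal(classify_lifestyle(8.16), "active")
  expect_equal(classify_lifestyle(8), "active")      # boundary is active
  expect_error(classify_lifestyle(25), "0, 24")
  expect_error(classify_lifestyle(-1), "0, 24")
})

test_that("the observed 20-person sample splits 7 active / 13 sedentary", {
  rec <- activity_time_records()
  expect_equal(nrow(rec), 20)
  out <- classify_cohort(rec)
  expect_equal(unname(out$counts["active"]), 7L)
  expect_equal(unname(out$counts["sedentary"]), 13L)
  expect_equal(classify_cohort(data.frame(active_time = rep(24, 5)))$counts,
               c(active = 5L, sedentary = 0L))
  expect_equal(classify_cohort(data.frame(active_time = rep(0, 5)))$counts,
               c(active = 0L, sedentary = 5L))
})

test_that("MET-hours integrate the above-cutoff indicator", {
  expect_equal(met_hours(rep(0, 1440)), 0)       # MET(0) ~ 1.32 < 1.5
  expect_equal(met_hours(rep(89.26, 1440)), 24)
  u <- rep(0, 1440); u[1:360] <- 50              # 6 h at ~6.9 MET
  expect_equal(met_hours(u), 6)
})

test_that("generated schedules classify coherently with their lifestyle group", {
  set.seed(99)
  hits <- 0
  for (i in 1:30) {
    p <- generate_patient("male", "active")
    if (schedule_active_hours(generate_schedule(p)) >= 8) hits <- hits + 1
  }
  expect_gte(hits / 30, 0.9)
  hits <- 0
  for (i in 1:30) {
    p <- generate_patient("female", "sedentary")
    if (schedule_active_hours(generate_schedule(p)) < 8) hits <- hits + 1
  }
  expect_gte(hits / 30, 0.9)
})
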