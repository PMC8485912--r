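test_that("MPG takes the in-window maximum with half-open truncation", {
  # flat trace: the peak is the flat value
  trace <- flat_trace(5)
  meal <- as.POSIXct("2020-03-01 12:00:00", tz = "UTC")
  expect_equal(compute_mpg(trace, meal)$mpg, 5.0)

  # meal at 12:00, next at 14:00; the global max 7.0 sits at 14:30, outside
  # the truncated window, whose own max is 6.1
  h <- seq(0, 24, by = 0.25)
  g <- rep(5, length(h))
  g[h == 14.5] <- 7.0
  g[h == 13.0] <- 6.1
  trace <- fun_trace(function(hh) g[match(hh, h)])
  next_meal <- as.POSIXct("2020-03-01 14:00:00", tz = "UTC")
  # brute-force expectation over the enumerated window samples
  in_window <- h >= 12 & h < 14
  expect_equal(max(g[in_window]), 6.1)
  res <- compute_mpg(trace, meal, next_meal)
  expect_equal(res$mpg, 6.1)
  expect_equal(res$window_end, next_meal)
  # a sample exactly at the next meal's start belongs to the next meal
  g2 <- g
  g2[h == 14.0] <- 9.0
  trace2 <- fun_trace(function(hh) g2[match(hh, h)])
  expect_equal(compute_mpg(trace2, meal, next_meal)$mpg, 6.1)
  # without truncation the 3-h window is used
  expect_equal(compute_mpg(trace2, meal)$mpg, 9.0)
})

test_that("meal metrics skip missed meals and flag empty windows", {
  trace <- flat_trace(5)
  meals <- tibble::tibble(
    participant_id = "P01", date = as.Date("2020-03-01"),
    slot = c("breakfast", "lunch", "dinner"),
    time = c("08:00", "12:00", "18:00"),
    consumed = c(TRUE, FALSE, TRUE))
  mm <- compute_meal_metrics(trace, meals)
  expect_equal(nrow(mm), 2L) # no row for the missed lunch
  expect_false("lunch" %in% mm$slot)
  # a meal whose window has no CGM data yields NA with a warning
  gap <- trace[nof1cgm:::hours_of_day(trace$timestamp) < 17.9, ]
  expect_warning(mm2 <- compute_meal_metrics(gap, meals),
                 "no CGM sample")
  expect_true(is.na(mm2$mpg[mm2$slot == "dinner"]))
})

test_that("MAGE handles constant, sinusoidal and two-bump fixtures", {
  expect_true(is.na(compute_mage(rep(5, 96))))
  expect_true(is.na(compute_mage(c(5, 5.1))))

  # 6-h period sinusoid sampled at 15 min: every excursion has amplitude 4
  g <- 5 + 2 * sin(2 * pi * seq(0, 23.75, by = 0.25) / 6)
  expect_equal(compute_mage(g), 4.0)
  expect_equal(mage_oracle(g), 4.0)

  # two bumps: only the 3.0 bump exceeds the daily SD
  h <- seq(0, 23.75, by = 0.25)
  bump <- function(hh, center, amp, width = 1) {
    amp * pmax(0, 1 - abs(hh - center) / width)
  }
  g2 <- 5 + bump(h, 8, 3) + bump(h, 18, 0.3)
  expect_lt(sd(g2), 3)
  expect_gt(sd(g2), 0.3)
  expect_equal(compute_mage(g2), 3.0)
  expect_equal(compute_mage(g2), mage_oracle(g2))
})

test_that("MAGE equals the brute-force turning-point oracle on random traces", {
  withr::local_seed(424)
  for (i in 1:1000) {
    g <- random_trace_values(sample(10:40, 1))
    expect_identical(compute_mage(g), mage_oracle(g))
  }
})

test_that("single-direction MAGE restricts to the first qualifying direction", {
  # descending 3.0 first, then ascending 2.5: "both" averages them,
  # "ascending" (first-direction) keeps only descents here
  g <- c(5, 8, 5, 7.5, 5, 5, 5, 5, 5, 5, 5, 5)
  both <- compute_mage(g)
  one <- compute_mage(g, direction = "ascending")
  # turning points 8, 5, 7.5; amplitudes 3 and 2.5, SD ~1.3
  expect_equal(both, mean(c(3, 2.5)))
  expect_equal(one, 3)
})

test_that("AUC24 integrates the day with exact boundary handling", {
  # constant day, closing midnight sample present: 5 * 24
  trace <- flat_trace(5)
  h <- as.numeric(trace$timestamp - trace$timestamp[1], units = "hours")
  expect_equal(compute_auc24(h, trace$glucose), 120)
  # linear ramp 4 -> 6 across the day: trapezoid symmetry gives 120
  ramp <- fun_trace(function(hh) 4 + 2 * hh / 24)
  hr <- as.numeric(ramp$timestamp - ramp$timestamp[1], units = "hours")
  expect_equal(compute_auc24(hr, ramp$glucose), 120)
  # irregular toy series vs the independent trapezoid computation, with the
  # edge values extended to the day boundaries
  ht <- c(0.5, 2, 5, 7.25, 9, 13.5, 16, 19, 21.75, 23.5)
  gt <- c(4.4, 4.6, 5.4, 7.2, 5.1, 6.3, 5.0, 6.8, 5.2, 4.7)
  expected <- trapz_oracle(c(0, ht, 24), c(gt[1], gt, gt[10]))
  expect_equal(compute_auc24(ht, gt), expected)
  # single sample is not integrable
  expect_true(is.na(compute_auc24(12, 5)))
  expect_error(compute_auc24(c(1, 25), c(5, 5)), "\\[0, 24\\]")
})

test_that("AUC24 is linear in a constant offset", {
  withr::local_seed(7)
  h <- sort(runif(40, 0, 24))
  g <- 5 + cumsum(rnorm(40, 0, 0.2))
  expect_equal(compute_auc24(h, g + 1.5), compute_auc24(h, g) + 24 * 1.5,
               tolerance = 1e-9)
})

test_that("MPG is invariant under super-sampling of a noise-free trace", {
  design <- generate_design(1, n_sets = 1, seed = 51)
  meals <- generate_meal_log(design)
  prof <- list(participant_id = "P01", baseline_glucose = 4.5,
               circadian_amplitude = 0.3, meal_response_base = 2.0,
               diet_effect_mpg = 0.4, carb_dose_slope = 0, noise_sd = 0,
               ar1_rho = 0)
  trace <- simulate_trace(prof, design, meals)
  mm <- compute_meal_metrics(trace, meals)
  # add linearly interpolated midpoints: never above the sampled max
  mid <- tibble::tibble(
    participant_id = "P01",
    timestamp = trace$timestamp[-nrow(trace)] + 450,
    glucose = (trace$glucose[-1] + trace$glucose[-nrow(trace)]) / 2)
  dense <- dplyr::arrange(dplyr::bind_rows(trace, mid), timestamp)
  mm2 <- compute_meal_metrics(dense, meals)
  expect_equal(mm2$mpg, mm$mpg, tolerance = 1e-12)
})

test_that("metric values are unchanged by shifting all timestamps a day", {
  design <- generate_design(1, n_sets = 1, seed = 52)
  meals <- generate_meal_log(design)
  prof <- list(participant_id = "P01", baseline_glucose = 4.5,
               circadian_amplitude = 0.3, meal_response_base = 2.0,
               diet_effect_mpg = 0.3, carb_dose_slope = 0, noise_sd = 0.2,
               ar1_rho = 0.5)
  trace <- simulate_trace(prof, design, meals, seed = 5)
  dm <- compute_daily_metrics(trace, meals)
  shift_trace <- dplyr::mutate(trace, timestamp = timestamp + 86400)
  shift_meals <- dplyr::mutate(meals, date = date + 1)
  dm2 <- compute_daily_metrics(shift_trace, shift_meals)
  expect_equal(dm2$date, dm$date + 1)
  expect_equal(dm2$mage, dm$mage)
  expect_equal(dm2$auc24, dm$auc24)
})

test_that("outcome series counts, exclusions and labelling are correct", {
  design <- generate_design(1, seed = 53)
  meals <- generate_meal_log(design)
  prof <- list(participant_id = "P01", baseline_glucose = 4.5,
               circadian_amplitude = 0.3, meal_response_base = 2.0,
               diet_effect_mpg = 0.3, carb_dose_slope = 0, noise_sd = 0.2,
               ar1_rho = 0.5)
  trace <- simulate_trace(prof, design, meals, seed = 6)
  mm <- compute_meal_metrics(trace, meals)
  dm <- compute_daily_metrics(trace, meals, meal_metrics = mm)
  ser <- build_outcome_series(mm, dm, design)
  mpg <- ser[ser$outcome == "MPG", ]
  # complete 6-period participant: 54 observations per arm
  expect_equal(sum(mpg$treatment == 0), 54L)
  expect_equal(sum(mpg$treatment == 1), 54L)
  expect_setequal(unique(mpg$carb_pct), c(15, 25, 65, 75))
  # washout days never enter any series
  cal <- design_calendar(design)
  washout_days <- cal$date[cal$diet == "washout"]
  expect_false(any(ser$date %in% washout_days))

  # a fully-missed intervention day drops MAGE/AUC24 for that day only
  iv_day <- cal$date[cal$diet != "washout"][2]
  meals2 <- dplyr::mutate(meals, consumed = consumed & date != iv_day)
  trace2 <- simulate_trace(prof, design, meals2, seed = 6)
  mm2 <- compute_meal_metrics(trace2, meals2)
  dm2 <- compute_daily_metrics(trace2, meals2, meal_metrics = mm2)
  ser2 <- build_outcome_series(mm2, dm2, design)
  mage2 <- ser2[ser2$outcome == "MAGE", ]
  expect_false(iv_day %in% mage2$date)
  expect_equal(nrow(mage2), 35L) # 36 intervention days minus the missed one
  # the day is absent because n_valid_meals is 0, not because of coverage
  expect_equal(dm2$n_valid_meals[dm2$date == iv_day], 0L)

  # observations outside the design calendar are rejected
  stray <- dplyr::mutate(mm[1, ], date = max(cal$date) + 30)
  expect_error(build_outcome_series(dplyr::bind_rows(mm, stray), dm, design),
               "outside any design period")
})

test_that("days below the coverage minimum yield no MAGE or AUC24", {
  trace <- flat_trace(5)
  # keep only 4 hours of samples (coverage ~0.17)
  sparse <- trace[nof1cgm:::hours_of_day(trace$timestamp) < 4 &
                    nof1cgm:::ts_date(trace$timestamp) == as.Date("2020-03-01"), ]
  meals <- tibble::tibble(participant_id = "P01",
                          date = as.Date("2020-03-01"),
                          slot = "breakfast", time = "08:00", consumed = TRUE)
  dm <- suppressWarnings(compute_daily_metrics(sparse, meals))
  expect_true(is.na(dm$auc24))
  expect_lt(dm$coverage_fraction, 0.7)
})
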