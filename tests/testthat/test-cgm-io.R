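test_that("unit conversion uses the 18.0 divisor and is an involution", {
  expect_equal(convert_glucose(90, "mg/dL", "mmol/L"), 5.0)
  # the three conventional meaningful-difference thresholds, to 3 decimals
  expect_equal(round(convert_glucose(3, "mg/dL", "mmol/L"), 3), 0.167)
  expect_equal(round(convert_glucose(1.3, "mg/dL", "mmol/L"), 3), 0.072)
  expect_equal(round(convert_glucose(15000 / 60, "mg/dL", "mmol/L"), 3), 13.889)
  x <- c(3.9, 5.55, 10.001, 29.9)
  back <- convert_glucose(convert_glucose(x, "mmol/L", "mg/dL"),
                          "mg/dL", "mmol/L")
  expect_equal(back, x, tolerance = 1e-12)
})

test_that("read_cgm normalizes units and sorts deterministically", {
  df <- tibble::tibble(
    participant_id = c("B", "A", "A", "B"),
    timestamp = c("2020-03-01 08:15", "2020-03-01 08:15",
                  "2020-03-01 08:00", "2020-03-01 08:00"),
    glucose = c(90, 5.2, 5.0, 108),
    unit = c("mg/dL", "mmol/L", "mmol/L", "mg/dL"))
  path <- write_temp_csv(df)
  out <- read_cgm(path, unit_hint = "auto")
  expect_equal(out$participant_id, c("A", "A", "B", "B"))
  expect_equal(out$glucose, c(5.0, 5.2, 6.0, 5.0))
  # shuffled input rows give the identical result
  path2 <- write_temp_csv(df[c(3, 1, 4, 2), ])
  expect_equal(read_cgm(path2, unit_hint = "auto"), out)
})

test_that("read_cgm rejects malformed input with named rows", {
  base <- tibble::tibble(participant_id = "A",
                         timestamp = "2020-03-01 08:00", glucose = 5)
  bad_ts <- base
  bad_ts$timestamp <- "yesterday-ish"
  expect_error(read_cgm(write_temp_csv(bad_ts), "mmol/L"),
               "unparseable timestamp in row 1")
  neg <- base
  neg$glucose <- -1
  expect_error(read_cgm(write_temp_csv(neg), "mmol/L"), "negative glucose")
  dup <- dplyr::bind_rows(base, base)
  expect_error(read_cgm(write_temp_csv(dup), "mmol/L"),
               "duplicate timestamp")
  # auto unit detection never guesses silently
  expect_error(read_cgm(write_temp_csv(base), "auto"), "refusing to guess")
  bad_unit <- dplyr::mutate(base, unit = "mg%")
  expect_error(read_cgm(write_temp_csv(bad_unit), "auto"), "unknown glucose unit")
  out_of_range <- dplyr::mutate(base, glucose = 35)
  expect_error(read_cgm(write_temp_csv(out_of_range), "mmol/L"),
               "physiological range")
})

test_that("empty CGM file yields an empty collection with a warning", {
  path <- write_temp_csv(tibble::tibble(participant_id = character(),
                                        timestamp = character(),
                                        glucose = numeric()))
  expect_warning(out <- read_cgm(path, "mmol/L"), "empty")
  expect_equal(nrow(out), 0L)
})

test_that("Libre-style exports are mapped onto the canonical schema", {
  df <- tibble::tibble(
    `Serial Number` = "SN123",
    `Device Timestamp` = c("2020-03-01 08:00", "2020-03-01 08:15"),
    `Record Type` = 0,
    `Historic Glucose mg/dL` = c(90, 99))
  out <- read_cgm_libre(write_temp_csv(df), participant_id = "P01")
  expect_equal(out$participant_id, c("P01", "P01"))
  expect_equal(out$glucose, c(5.0, 5.5))
})

test_that("meal log validation enforces slots, duplicates and calendars", {
  meals <- tibble::tibble(
    participant_id = "A", date = as.Date("2020-03-01"),
    slot = c("breakfast", "lunch", "dinner"),
    time = c("08:00", "12:00", "18:00"), consumed = TRUE)
  out <- read_meal_log(write_temp_csv(meals))
  expect_equal(nrow(out), 3L)

  snack <- dplyr::mutate(meals[1, ], slot = "snack")
  expect_error(read_meal_log(write_temp_csv(dplyr::bind_rows(meals, snack))),
               "invalid meal slot 'snack'")
  expect_error(read_meal_log(write_temp_csv(meals[c(1, 1, 2, 3), ])),
               "duplicate meal row")
  # missing slots: error without a design, filled as not-consumed with one
  partial <- meals[1:2, ]
  expect_error(read_meal_log(write_temp_csv(partial)),
               "supply `design`")
  design <- generate_design(1, n_sets = 1, participant_ids = "A",
                            start_date = as.Date("2020-02-24"), seed = 1)
  full <- read_meal_log(write_temp_csv(partial), design = design)
  expect_equal(sum(full$consumed), 2L)
  expect_equal(nrow(full), 3L * 24L) # every calendar day completed
  day1 <- full[full$date == as.Date("2020-03-01"), ]
  expect_equal(day1$consumed[day1$slot == "dinner"], FALSE)
})

test_that("meal schedule windows are enforced when requested", {
  meals <- tibble::tibble(
    participant_id = "A", date = as.Date("2020-03-01"),
    slot = c("breakfast", "lunch", "dinner"),
    time = c("08:00", "14:30", "18:00"), consumed = TRUE)
  expect_error(read_meal_log(write_temp_csv(meals), validate_schedule = TRUE),
               "outside the lunch window")
})

test_that("a complete 6-day period carries 18 consumed meal events", {
  design <- generate_design(1, n_sets = 1, participant_ids = "A", seed = 2)
  meals <- generate_meal_log(design)
  cal <- design_calendar(design)
  one_period <- cal[cal$diet != "washout" & cal$period == 2, ]
  in_period <- meals[meals$date %in% one_period$date, ]
  expect_equal(nrow(in_period), 18L)
  expect_true(all(in_period$consumed))
})

test_that("design validation rejects malformed crossover structures", {
  design <- generate_design(2, seed = 3)
  expect_silent(validate_design(design))
  # two LF-HC periods within one set
  broken <- design
  rows <- broken$participant_id == "P01" & broken$set == 1 &
    broken$diet %in% c("LF-HC", "HF-LC")
  broken$diet[rows] <- "LF-HC"
  expect_error(validate_design(broken), "exactly one LF-HC and one HF-LC")
  # macronutrients must close to 100 with protein at 15
  bad_macro <- design
  bad_macro$fat_pct[1] <- bad_macro$fat_pct[1] + 5
  expect_error(validate_design(bad_macro), "100")
  # a 3-day intervention period
  short <- design[!(design$participant_id == "P01" & design$set == 1 &
                      design$period == 2 & design$carb_pct %in% c(75, 15)), ]
  expect_error(validate_design(short), "not 6 days")
})

test_that("the realized whole-study diet order of the trial validates", {
  # LF-HC, HF-LC | HF-LC, LF-HC | HF-LC, LF-HC with interspersed washouts
  orders <- list(c("LF-HC", "HF-LC"), c("HF-LC", "LF-HC"), c("HF-LC", "LF-HC"))
  rows <- list()
  cursor <- as.Date("2019-10-21")
  for (s in 1:3) {
    for (k in 1:2) {
      rows[[length(rows) + 1]] <- tibble::tibble(
        participant_id = "P01", set = s, period = 2L * k - 1L,
        diet = "washout", carb_pct = 55, fat_pct = 30,
        start_date = cursor, days = 6L)
      cursor <- cursor + 6
      d <- orders[[s]][k]
      carb <- if (d == "LF-HC") c(65, 75) else c(25, 15)
      rows[[length(rows) + 1]] <- tibble::tibble(
        participant_id = "P01", set = s, period = 2L * k,
        diet = d, carb_pct = carb, fat_pct = 85 - carb,
        start_date = cursor + c(0, 3), days = 3L)
      cursor <- cursor + 6
    }
  }
  expect_silent(validate_design(dplyr::bind_rows(rows)))
})

test_that("result tables round-trip through CSV to at least 6 decimals", {
  posterior <- tibble::tibble(
    participant_id = c("P01", "P02"), outcome = "MPG",
    beta_mean = c(0.1234567891, -0.9876543219),
    p_below = c(0.001234567, 0.87654321),
    p_above = c(0.998765432, 0.12345678))
  dir <- withr::local_tempdir()
  manifest <- write_results(list(posterior = posterior), dir,
                            config = list(a = 1), seed = 42L)
  expect_true(file.exists(file.path(dir, "manifest.json")))
  expect_equal(manifest$tables$posterior, 2L)
  back <- readr::read_csv(file.path(dir, "posterior.csv"),
                          show_col_types = FALSE)
  expect_equal(back$beta_mean, posterior$beta_mean, tolerance = 1e-9)
  expect_equal(back$p_above, posterior$p_above, tolerance = 1e-9)
  # manifest hash is stable for identical configs
  dir2 <- withr::local_tempdir()
  manifest2 <- write_results(list(posterior = posterior), dir2,
                             config = list(a = 1), seed = 42L)
  expect_equal(manifest$config_hash, manifest2$config_hash)
})
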