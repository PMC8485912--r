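#' Specify a synthetic n-of-1 CGM cohort
#'
#' Bundles the generative settings for a complete synthetic cohort: a
#' block-randomized crossover design (per set one low-fat/high-carbohydrate
#' and one high-fat/low-carbohydrate 6-day period, washouts interspersed),
#' meal logs, 15-minute CGM traces and participant metadata. Defaults emulate
#' a cohort of 30 healthy young adults, of whom two withdraw early so 28
#' contribute complete data, with a (9, 6, 13)/28 mixture of
#' high-carbohydrate responders, high-fat responders and nonresponders.
#'
#' The trace model is
#' `baseline + circadian + sum(meal excursions) + AR(1) noise`, where each
#' consumed meal contributes a unimodal excursion peaking 45 minutes after the
#' first bite and decaying to zero by 3 hours. The diet effect enters as a
#' shift of the excursion peak height during LF-HC periods (not of the basal
#' level), so peak-sensitive outcomes (MPG, MAGE) respond while AUC24
#' responds only weakly.
#'
#' @param n_participants Cohort size.
#' @param n_sets Intervention sets per participant (each one LF-HC and one
#'   HF-LC period).
#' @param days_per_period Days per intervention period.
#' @param meals_per_day Scheduled meals per day.
#' @param mixture Named proportions `c(HC=, HF=, non=)` of responder classes;
#'   must sum to 1. Class counts are allocated exactly (largest remainder).
#' @param effect_hc,effect_hf True LF-HC minus HF-LC shift of the post-meal
#'   excursion peak (mmol/L) for HC- and HF-responders; nonresponders get 0.
#' @param baseline_glucose Basal glucose, mmol/L.
#' @param circadian_amplitude Amplitude of the 24-h sinusoidal baseline
#'   modulation, mmol/L.
#' @param meal_response_base Excursion peak height on the HF-LC diet, mmol/L.
#' @param carb_dose_slope Optional linear dose-response: extra peak height per
#'   carbohydrate percent of energy above 15 (mmol/L per %E). Default 0 (off).
#' @param noise_sd Stationary standard deviation of the AR(1) sensor noise,
#'   mmol/L.
#' @param ar1_rho Lag-1 autocorrelation of the sensor noise at 15-min spacing.
#' @param missing_meal_prob Probability that a scheduled meal is missed.
#' @param n_withdrawals Participants who withdraw early (complete only 1-2
#'   sets).
#' @param n_low_valid Completing participants given a long sensor failure so
#'   their valid-data fraction drops below 50%.
#' @param n_flagged Completing participants flagged for chronic disease or
#'   medication use.
#' @param start_date First study day (leading washout).
#' @param seed Integer seed; every stochastic draw in cohort generation flows
#'   from it.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_participants = 30L, n_sets = 3L,
                        days_per_period = 6L, meals_per_day = 3L,
                        mixture = c(HC = 9, HF = 6, non = 13) / 28,
                        effect_hc = 0.3, effect_hf = -0.3,
                        baseline_glucose = 4.5, circadian_amplitude = 0.3,
                        meal_response_base = 2.0, carb_dose_slope = 0,
                        noise_sd = 0.3, ar1_rho = 0.7,
                        missing_meal_prob = 0.02,
                        n_withdrawals = 2L, n_low_valid = 1L, n_flagged = 1L,
                        start_date = as.Date("2019-10-21"), seed = 20191020L) {
  assert_scalar_number(n_participants, "n_participants", 1)
  assert_scalar_number(n_sets, "n_sets", 1)
  assert_scalar_number(noise_sd, "noise_sd", 0)
  assert_scalar_number(ar1_rho, "ar1_rho", 0, 1 - 1e-9)
  assert_scalar_number(missing_meal_prob, "missing_meal_prob", 0, 1)
  if (abs(sum(mixture) - 1) > 1e-9) {
    stop_validation("responder mixture proportions must sum to 1")
  }
  if (!all(c("HC", "HF", "non") %in% names(mixture))) {
    stop_validation("mixture must be named with HC, HF and non")
  }
  if (n_withdrawals + n_low_valid + n_flagged > n_participants) {
    stop_validation("withdrawal/flag counts exceed the cohort size")
  }
  structure(list(
    n_participants = as.integer(n_participants), n_sets = as.integer(n_sets),
    days_per_period = as.integer(days_per_period),
    meals_per_day = as.integer(meals_per_day),
    mixture = mixture, effect_hc = effect_hc, effect_hf = effect_hf,
    baseline_glucose = baseline_glucose,
    circadian_amplitude = circadian_amplitude,
    meal_response_base = meal_response_base,
    carb_dose_slope = carb_dose_slope,
    noise_sd = noise_sd, ar1_rho = ar1_rho,
    missing_meal_prob = missing_meal_prob,
    n_withdrawals = as.integer(n_withdrawals),
    n_low_valid = as.integer(n_low_valid), n_flagged = as.integer(n_flagged),
    start_date = as.Date(start_date), seed = as.integer(seed)),
    class = "cohort_spec")
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf("Synthetic cohort spec: %d participants, %d sets x 2 periods x %d days, %d meals/day\n",
              x$n_participants, x$n_sets, x$days_per_period, x$meals_per_day))
  cat(sprintf("  responder mixture HC/HF/non: %s\n",
              paste(signif(x$mixture, 3), collapse = "/")))
  cat(sprintf("  effects %+.2f/%+.2f mmol/L, noise sd %.2f (AR1 rho %.2f), missing meal prob %.3f\n",
              x$effect_hc, x$effect_hf, x$noise_sd, x$ar1_rho,
              x$missing_meal_prob))
  invisible(x)
}

# Exact class counts by largest remainder, so a (9,6,13)/28 mixture over 28
# participants yields exactly 9, 6 and 13.
mixture_counts <- function(mixture, n) {
  raw <- mixture * n
  counts <- floor(raw)
  left <- n - sum(counts)
  if (left > 0) {
    add <- order(raw - counts, decreasing = TRUE)[seq_len(left)]
    counts[add] <- counts[add] + 1
  }
  as.integer(counts)
}

#' Draw participant-level generative profiles
#'
#' Assigns each participant a responder class (exact counts from the mixture,
#' order shuffled) and jittered physiological parameters: fasting baseline in
#' the normoglycemic 3.5-6.0 mmol/L band, circadian amplitude and excursion
#' height around the spec values.
#'
#' @param spec A [cohort_spec()].
#' @param seed Integer seed (defaults to a stream derived from `spec$seed`).
#' @return Tibble with one row per participant: identifiers, responder label,
#'   true `diet_effect_mpg` and the trace-model parameters.
#' @export
generate_profiles <- function(spec, seed = child_seed(spec$seed, 1L)) {
  local_seed_if(seed)
  n <- spec$n_participants
  counts <- mixture_counts(spec$mixture, n)
  labels <- sample(rep(c("HC-responder", "HF-responder", "nonresponder"),
                       counts))
  effect <- c("HC-responder" = spec$effect_hc, "HF-responder" = spec$effect_hf,
              "nonresponder" = 0)[labels]
  tibble::tibble(
    participant_id = sprintf("P%02d", seq_len(n)),
    responder_label = labels,
    diet_effect_mpg = unname(effect),
    baseline_glucose = pmin(6, pmax(3.5, rnorm(n, spec$baseline_glucose, 0.25))),
    circadian_amplitude = pmax(0.05, rnorm(n, spec$circadian_amplitude, 0.05)),
    meal_response_base = pmax(0.5, rnorm(n, spec$meal_response_base, 0.2)),
    carb_dose_slope = spec$carb_dose_slope,
    noise_sd = spec$noise_sd,
    ar1_rho = spec$ar1_rho,
    missing_meal_prob = spec$missing_meal_prob)
}

# Macronutrient sub-compositions: each 6-day intervention period carries two
# 3-day segments; washouts are a single 6-day segment.
DIET_SEGMENTS <- list(
  "LF-HC" = data.frame(carb_pct = c(65, 75), fat_pct = c(20, 10)),
  "HF-LC" = data.frame(carb_pct = c(25, 15), fat_pct = c(60, 70)),
  "washout" = data.frame(carb_pct = 55, fat_pct = 30))

#' Generate a block-randomized crossover design
#'
#' Each participant receives, per set, a 6-day washout followed by one LF-HC
#' and one HF-LC 6-day period in random order (block size 2), with a second
#' washout between the pair. Within an intervention period, days 1-3 and 4-6
#' carry the two sub-compositions (LF-HC 65/75 %E carbohydrate; HF-LC
#' 25/15 %E; washout 55 %E; protein fixed at 15 %E).
#'
#' @param n_participants Number of participants, or a [cohort_spec()].
#' @param n_sets Sets per participant (ignored when a spec is given).
#' @param days_per_period Days per intervention period.
#' @param start_date First washout day.
#' @param participant_ids Optional identifiers (default `P01`, `P02`, ...).
#' @param seed Integer seed.
#' @return Validated design tibble in the [read_design()] schema.
#' @export
generate_design <- function(n_participants, n_sets = 3L, days_per_period = 6L,
                            start_date = as.Date("2019-10-21"),
                            participant_ids = NULL, seed = NULL) {
  if (inherits(n_participants, "cohort_spec")) {
    spec <- n_participants
    n_participants <- spec$n_participants
    n_sets <- spec$n_sets
    days_per_period <- spec$days_per_period
    start_date <- spec$start_date
    seed <- seed %||% child_seed(spec$seed, 2L)
  }
  local_seed_if(seed)
  ids <- participant_ids %||% sprintf("P%02d", seq_len(n_participants))
  dpp <- as.integer(days_per_period)
  half <- dpp %/% 2L
  # per set: washout | diet1 (2 segments) | washout | diet2 (2 segments)
  seg_period <- c(1L, 2L, 2L, 3L, 4L, 4L)
  seg_offset <- c(0L, dpp, dpp + half, 2L * dpp, 3L * dpp, 3L * dpp + half)
  seg_days <- c(dpp, half, dpp - half, dpp, half, dpp - half)
  seg_slot <- c(0L, 1L, 1L, 0L, 2L, 2L) # 0 washout, 1 first diet, 2 second
  seg_sub <- c(1L, 1L, 2L, 1L, 1L, 2L)  # sub-composition index within diet

  lfhc_first <- matrix(runif(n_participants * n_sets) < 0.5,
                       n_participants, n_sets)
  grid <- expand.grid(k = seq_along(seg_period), set = seq_len(n_sets),
                      p = seq_len(n_participants))
  first_diet <- ifelse(lfhc_first[cbind(grid$p, grid$set)], "LF-HC", "HF-LC")
  second_diet <- ifelse(lfhc_first[cbind(grid$p, grid$set)], "HF-LC", "LF-HC")
  diet <- rep("washout", nrow(grid))
  diet[seg_slot[grid$k] == 1L] <- first_diet[seg_slot[grid$k] == 1L]
  diet[seg_slot[grid$k] == 2L] <- second_diet[seg_slot[grid$k] == 2L]
  sub <- seg_sub[grid$k]
  carb <- ifelse(diet == "washout", 55,
                 ifelse(diet == "LF-HC", ifelse(sub == 1L, 65, 75),
                        ifelse(sub == 1L, 25, 15)))
  out <- tibble::tibble(
    participant_id = ids[grid$p],
    set = as.integer(grid$set),
    period = seg_period[grid$k],
    diet = diet,
    carb_pct = carb,
    fat_pct = 85 - carb,
    start_date = as.Date(start_date) +
      (grid$set - 1L) * 4L * dpp + seg_offset[grid$k],
    days = seg_days[grid$k])
  validate_design(out)
}

#' Generate a fully adherent meal log for a design
#'
#' Three meals per calendar day at the scheduled first-bite times (08:00,
#' 12:00, 18:00), all marked consumed. Missingness is layered on afterwards
#' by [inject_missingness()].
#'
#' @param design Design tibble.
#' @return Meal-log tibble (`participant_id, date, slot, time, consumed`).
#' @export
generate_meal_log <- function(design) {
  cal <- design_calendar(design)
  days <- dplyr::distinct(cal, .data$participant_id, .data$date)
  out <- tidyr::crossing(days, slot = MEAL_SLOTS)
  out$time <- default_meal_time(out$slot)
  out$consumed <- TRUE
  out$slot <- factor(out$slot, levels = MEAL_SLOTS)
  out <- dplyr::arrange(out, .data$participant_id, .data$date, .data$slot)
  out$slot <- as.character(out$slot)
  out
}

# Post-meal excursion kernel on hours since first bite: rises to 1 at 45 min
# and returns to exactly 0 at 3 h (gamma-shaped pulse, floor-shifted so the
# support is compact and non-overlapping meals stay strictly additive-free).
meal_kernel <- function(u) {
  p <- u / 0.75
  raw <- ifelse(u > 0 & u < 3, p^3 * exp(3 * (1 - p)), 0)
  c3 <- 4^3 * exp(-9)
  pmax(0, raw - c3) / (1 - c3)
}

#' Simulate a CGM trace for one participant
#'
#' Produces a 15-minute grid over the participant's whole design calendar
#' (plus the closing midnight sample, so every day has both boundary
#' readings). Glucose is baseline + a 24-h sinusoid + the sum of meal
#' excursions + stationary AR(1) noise. The excursion peak height is
#' `meal_response_base`, raised by the participant's `diet_effect_mpg` on
#' LF-HC days and, when dose-response mode is on, by
#' `carb_dose_slope * (carb%E - 15)`. Missed meals contribute no excursion;
#' overlapping kernels are summed.
#'
#' @param profile One-row profile (as from [generate_profiles()]), or a list
#'   with the same fields.
#' @param design Design tibble (may contain several participants; the
#'   profile's rows are selected).
#' @param meal_log Meal-log tibble.
#' @param seed Integer seed for the noise stream.
#' @return CGM tibble `participant_id, timestamp, glucose` (mmol/L).
#' @export
simulate_trace <- function(profile, design, meal_log, seed = NULL) {
  local_seed_if(seed)
  profile <- as.list(profile)
  pid <- profile$participant_id
  cal <- design_calendar(design[design$participant_id == pid, , drop = FALSE])
  meals <- meal_log[meal_log$participant_id == pid, , drop = FALSE]
  if (!all(cal$date %in% meals$date)) {
    stop_validation("meal log does not cover all design days for participant %s", pid)
  }
  t0 <- as.POSIXct(paste(min(cal$date), "00:00:00"), tz = "UTC")
  t1 <- as.POSIXct(paste(max(cal$date) + 1L, "00:00:00"), tz = "UTC")
  grid <- seq(t0, t1, by = 900)
  hod <- (as.numeric(grid - t0, units = "hours") +
            hours_of_day(t0[1])) %% 24
  g <- profile$baseline_glucose +
    profile$circadian_amplitude * sin(2 * pi * (hod - 10) / 24)

  meals <- dplyr::inner_join(meals, cal, by = c("participant_id", "date"))
  meals <- meals[meals$consumed, , drop = FALSE]
  if (nrow(meals)) {
    amp <- profile$meal_response_base +
      profile$diet_effect_mpg * (meals$diet == "LF-HC") +
      (profile$carb_dose_slope %||% 0) *
        ifelse(meals$diet == "washout", 0, meals$carb_pct - 15)
    meal_dt <- as.POSIXct(paste(meals$date, meals$time), tz = "UTC")
    for (m in seq_len(nrow(meals))) {
      off_h <- as.numeric(meal_dt[m] - t0, units = "hours")
      i0 <- floor(off_h * 4) + 1L
      idx <- i0:(i0 + 13L)
      idx <- idx[idx >= 1L & idx <= length(grid)]
      u <- as.numeric(grid[idx] - meal_dt[m], units = "hours")
      g[idx] <- g[idx] + amp[m] * meal_kernel(u)
    }
  }
  if (profile$noise_sd > 0) {
    w <- rnorm(length(grid), 0, profile$noise_sd * sqrt(1 - profile$ar1_rho^2))
    e <- as.numeric(stats::filter(w, profile$ar1_rho, method = "recursive",
                                  init = rnorm(1, 0, profile$noise_sd)))
    g <- g + e
  }
  tibble::tibble(participant_id = pid, timestamp = grid,
                 glucose = pmin(29.9, pmax(0.1, g)))
}

#' Inject meal missingness and sensor dropout
#'
#' Flips `consumed` flags to `FALSE` independently with probability
#' `missing_meal_prob` and, optionally, deletes contiguous CGM windows to
#' emulate sensor failure.
#'
#' @param cgm CGM tibble.
#' @param meal_log Meal-log tibble.
#' @param missing_meal_prob Per-meal miss probability.
#' @param sensor_dropout Optional list `list(n_windows=, duration_hours=)`;
#'   windows are placed uniformly over each participant's trace.
#' @param seed Integer seed.
#' @return List with elements `cgm` and `meals`.
#' @export
inject_missingness <- function(cgm, meal_log, missing_meal_prob,
                               sensor_dropout = NULL, seed = NULL) {
  local_seed_if(seed)
  assert_scalar_number(missing_meal_prob, "missing_meal_prob", 0, 1)
  meals <- meal_log
  if (missing_meal_prob > 0) {
    flip <- runif(nrow(meals)) < missing_meal_prob
    meals$consumed <- meals$consumed & !flip
  }
  if (!is.null(sensor_dropout) && sensor_dropout$n_windows > 0) {
    keep <- rep(TRUE, nrow(cgm))
    for (pid in unique(cgm$participant_id)) {
      rows <- which(cgm$participant_id == pid)
      span <- range(cgm$timestamp[rows])
      for (w in seq_len(sensor_dropout$n_windows)) {
        start <- span[1] + runif(1) * as.numeric(span[2] - span[1], units = "secs")
        end <- start + sensor_dropout$duration_hours * 3600
        keep[rows] <- keep[rows] &
          !(cgm$timestamp[rows] >= start & cgm$timestamp[rows] < end)
      }
    }
    cgm <- cgm[keep, , drop = FALSE]
  }
  list(cgm = cgm, meals = meals)
}

#' Generate a complete synthetic cohort
#'
#' Produces every artifact the analysis consumes -- design, meal log, CGM
#' traces, participant metadata -- plus a ground-truth table of the
#' generative profiles for parameter-recovery testing. Early withdrawals are
#' emulated by truncating a participant's design after 1 or 2 completed sets;
#' a low-validity participant receives a long sensor failure; flagged
#' participants carry the chronic-disease/medication marker. Deterministic
#' given `spec$seed`.
#'
#' @param spec A [cohort_spec()].
#' @param out_dir Optional directory; when given, all tables are written as
#'   CSV (plus `truth.csv` and a manifest) via [write_results()].
#' @return List with tibbles `design`, `meals`, `cgm`, `meta`, `truth`.
#' @export
generate_cohort <- function(spec, out_dir = NULL) {
  profiles <- generate_profiles(spec)
  design <- generate_design(spec)
  ids <- sprintf("P%02d", seq_len(spec$n_participants))

  withr::local_seed(child_seed(spec$seed, 3L))
  special <- sample(ids, spec$n_withdrawals + spec$n_low_valid + spec$n_flagged)
  withdrawn <- head(special, spec$n_withdrawals)
  low_valid <- head(tail(special, -spec$n_withdrawals), spec$n_low_valid)
  flagged <- tail(special, spec$n_flagged)
  sets_completed <- stats::setNames(rep(spec$n_sets, length(ids)), ids)
  if (length(withdrawn)) {
    sets_completed[withdrawn] <- rep(c(1L, 2L), length.out = length(withdrawn))
  }
  design <- design[design$set <= sets_completed[design$participant_id], ,
                   drop = FALSE]
  meals <- generate_meal_log(design)

  traces <- vector("list", length(ids))
  meal_parts <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    prof <- profiles[i, ]
    tr <- simulate_trace(prof, design, meals,
                         seed = child_seed(spec$seed, 100L + i))
    ml <- meals[meals$participant_id == ids[i], , drop = FALSE]
    dropout <- if (ids[i] %in% low_valid) {
      # one long sensor failure: drops usable data below half the meals
      list(n_windows = 1L,
           duration_hours = 0.62 * as.numeric(
             diff(range(tr$timestamp)), units = "hours"))
    } else {
      NULL
    }
    inj <- inject_missingness(tr, ml, spec$missing_meal_prob,
                              sensor_dropout = dropout,
                              seed = child_seed(spec$seed, 500L + i))
    traces[[i]] <- inj$cgm
    meal_parts[[i]] <- inj$meals
  }
  cgm <- dplyr::bind_rows(traces)
  meals <- dplyr::bind_rows(meal_parts)

  withr::local_seed(child_seed(spec$seed, 4L))
  n <- length(ids)
  meta <- tibble::tibble(
    participant_id = ids,
    age = sample(22:34, n, replace = TRUE),
    sex = ifelse(runif(n) < 0.32, "M", "F"),
    bmi = round(pmin(32, pmax(17.2, rnorm(n, 22.5, 3))), 1),
    completed_all_periods = !(ids %in% withdrawn),
    valid_data_fraction = NA_real_,
    chronic_disease_or_medication = ids %in% flagged)
  vf <- compute_valid_fraction(cgm, meals, design)
  meta$valid_data_fraction <- unname(vf[meta$participant_id])

  truth <- dplyr::mutate(profiles,
                         withdrew_early = .data$participant_id %in% withdrawn,
                         low_valid_data = .data$participant_id %in% low_valid)
  out <- list(design = design, meals = meals, cgm = cgm, meta = meta,
              truth = truth)
  if (!is.null(out_dir)) {
    write_results(out, out_dir, config = unclass(spec), seed = spec$seed)
  }
  out
}

# Share of offered intervention meals that were consumed and have at least
# one CGM sample in their MPG window, per participant (named vector).
compute_valid_fraction <- function(cgm, meals, design) {
  cal <- design_calendar(design)
  iv_days <- cal[cal$diet != "washout", c("participant_id", "date")]
  mm <- dplyr::inner_join(meals, iv_days, by = c("participant_id", "date"))
  metrics <- suppressWarnings(compute_meal_metrics(cgm, mm))
  n_valid <- dplyr::summarise(dplyr::group_by(metrics, .data$participant_id),
                              n_valid = sum(!is.na(.data$mpg)),
                              .groups = "drop")
  res <- dplyr::left_join(dplyr::count(mm, .data$participant_id,
                                       name = "offered"),
                          n_valid, by = "participant_id")
  res$n_valid[is.na(res$n_valid)] <- 0L
  stats::setNames(res$n_valid / res$offered, res$participant_id)
}
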