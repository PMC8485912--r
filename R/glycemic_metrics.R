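#' Maximum postprandial glucose for a single meal
#'
#' MPG is the maximum CGM reading in the half-open window from the meal's
#' first bite to 3 hours later, truncated at the next meal's first bite when
#' the gap is shorter than 3 hours (a sample exactly at the next meal's start
#' belongs to the next meal). Ties take the earliest timestamp.
#'
#' @param trace Tibble with `timestamp` (POSIXct) and `glucose` columns for
#'   one participant.
#' @param meal_time POSIXct first-bite time of the meal.
#' @param next_meal_time Optional POSIXct first-bite time of the following
#'   meal.
#' @return List with `mpg` (mmol/L, `NA` if no sample falls in the window),
#'   `peak_time`, `window_start`, `window_end`.
#' @export
compute_mpg <- function(trace, meal_time, next_meal_time = NULL) {
  window_end <- meal_time + 3 * 3600
  if (!is.null(next_meal_time) && !is.na(next_meal_time)) {
    window_end <- min(window_end, next_meal_time)
  }
  sel <- trace$timestamp >= meal_time & trace$timestamp < window_end
  if (!any(sel)) {
    return(list(mpg = NA_real_, peak_time = parse_timestamp(NA),
                window_start = meal_time, window_end = window_end))
  }
  g <- trace$glucose[sel]
  ts <- trace$timestamp[sel]
  i <- which.max(g) # which.max returns the earliest tie
  list(mpg = g[i], peak_time = ts[i],
       window_start = meal_time, window_end = window_end)
}

#' Per-meal MPG metrics for a cohort
#'
#' Emits one row per *consumed* meal (data from missed meals are not used).
#' Meals whose window contains no CGM sample get `mpg = NA` and are counted
#' against the participant's valid-data fraction.
#'
#' @param cgm CGM tibble (`participant_id, timestamp, glucose`).
#' @param meals Meal-log tibble (`participant_id, date, slot, time, consumed`).
#' @return Tibble `participant_id, date, slot, time, mpg, window_start,
#'   window_end`.
#' @export
compute_meal_metrics <- function(cgm, meals) {
  meals <- meals[meals$consumed, , drop = FALSE]
  if (!nrow(meals)) {
    return(tibble::tibble(participant_id = character(), date = as.Date(integer()),
                          slot = character(), time = character(),
                          mpg = numeric(),
                          window_start = parse_timestamp(character()),
                          window_end = parse_timestamp(character())))
  }
  meals$meal_dt <- as.POSIXct(paste(meals$date, meals$time), tz = "UTC")
  meals <- dplyr::arrange(meals, .data$participant_id, .data$meal_dt)
  out <- vector("list", length(unique(meals$participant_id)))
  k <- 0L
  for (pid in unique(meals$participant_id)) {
    mm <- meals[meals$participant_id == pid, , drop = FALSE]
    tr <- cgm[cgm$participant_id == pid, , drop = FALSE]
    ts_num <- as.numeric(tr$timestamp)
    starts <- as.numeric(mm$meal_dt)
    nexts <- c(starts[-1], Inf)
    ends <- pmin(starts + 3 * 3600, nexts)
    # half-open window [start, end): indices via binary search
    i_lo <- findInterval(starts - 1e-6, ts_num) + 1L
    i_hi <- findInterval(ends - 1e-6, ts_num)
    mpg <- rep(NA_real_, nrow(mm))
    for (m in seq_len(nrow(mm))) {
      if (i_lo[m] <= i_hi[m]) mpg[m] <- max(tr$glucose[i_lo[m]:i_hi[m]])
    }
    k <- k + 1L
    out[[k]] <- tibble::tibble(
      participant_id = pid, date = mm$date, slot = mm$slot, time = mm$time,
      mpg = mpg,
      window_start = as.POSIXct(starts, origin = "1970-01-01", tz = "UTC"),
      window_end = as.POSIXct(ends, origin = "1970-01-01", tz = "UTC"))
  }
  res <- dplyr::bind_rows(out[seq_len(k)])
  n_missing <- sum(is.na(res$mpg))
  if (n_missing > 0) {
    rlang::warn(sprintf("%d consumed meal(s) have no CGM sample in their MPG window", n_missing))
  }
  res
}

#' Mean amplitude of glycemic excursions for one day of readings
#'
#' Implements the turning-point definition: (1) the day's sample standard
#' deviation (n-1 denominator) is computed from all readings; (2) plateaus
#' are collapsed and local maxima/minima located at strict sign changes of
#' successive differences; (3) amplitudes between consecutive turning points
#' qualify when they exceed `sd_mult` standard deviations; (4) MAGE is the
#' arithmetic mean of qualifying absolute amplitudes. Returns `NA` when fewer
#' than 3 readings are available or no excursion qualifies (including the
#' constant-trace case, where no turning point exists).
#'
#' @param glucose Numeric vector of one calendar day's readings in time order.
#' @param sd_mult Multiplier of the daily SD an excursion must exceed
#'   (default 1).
#' @param direction `"both"` counts every qualifying peak-nadir and
#'   nadir-peak amplitude; `"ascending"` restricts to the direction of the
#'   first qualifying excursion (the classic single-direction convention).
#' @param smooth Apply a 3-point running median before turning-point
#'   detection (off by default).
#' @return MAGE in mmol/L, or `NA_real_`.
#' @export
compute_mage <- function(glucose, sd_mult = 1,
                         direction = c("both", "ascending"), smooth = FALSE) {
  direction <- match.arg(direction)
  g <- glucose[!is.na(glucose)]
  if (length(g) < 3L) return(NA_real_)
  if (smooth) g <- as.numeric(stats::runmed(g, 3))
  s <- stats::sd(g)
  v <- g[c(TRUE, diff(g) != 0)] # collapse plateaus to a single point
  if (length(v) < 3L) return(NA_real_)
  d <- diff(v)
  turn <- which(d[-length(d)] * d[-1L] < 0) + 1L
  if (length(turn) < 2L) return(NA_real_)
  amps <- diff(v[turn])
  if (direction == "ascending") {
    qual <- abs(amps) > sd_mult * s
    if (!any(qual)) return(NA_real_)
    first_sign <- sign(amps[which(qual)[1L]])
    amps <- amps[sign(amps) == first_sign]
  }
  q <- abs(amps)[abs(amps) > sd_mult * s]
  if (!length(q)) return(NA_real_)
  mean(q)
}

#' 24-hour area under the glucose curve
#'
#' Trapezoidal integral of glucose against time over 00:00-24:00 of one
#' calendar day, in mmol/L·h. When the first or last reading does not sit on
#' a day boundary, the boundary value is carried from the nearest reading
#' (constant extension); passing the next day's midnight sample as the last
#' point makes the right boundary exact.
#'
#' @param hours Numeric sample times in hours since the day's midnight
#'   (values in `[0, 24]`).
#' @param glucose Matching glucose readings, mmol/L.
#' @return AUC24 in mmol/L·h, or `NA_real_` with fewer than 2 samples.
#' @export
compute_auc24 <- function(hours, glucose) {
  ok <- !is.na(hours) & !is.na(glucose)
  h <- hours[ok]
  g <- glucose[ok]
  if (length(h) < 2L) return(NA_real_)
  if (any(h < 0 | h > 24)) stop_validation("sample hours must lie in [0, 24]")
  o <- order(h)
  h <- h[o]
  g <- g[o]
  if (h[1L] > 0) {
    h <- c(0, h)
    g <- c(g[1L], g)
  }
  n <- length(h)
  if (h[n] < 24) {
    h <- c(h, 24)
    g <- c(g, g[n])
  }
  sum(diff(h) * (head(g, -1L) + tail(g, -1L)) / 2)
}

#' Day-level metrics (MAGE, AUC24, coverage) for a cohort
#'
#' Computes per participant-day MAGE and AUC24 together with the number of
#' valid meals (consumed meals with at least one CGM sample in their MPG
#' window) and the coverage fraction (observed samples out of the 96 expected
#' at 15-min spacing). MAGE/AUC24 are set missing below the coverage minimum
#' or on fully-missed days (`n_valid_meals == 0`).
#'
#' @param cgm CGM tibble.
#' @param meals Meal-log tibble.
#' @param coverage_min Minimum coverage fraction for a day to yield MAGE and
#'   AUC24 (default 0.7).
#' @param meal_metrics Optional precomputed output of
#'   [compute_meal_metrics()] to avoid recomputation.
#' @param mage_direction,mage_smooth Passed to [compute_mage()].
#' @return Tibble `participant_id, date, mage, auc24, n_valid_meals,
#'   coverage_fraction`.
#' @export
compute_daily_metrics <- function(cgm, meals, coverage_min = 0.7,
                                  meal_metrics = NULL,
                                  mage_direction = "both",
                                  mage_smooth = FALSE) {
  if (is.null(meal_metrics)) {
    meal_metrics <- suppressWarnings(compute_meal_metrics(cgm, meals))
  }
  valid_by_day <- dplyr::summarise(
    dplyr::group_by(meal_metrics, .data$participant_id, .data$date),
    n_valid_meals = sum(!is.na(.data$mpg)), .groups = "drop")
  days <- dplyr::distinct(meals, .data$participant_id, .data$date)
  days <- dplyr::left_join(days, valid_by_day,
                           by = c("participant_id", "date"))
  days$n_valid_meals[is.na(days$n_valid_meals)] <- 0L

  res <- vector("list", nrow(days))
  for (pid in unique(days$participant_id)) {
    tr <- cgm[cgm$participant_id == pid, , drop = FALSE]
    ts_num <- as.numeric(tr$timestamp)
    rows <- which(days$participant_id == pid)
    for (r in rows) {
      d <- days$date[r]
      day_start <- as.numeric(as.POSIXct(paste(d, "00:00:00"), tz = "UTC"))
      # include the closing midnight sample as the right AUC boundary
      i_lo <- findInterval(day_start - 1e-6, ts_num) + 1L
      i_hi <- findInterval(day_start + 86400 + 1e-6, ts_num)
      if (i_lo > i_hi) {
        res[[r]] <- tibble::tibble(participant_id = pid, date = d,
                                   mage = NA_real_, auc24 = NA_real_,
                                   n_valid_meals = days$n_valid_meals[r],
                                   coverage_fraction = 0)
        next
      }
      h <- (ts_num[i_lo:i_hi] - day_start) / 3600
      g <- tr$glucose[i_lo:i_hi]
      in_day <- h < 24 # coverage counts only the day's own 96 grid slots
      coverage <- sum(in_day) / 96
      if (coverage >= coverage_min && days$n_valid_meals[r] > 0L) {
        mage <- compute_mage(g[in_day], direction = mage_direction,
                             smooth = mage_smooth)
        auc <- compute_auc24(h, g)
      } else {
        mage <- NA_real_
        auc <- NA_real_
      }
      res[[r]] <- tibble::tibble(participant_id = pid, date = d,
                                 mage = mage, auc24 = auc,
                                 n_valid_meals = days$n_valid_meals[r],
                                 coverage_fraction = coverage)
    }
  }
  dplyr::arrange(dplyr::bind_rows(res), .data$participant_id, .data$date)
}

#' Assemble treatment-labelled outcome series
#'
#' Builds the observation series the Bayesian models consume: one MPG
#' observation per consumed meal with valid CGM, and one MAGE and AUC24
#' observation per intervention day that is not fully missed. Washout days
#' are excluded. Every observation carries the treatment indicator
#' (HF-LC = 0, LF-HC = 1), the set index and the day's carbohydrate percent
#' of energy.
#'
#' @param meal_metrics Output of [compute_meal_metrics()].
#' @param daily_metrics Output of [compute_daily_metrics()].
#' @param design Validated design tibble.
#' @return Tibble `participant_id, outcome, value, treatment, diet, set,
#'   carb_pct, date, slot`.
#' @export
build_outcome_series <- function(meal_metrics, daily_metrics, design) {
  cal <- design_calendar(design)
  check_in_calendar <- function(x, what) {
    j <- dplyr::anti_join(x, cal, by = c("participant_id", "date"))
    if (nrow(j)) {
      stop_validation("%s observation dated outside any design period: participant %s on %s",
                      what, j$participant_id[1L], j$date[1L])
    }
  }
  check_in_calendar(meal_metrics, "meal")
  check_in_calendar(daily_metrics, "day")

  mm <- dplyr::inner_join(meal_metrics, cal, by = c("participant_id", "date"))
  mm <- mm[mm$diet != "washout" & !is.na(mm$mpg), , drop = FALSE]
  mpg <- tibble::tibble(participant_id = mm$participant_id, outcome = "MPG",
                        value = mm$mpg,
                        treatment = as.integer(mm$diet == "LF-HC"),
                        diet = mm$diet, set = mm$set, carb_pct = mm$carb_pct,
                        date = mm$date, slot = mm$slot)

  dm <- dplyr::inner_join(daily_metrics, cal, by = c("participant_id", "date"))
  dm <- dm[dm$diet != "washout" & dm$n_valid_meals > 0L, , drop = FALSE]
  day_series <- function(col, name) {
    keep <- !is.na(dm[[col]])
    tibble::tibble(participant_id = dm$participant_id[keep], outcome = name,
                   value = dm[[col]][keep],
                   treatment = as.integer(dm$diet[keep] == "LF-HC"),
                   diet = dm$diet[keep], set = dm$set[keep],
                   carb_pct = dm$carb_pct[keep], date = dm$date[keep],
                   slot = NA_character_)
  }
  out <- dplyr::bind_rows(mpg, day_series("mage", "MAGE"),
                          day_series("auc24", "AUC24"))
  dplyr::arrange(out, .data$participant_id, .data$outcome, .data$date)
}
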