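#' @title Reading and validating study artifacts
#' @description
#' On-disk artifacts are plain CSV files with headers:
#' \describe{
#'   \item{cgm.csv}{`participant_id, timestamp, glucose, unit`}
#'   \item{meals.csv}{`participant_id, date, slot, time, consumed`}
#'   \item{design.csv}{`participant_id, set, period, diet, carb_pct, fat_pct,
#'     start_date, days`}
#'   \item{meta.csv}{`participant_id, age, sex, bmi, completed_all_periods,
#'     valid_data_fraction, chronic_disease_or_medication`}
#' }
#' All readers return tibbles sorted deterministically (participant, then
#' time), independent of input row order. Glucose is always normalized to
#' mmol/L on read.
#' @name cgm_io
NULL

MEAL_SLOTS <- c("breakfast", "lunch", "dinner")

# Scheduled first-bite windows (hours of day) for each meal slot.
MEAL_WINDOWS <- list(breakfast = c(7, 9), lunch = c(11, 13), dinner = c(17, 19))

DIET_LABELS <- c("LF-HC", "HF-LC", "washout")

read_csv_quiet <- function(path, col_types) {
  if (!file.exists(path)) stop_format("file not found: %s", path)
  readr::read_csv(path, col_types = col_types, progress = FALSE,
                  show_col_types = FALSE)
}

#' Read CGM traces from a canonical CSV file
#'
#' Reads `participant_id, timestamp, glucose` (plus an optional `unit` column)
#' and returns one row per reading with glucose in mmol/L. Rows are sorted per
#' participant by timestamp regardless of input order; duplicate timestamps
#' within a participant are rejected.
#'
#' @param path CSV file path.
#' @param unit_hint `"mmol/L"`, `"mg/dL"`, or `"auto"`. Under `"auto"` the
#'   file must carry a `unit` column; the unit is never guessed from the
#'   magnitude of the values.
#' @return Tibble with columns `participant_id` (character), `timestamp`
#'   (POSIXct, timezone-naive local time), `glucose` (mmol/L).
#' @export
read_cgm <- function(path, unit_hint = c("auto", "mmol/L", "mg/dL")) {
  unit_hint <- match.arg(unit_hint)
  raw <- read_csv_quiet(path, readr::cols(.default = readr::col_character()))
  if (nrow(raw) == 0L) {
    rlang::warn(sprintf("CGM file is empty: %s", path))
    return(tibble::tibble(participant_id = character(),
                          timestamp = parse_timestamp(character()),
                          glucose = numeric()))
  }
  need <- c("participant_id", "timestamp", "glucose")
  miss <- setdiff(need, names(raw))
  if (length(miss)) stop_format("cgm file missing column(s): %s",
                                paste(miss, collapse = ", "))
  ts <- parse_timestamp(raw$timestamp)
  if (anyNA(ts)) {
    bad <- which(is.na(ts))[1L]
    stop_format("unparseable timestamp in row %d: '%s'", bad,
                raw$timestamp[bad])
  }
  glucose <- suppressWarnings(as.numeric(raw$glucose))
  if (anyNA(glucose)) {
    bad <- which(is.na(glucose))[1L]
    stop_format("non-numeric glucose in row %d: '%s'", bad, raw$glucose[bad])
  }
  if (any(glucose < 0)) {
    bad <- which(glucose < 0)[1L]
    stop_validation("negative glucose in row %d: %s", bad, glucose[bad])
  }
  unit <- resolve_units(raw, unit_hint, nrow(raw))
  mmol <- ifelse(unit == "mg/dL", glucose / MGDL_PER_MMOL, glucose)
  out <- tibble::tibble(participant_id = raw$participant_id,
                        timestamp = ts, glucose = mmol)
  out <- dplyr::arrange(out, .data$participant_id, .data$timestamp)
  dup <- duplicated(out[, c("participant_id", "timestamp")])
  if (any(dup)) {
    d <- out[dup, ][1L, ]
    stop_validation("duplicate timestamp for participant %s at %s",
                    d$participant_id, format_timestamp(d$timestamp))
  }
  if (any(out$glucose <= 0 | out$glucose >= 30)) {
    stop_validation("glucose outside the physiological range (0, 30) mmol/L after unit normalization")
  }
  out
}

resolve_units <- function(raw, unit_hint, n) {
  if (unit_hint != "auto") return(rep(unit_hint, n))
  if (!"unit" %in% names(raw)) {
    stop_format("unit_hint = 'auto' requires a 'unit' column; refusing to guess units from value magnitudes")
  }
  unit <- raw$unit
  ok <- unit %in% c("mmol/L", "mg/dL")
  if (!all(ok)) {
    stop_format("unknown glucose unit '%s' in row %d", unit[!ok][1L],
                which(!ok)[1L])
  }
  unit
}

#' Read a FreeStyle-Libre-style CGM export
#'
#' Best-effort convenience reader for the wide export dialect of Libre-type
#' devices (extra columns, `Device Timestamp`, a
#' `Historic Glucose mmol/L` or `Historic Glucose mg/dL` column). Maps onto
#' the canonical schema and then applies the same validation as [read_cgm()].
#'
#' @param path CSV file path.
#' @param participant_id Identifier to assign (Libre exports are per-sensor
#'   files without a participant column); defaults to the `Serial Number`
#'   column when present.
#' @return Tibble in the canonical CGM schema (glucose in mmol/L).
#' @export
read_cgm_libre <- function(path, participant_id = NULL) {
  raw <- read_csv_quiet(path, readr::cols(.default = readr::col_character()))
  ts_col <- intersect(c("Device Timestamp", "Meter Timestamp", "timestamp"),
                      names(raw))[1L]
  if (is.na(ts_col)) stop_format("no device timestamp column found in %s", path)
  glu_cols <- grep("Glucose", names(raw), value = TRUE)
  if (!length(glu_cols)) stop_format("no glucose column found in %s", path)
  glu_col <- glu_cols[1L]
  unit <- if (grepl("mg/dL", glu_col)) "mg/dL" else "mmol/L"
  if (is.null(participant_id)) {
    participant_id <- if ("Serial Number" %in% names(raw)) {
      raw$`Serial Number`
    } else {
      stop_format("supply `participant_id`: export has no Serial Number column")
    }
  }
  keep <- !is.na(raw[[glu_col]]) & raw[[glu_col]] != ""
  pid <- if (length(participant_id) == 1L) rep(participant_id, sum(keep)) else participant_id[keep]
  tmp <- tibble::tibble(participant_id = pid,
                        timestamp = raw[[ts_col]][keep],
                        glucose = raw[[glu_col]][keep],
                        unit = unit)
  f <- tempfile(fileext = ".csv")
  on.exit(unlink(f), add = TRUE)
  readr::write_csv(tmp, f, progress = FALSE)
  read_cgm(f, unit_hint = "auto")
}

#' Read a meal log
#'
#' One row per participant-day-slot with a `consumed` flag. Duplicate
#' participant-day-slot rows and slot labels outside
#' breakfast/lunch/dinner are rejected. Slots absent from the file are
#' interpreted as not consumed only when a design is supplied (so the
#' expected calendar is known); otherwise an error is raised.
#'
#' @param path CSV file path (`participant_id, date, slot, time, consumed`).
#' @param design Optional design tibble from [read_design()] or
#'   [generate_design()]; enables completion of missing slots.
#' @param validate_schedule If `TRUE`, first-bite times outside the scheduled
#'   window for their slot (breakfast 07:00-09:00, lunch 11:00-13:00, dinner
#'   17:00-19:00) raise an error.
#' @return Tibble `participant_id, date, slot, time, consumed`, sorted by
#'   participant, date and slot order.
#' @export
read_meal_log <- function(path, design = NULL, validate_schedule = FALSE) {
  raw <- read_csv_quiet(path, readr::cols(
    participant_id = readr::col_character(),
    date = readr::col_date(),
    slot = readr::col_character(),
    time = readr::col_character(),
    consumed = readr::col_logical()))
  validate_meal_log(raw, design = design, validate_schedule = validate_schedule)
}

validate_meal_log <- function(meals, design = NULL, validate_schedule = FALSE) {
  bad_slot <- !meals$slot %in% MEAL_SLOTS
  if (any(bad_slot)) {
    stop_validation("invalid meal slot '%s' (row %d); slots must be one of %s",
                    meals$slot[bad_slot][1L], which(bad_slot)[1L],
                    paste(MEAL_SLOTS, collapse = "/"))
  }
  key <- paste(meals$participant_id, meals$date, meals$slot)
  if (anyDuplicated(key)) {
    d <- meals[duplicated(key), ][1L, ]
    stop_validation("duplicate meal row for participant %s on %s (%s)",
                    d$participant_id, d$date, d$slot)
  }
  if (validate_schedule) {
    hh <- vapply(strsplit(meals$time, ":"), function(p) {
      as.numeric(p[1]) + as.numeric(p[2]) / 60
    }, numeric(1))
    for (s in MEAL_SLOTS) {
      w <- MEAL_WINDOWS[[s]]
      off <- meals$slot == s & (hh < w[1] | hh > w[2])
      if (any(off)) {
        d <- meals[off, ][1L, ]
        stop_validation("first-bite time %s outside the %s window for participant %s on %s",
                        d$time, s, d$participant_id, d$date)
      }
    }
  }
  out <- meals
  if (!is.null(design)) {
    cal <- design_calendar(design)
    expected <- tidyr::crossing(
      dplyr::distinct(cal, .data$participant_id, .data$date),
      slot = MEAL_SLOTS)
    out <- dplyr::left_join(expected, meals,
                            by = c("participant_id", "date", "slot"))
    filled <- is.na(out$consumed)
    out$consumed[filled] <- FALSE
    out$time[filled] <- default_meal_time(out$slot[filled])
  } else {
    n_slots <- dplyr::count(meals, .data$participant_id, .data$date)
    if (any(n_slots$n < length(MEAL_SLOTS))) {
      d <- n_slots[n_slots$n < 3L, ][1L, ]
      stop_validation("participant %s has only %d meal rows on %s; supply `design` to interpret absent slots as not consumed",
                      d$participant_id, d$n, d$date)
    }
  }
  out$slot <- factor(out$slot, levels = MEAL_SLOTS)
  out <- dplyr::arrange(out, .data$participant_id, .data$date, .data$slot)
  out$slot <- as.character(out$slot)
  out
}

default_meal_time <- function(slot) {
  c(breakfast = "08:00", lunch = "12:00", dinner = "18:00")[slot]
}

#' Read a study design table
#'
#' The design is stored as one row per diet *segment*: washout periods are a
#' single 6-day segment, intervention periods are two 3-day segments (the two
#' sub-compositions of the 6-day period) sharing a period index. Validates the
#' crossover structure: within each set exactly one LF-HC and one HF-LC
#' period, intervention periods 6 days long, and carbohydrate + fat + 15
#' (protein) percent of energy summing to 100.
#'
#' @param path CSV file path.
#' @return Validated design tibble.
#' @export
read_design <- function(path) {
  raw <- read_csv_quiet(path, readr::cols(
    participant_id = readr::col_character(),
    set = readr::col_integer(),
    period = readr::col_integer(),
    diet = readr::col_character(),
    carb_pct = readr::col_double(),
    fat_pct = readr::col_double(),
    start_date = readr::col_date(),
    days = readr::col_integer()))
  validate_design(raw)
}

#' Validate a study design tibble
#'
#' @param design Design tibble in the [read_design()] schema.
#' @return The design, sorted by participant and start date, invisibly usable.
#' @export
validate_design <- function(design) {
  bad <- !design$diet %in% DIET_LABELS
  if (any(bad)) {
    stop_validation("unknown diet label '%s' for participant %s",
                    design$diet[bad][1L], design$participant_id[bad][1L])
  }
  macro <- design$carb_pct + design$fat_pct
  if (any(abs(macro - 85) > 1e-9)) {
    d <- design[abs(macro - 85) > 1e-9, ][1L, ]
    stop_validation("carbohydrate + fat + protein(15) != 100 %%E for participant %s set %d",
                    d$participant_id, d$set)
  }
  iv <- design[design$diet != "washout", ]
  per_period <- dplyr::summarise(
    dplyr::group_by(iv, .data$participant_id, .data$set, .data$period),
    diet = dplyr::first(.data$diet), total_days = sum(.data$days),
    n_diets = dplyr::n_distinct(.data$diet), .groups = "drop")
  if (any(per_period$n_diets != 1L)) {
    d <- per_period[per_period$n_diets != 1L, ][1L, ]
    stop_validation("mixed diet labels within one period: participant %s set %d",
                    d$participant_id, d$set)
  }
  if (any(per_period$total_days != 6L)) {
    d <- per_period[per_period$total_days != 6L, ][1L, ]
    stop_validation("intervention period is not 6 days: participant %s set %d",
                    d$participant_id, d$set)
  }
  per_set <- dplyr::summarise(
    dplyr::group_by(per_period, .data$participant_id, .data$set),
    n_lfhc = sum(.data$diet == "LF-HC"), n_hflc = sum(.data$diet == "HF-LC"),
    .groups = "drop")
  off <- per_set$n_lfhc != 1L | per_set$n_hflc != 1L
  if (any(off)) {
    d <- per_set[off, ][1L, ]
    stop_validation("set must contain exactly one LF-HC and one HF-LC period: participant %s set %d has %d LF-HC and %d HF-LC",
                    d$participant_id, d$set, d$n_lfhc, d$n_hflc)
  }
  dplyr::arrange(design, .data$participant_id, .data$start_date)
}

#' Expand a design into a per-day calendar
#'
#' @param design Validated design tibble.
#' @return Tibble with one row per participant-day: `participant_id, date,
#'   set, period, diet, carb_pct, fat_pct`.
#' @export
design_calendar <- function(design) {
  rows <- dplyr::mutate(design, .row = dplyr::row_number())
  out <- tidyr::uncount(rows, weights = .data$days, .id = "day_in_segment")
  out$date <- out$start_date + out$day_in_segment - 1L
  out <- out[, c("participant_id", "date", "set", "period", "diet",
                 "carb_pct", "fat_pct")]
  dup <- duplicated(out[, c("participant_id", "date")])
  if (any(dup)) {
    d <- out[dup, ][1L, ]
    stop_validation("overlapping design segments: participant %s on %s",
                    d$participant_id, d$date)
  }
  dplyr::arrange(out, .data$participant_id, .data$date)
}

#' Read participant metadata
#'
#' @param path CSV file path.
#' @return Tibble `participant_id, age, sex, bmi, completed_all_periods,
#'   valid_data_fraction, chronic_disease_or_medication`.
#' @export
read_participant_meta <- function(path) {
  raw <- read_csv_quiet(path, readr::cols(
    participant_id = readr::col_character(),
    age = readr::col_double(),
    sex = readr::col_character(),
    bmi = readr::col_double(),
    completed_all_periods = readr::col_logical(),
    valid_data_fraction = readr::col_double(),
    chronic_disease_or_medication = readr::col_logical()))
  if (any(raw$valid_data_fraction < 0 | raw$valid_data_fraction > 1,
          na.rm = TRUE)) {
    stop_validation("valid_data_fraction must lie in [0, 1]")
  }
  dplyr::arrange(raw, .data$participant_id)
}

#' Write result tables with a reproducibility manifest
#'
#' Writes every element of `results` (a named list of data frames) as
#' `<name>.csv` under `dir`, together with `manifest.json` recording the
#' configuration hash, seeds, package version and per-table row counts.
#' Reading a written table back reproduces it to at least six decimals.
#'
#' @param results Named list of data frames.
#' @param dir Output directory (created if needed).
#' @param config Optional configuration list stored (and hashed) in the
#'   manifest.
#' @param seed Optional integer seed recorded in the manifest.
#' @return Invisibly, the manifest list.
#' @export
write_results <- function(results, dir, config = NULL, seed = NULL) {
  stopifnot(is.list(results), all(nzchar(names(results))))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  counts <- list()
  for (nm in names(results)) {
    x <- results[[nm]]
    if (!is.data.frame(x)) next
    x <- prepare_for_csv(x)
    readr::write_csv(x, file.path(dir, paste0(nm, ".csv")), progress = FALSE)
    counts[[nm]] <- nrow(x)
  }
  cfg_json <- jsonlite::toJSON(config %||% list(), auto_unbox = TRUE,
                               digits = NA, null = "null")
  cfg_file <- tempfile()
  writeLines(cfg_json, cfg_file)
  manifest <- list(
    package = "nof1cgm",
    version = as.character(utils::packageVersion("nof1cgm")),
    seed = seed,
    config = config,
    config_hash = unname(tools::md5sum(cfg_file)),
    tables = counts)
  unlink(cfg_file)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(manifest)
}

# POSIXct columns are serialized through the canonical timestamp format so
# that write -> read round-trips are exact to the second.
prepare_for_csv <- function(x) {
  for (j in seq_along(x)) {
    if (inherits(x[[j]], "POSIXct")) x[[j]] <- format_timestamp(x[[j]])
  }
  x
}
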