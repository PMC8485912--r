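#' @importFrom rlang %||% abort warn inform
#' @importFrom stats rnorm rgamma runif sd quantile qt pt var median acf
#' @importFrom utils packageVersion head tail
NULL

# mg/dL -> mmol/L divisor. Exactly 18: reproduces the conventional printed
# threshold pairs (3 mg/dL -> 0.167, 1.3 -> 0.072, 15000 mg/dL.min -> 13.889
# mmol/L.h) at 3-decimal precision.
MGDL_PER_MMOL <- 18.0

#' Convert glucose concentrations between mg/dL and mmol/L
#'
#' The conversion divisor is fixed at exactly 18.0 mg/dL per mmol/L, the
#' convention under which 3 mg/dL is 0.167 mmol/L and
#' 15000 mg/dL·min is 13.889 mmol/L·h at three decimals.
#'
#' @param x Numeric vector of glucose values (or glucose-derived quantities in
#'   the same per-concentration units, e.g. AUC).
#' @param from,to Units, each one of `"mg/dL"` or `"mmol/L"`.
#' @return Numeric vector in the target unit.
#' @examples
#' convert_glucose(90, "mg/dL", "mmol/L") # 5.0
#' @export
convert_glucose <- function(x, from = c("mg/dL", "mmol/L"),
                            to = c("mmol/L", "mg/dL")) {
  from <- match.arg(from)
  to <- match.arg(to)
  if (from == to) return(x)
  if (from == "mg/dL") x / MGDL_PER_MMOL else x * MGDL_PER_MMOL
}

# Deterministic child seed derivation: keeps every stream reproducible from a
# single user seed while avoiding correlated streams; always < 2^31.
child_seed <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  as.integer((as.double(seed) * 48271 + 1009 * as.double(k)) %% 2147483629)
}

# Set the RNG locally for the calling frame when a seed is supplied.
local_seed_if <- function(seed, env = parent.frame()) {
  if (!is.null(seed)) withr::local_seed(seed, .local_envir = env)
  invisible(NULL)
}

stop_validation <- function(msg, ...) {
  rlang::abort(sprintf(msg, ...), class = "nof1cgm_validation_error")
}

stop_format <- function(msg, ...) {
  rlang::abort(sprintf(msg, ...), class = "nof1cgm_format_error")
}

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lower || x > upper) {
    stop_validation("`%s` must be a single number in [%s, %s]", name,
                    format(lower), format(upper))
  }
  invisible(x)
}

# Parse "YYYY-MM-DD HH:MM[:SS]" as timezone-naive local time (stored as UTC so
# arithmetic is DST-free). Returns NA for unparseable entries.
parse_timestamp <- function(x) {
  x <- as.character(x)
  out <- as.POSIXct(rep(NA_real_, length(x)), origin = "1970-01-01", tz = "UTC")
  for (fmt in c("%Y-%m-%d %H:%M:%S", "%Y-%m-%d %H:%M",
                "%Y-%m-%dT%H:%M:%S", "%Y-%m-%dT%H:%M")) {
    miss <- is.na(out) & !is.na(x)
    if (!any(miss)) break
    out[miss] <- as.POSIXct(strptime(x[miss], fmt, tz = "UTC"))
  }
  out
}

format_timestamp <- function(x) format(x, "%Y-%m-%d %H:%M:%S", tz = "UTC")

hours_of_day <- function(ts) {
  as.numeric(ts - as.POSIXct(paste(format(ts, "%Y-%m-%d", tz = "UTC"), "00:00:00"),
                             tz = "UTC"), units = "hours")
}

ts_date <- function(ts) as.Date(format(ts, "%Y-%m-%d", tz = "UTC"))
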