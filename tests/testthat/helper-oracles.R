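# Independent oracles and small fixture builders shared across tests.

# Brute-force MAGE: naive loop over collapsed values, scanning every strict
# sign change and averaging qualifying turning-point amplitudes.
mage_oracle <- function(g, sd_mult = 1) {
  g <- g[!is.na(g)]
  if (length(g) < 3) return(NA_real_)
  s <- sd(g)
  v <- g[1]
  for (k in 2:length(g)) if (g[k] != v[length(v)]) v <- c(v, g[k])
  if (length(v) < 3) return(NA_real_)
  tp <- c()
  for (k in 2:(length(v) - 1)) {
    if ((v[k] - v[k - 1]) * (v[k + 1] - v[k]) < 0) tp <- c(tp, v[k])
  }
  if (length(tp) < 2) return(NA_real_)
  amps <- abs(diff(tp))
  q <- amps[amps > sd_mult * s]
  if (!length(q)) return(NA_real_)
  mean(q)
}

# Piecewise trapezoid on explicit (hours, glucose) points.
trapz_oracle <- function(h, g) {
  sum(diff(h) * (g[-length(g)] + g[-1]) / 2)
}

# Flat-prior posterior of the two-group mean difference is a scaled t with
# n-2 df; closed-form tail probabilities for comparison with the Gibbs path.
t_tail_oracle <- function(y, x, delta) {
  y0 <- y[x == 0]; y1 <- y[x == 1]
  n0 <- length(y0); n1 <- length(y1)
  bhat <- mean(y1) - mean(y0)
  s2 <- (sum((y0 - mean(y0))^2) + sum((y1 - mean(y1))^2)) / (n0 + n1 - 2)
  se <- sqrt(s2 * (1 / n0 + 1 / n1))
  # beta | y ~ bhat + se * T(n-2): P(beta > d) = P(T < (bhat - d)/se)
  list(mean = bhat, se = se,
       p_above = pt((bhat - delta) / se, n0 + n1 - 2),
       p_below = pt((-delta - bhat) / se, n0 + n1 - 2))
}

# Reduced sampler settings for fast unit tests (acceptance tests use the
# package defaults).
quick_spec <- function(seed = NULL, ...) {
  nof1_model_spec(chains = 2L, iter = 3000L, burn = 500L, seed = seed, ...)
}

quick_hier_spec <- function(seed = NULL, ...) {
  hier_spec(chains = 2L, iter = 3000L, burn = 500L, seed = seed, ...)
}

# A flat-glucose trace over n_days for one participant, 15-min grid with the
# closing midnight sample.
flat_trace <- function(value = 5, n_days = 1, participant_id = "P01",
                       start = as.Date("2020-03-01")) {
  t0 <- as.POSIXct(paste(start, "00:00:00"), tz = "UTC")
  grid <- seq(t0, t0 + n_days * 86400, by = 900)
  tibble::tibble(participant_id = participant_id, timestamp = grid,
                 glucose = rep(value, length(grid)))
}

# Trace built from a function of hours-since-midnight on day `start`.
fun_trace <- function(f, participant_id = "P01",
                      start = as.Date("2020-03-01"), include_midnight = TRUE) {
  t0 <- as.POSIXct(paste(start, "00:00:00"), tz = "UTC")
  end <- if (include_midnight) 86400 else 86400 - 900
  grid <- seq(t0, t0 + end, by = 900)
  h <- as.numeric(grid - t0, units = "hours")
  tibble::tibble(participant_id = participant_id, timestamp = grid,
                 glucose = f(h))
}

# Random short glucose series with plateaus and ties (values on a 0.1 grid).
random_trace_values <- function(n) {
  round(5 + cumsum(sample(c(-0.3, -0.1, 0, 0, 0.1, 0.3), n, replace = TRUE)), 1)
}

# Balanced two-arm outcome series for individual-model tests.
make_series <- function(n_per_arm, effect, sd, baseline = 5,
                        participant_id = "P01", outcome = "MPG") {
  tibble::tibble(
    participant_id = participant_id, outcome = outcome,
    value = c(rnorm(n_per_arm, baseline, sd),
              rnorm(n_per_arm, baseline + effect, sd)),
    treatment = rep(c(0L, 1L), each = n_per_arm),
    set = rep(rep(seq_len(3), length.out = n_per_arm), 2),
    date = as.Date("2020-01-01") + seq_len(2 * n_per_arm))
}

write_temp_csv <- function(df, name = "fixture.csv") {
  path <- withr::local_tempfile(fileext = ".csv",
                                .local_envir = parent.frame())
  readr::write_csv(df, path, progress = FALSE)
  path
}
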