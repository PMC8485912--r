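#' Clinically meaningful difference thresholds
#'
#' Default thresholds for a meaningful diet-induced difference:
#' 0.167 mmol/L for MPG, 0.072 mmol/L for MAGE and 13.889 mmol/L·h for AUC24
#' (the mg/dL-derived conventions 3 mg/dL, 1.3 mg/dL and
#' 1.5e4 mg/dL·min divided by 18).
#'
#' @param mpg,mage,auc24 Positive thresholds on each outcome's scale.
#' @return Named numeric vector with elements `MPG`, `MAGE`, `AUC24`.
#' @export
meaningful_thresholds <- function(mpg = 0.167, mage = 0.072, auc24 = 13.889) {
  out <- c(MPG = mpg, MAGE = mage, AUC24 = auc24)
  if (any(out <= 0)) stop_validation("thresholds must be positive")
  out
}

#' Sampler settings for the individual treatment-effect model
#'
#' The individual model regresses an outcome series on the treatment
#' indicator, `y = alpha + beta * x + e` with `x` coded HF-LC = 0 and
#' LF-HC = 1, so `beta > 0` means higher glycemia on the high-carbohydrate
#' diet. Noninformative priors: `alpha, beta ~ Normal(0, 1e6)` on the
#' outcome's mmol/L scale and residual variance
#' `~ InverseGamma(0.001, 0.001)`.
#'
#' @param prior_mean,prior_var Normal prior for `alpha` and `beta`.
#' @param resid_shape,resid_scale Inverse-gamma prior for the residual
#'   variance.
#' @param chains,iter,burn,thin MCMC settings: `iter` total iterations per
#'   chain, of which the first `burn` are discarded.
#' @param rhat_max Split-chain R-hat above which a fit is flagged
#'   non-converged.
#' @param method `"observation"` fits at observation level (all meal- or
#'   day-level values); `"paired"` first collapses each set into one paired
#'   mean difference and models those.
#' @param seed Integer seed.
#' @return Object of class `nof1_model_spec`.
#' @export
nof1_model_spec <- function(prior_mean = 0, prior_var = 1e6,
                            resid_shape = 0.001, resid_scale = 0.001,
                            chains = 4L, iter = 10000L, burn = 2000L,
                            thin = 1L, rhat_max = 1.05,
                            method = c("observation", "paired"),
                            seed = NULL) {
  if (iter <= burn) stop_validation("iter must exceed burn")
  if (prior_var <= 0 || resid_shape <= 0 || resid_scale <= 0) {
    stop_validation("prior variances and inverse-gamma parameters must be positive")
  }
  structure(list(prior_mean = prior_mean, prior_var = prior_var,
                 resid_shape = resid_shape, resid_scale = resid_scale,
                 chains = as.integer(chains), iter = as.integer(iter),
                 burn = as.integer(burn), thin = as.integer(thin),
                 rhat_max = rhat_max, method = match.arg(method),
                 seed = seed),
            class = "nof1_model_spec")
}

# Gibbs sampler for y = alpha + beta*x + e with conjugate full conditionals.
# Returns a chains x kept matrix of beta draws (and sigma2 for diagnostics).
gibbs_linear <- function(y, x, spec) {
  n <- length(y)
  Sx <- sum(x)
  Sxx <- sum(x * x)
  Sy <- sum(y)
  Sxy <- sum(x * y)
  Syy <- sum(y * y)
  kept <- (spec$iter - spec$burn) %/% spec$thin
  beta_draws <- matrix(NA_real_, spec$chains, kept)
  alpha_draws <- matrix(NA_real_, spec$chains, kept)
  sigma2_draws <- matrix(NA_real_, spec$chains, kept)
  prior_prec <- 1 / spec$prior_var
  pm <- spec$prior_mean
  for (ch in seq_len(spec$chains)) {
    sigma2 <- max(var(y), 1e-6) * runif(1, 0.5, 2) # overdispersed start
    alpha <- mean(y) + rnorm(1, 0, sqrt(sigma2 / n))
    beta <- 0
    k <- 0L
    for (it in seq_len(spec$iter)) {
      inv_s2 <- 1 / sigma2
      # (alpha, beta) | sigma2: bivariate normal, 2x2 solved in closed form
      a11 <- n * inv_s2 + prior_prec
      a12 <- Sx * inv_s2
      a22 <- Sxx * inv_s2 + prior_prec
      b1 <- Sy * inv_s2 + pm * prior_prec
      b2 <- Sxy * inv_s2 + pm * prior_prec
      det <- a11 * a22 - a12 * a12
      m1 <- (a22 * b1 - a12 * b2) / det
      m2 <- (a11 * b2 - a12 * b1) / det
      # Cholesky of the 2x2 covariance (inverse of the precision matrix)
      l11 <- sqrt(a22 / det)
      l21 <- -a12 / det / l11
      l22 <- sqrt(a11 / det - l21 * l21)
      z1 <- rnorm(1)
      z2 <- rnorm(1)
      alpha <- m1 + l11 * z1
      beta <- m2 + l21 * z1 + l22 * z2
      ssr <- Syy - 2 * alpha * Sy - 2 * beta * Sxy +
        n * alpha * alpha + 2 * alpha * beta * Sx + beta * beta * Sxx
      sigma2 <- 1 / rgamma(1, spec$resid_shape + n / 2,
                           spec$resid_scale + max(ssr, 0) / 2)
      if (it > spec$burn && (it - spec$burn) %% spec$thin == 0L) {
        k <- k + 1L
        beta_draws[ch, k] <- beta
        alpha_draws[ch, k] <- alpha
        sigma2_draws[ch, k] <- sigma2
      }
    }
  }
  list(beta = beta_draws, alpha = alpha_draws, sigma2 = sigma2_draws)
}

# Split-chain R-hat (each chain halved, rank-free classical form).
split_rhat <- function(draws) {
  half <- ncol(draws) %/% 2L
  segs <- rbind(draws[, seq_len(half), drop = FALSE],
                draws[, half + seq_len(half), drop = FALSE])
  m <- nrow(segs)
  n <- ncol(segs)
  means <- rowMeans(segs)
  vars <- apply(segs, 1, var)
  B <- n * var(means)
  W <- mean(vars)
  if (W <= 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Fit the individual Bayesian treatment-effect model
#'
#' Gibbs sampling over `(alpha, beta, sigma^2)` with conjugate full
#' conditionals. The posterior tail probabilities
#' `P(beta > +delta)` and `P(beta < -delta)` are the fractions of
#' post-burn-in draws beyond the meaningful-difference threshold.
#'
#' @param series Outcome-series tibble for one participant and one outcome
#'   (columns `value`, `treatment`, and `set` when `method = "paired"`).
#' @param delta Meaningful-difference threshold on the outcome scale.
#' @param spec A [nof1_model_spec()].
#' @param participant_id,outcome Optional labels carried into the result
#'   (inferred from the series when present).
#' @return Object of class `nof1_fit`: posterior mean, 95% credible
#'   interval, `p_above`, `p_below`, per-arm observation counts, split-chain
#'   R-hat and convergence flag, and the retained beta draws.
#' @export
fit_individual <- function(series, delta, spec = nof1_model_spec(),
                           participant_id = NULL, outcome = NULL) {
  participant_id <- participant_id %||%
    (if ("participant_id" %in% names(series)) unique(series$participant_id)[1] else NA_character_)
  outcome <- outcome %||%
    (if ("outcome" %in% names(series)) unique(series$outcome)[1] else NA_character_)
  assert_scalar_number(delta, "delta", 1e-12)
  y <- series$value
  x <- series$treatment
  keep <- !is.na(y) & !is.na(x)
  y <- y[keep]
  x <- x[keep]
  n0 <- sum(x == 0)
  n1 <- sum(x == 1)
  if (n0 < 2L || n1 < 2L) {
    stop_validation("insufficient data for participant %s (%s): %d HF-LC and %d LF-HC observations (need >= 2 per arm)",
                    participant_id, outcome, n0, n1)
  }
  if (spec$method == "paired") {
    if (!"set" %in% names(series)) {
      stop_validation("paired method needs a `set` column")
    }
    byset <- dplyr::summarise(
      dplyr::group_by(series[keep, , drop = FALSE], .data$set),
      d = mean(.data$value[.data$treatment == 1]) -
        mean(.data$value[.data$treatment == 0]), .groups = "drop")
    y <- byset$d
    x <- rep(1, nrow(byset))
    if (length(y) < 2L) {
      stop_validation("paired method needs >= 2 completed sets")
    }
  }
  local_seed_if(spec$seed)
  draws <- gibbs_linear(y, x, spec)
  if (spec$method == "paired") {
    # with x identically 1 the treatment effect is alpha + beta; use their sum
    beta <- draws$alpha + draws$beta
  } else {
    beta <- draws$beta
  }
  bvec <- as.numeric(t(beta))
  rhat <- split_rhat(beta)
  structure(list(
    participant_id = participant_id, outcome = outcome, delta = delta,
    beta_mean = mean(bvec),
    ci95 = unname(quantile(bvec, c(0.025, 0.975))),
    p_above = mean(bvec > delta),
    p_below = mean(bvec < -delta),
    n_obs = c(hflc = n0, lfhc = n1),
    rhat = rhat, converged = rhat < spec$rhat_max,
    draws = beta, sigma2 = draws$sigma2, spec = spec),
    class = "nof1_fit")
}

#' @export
print.nof1_fit <- function(x, ...) {
  cat(sprintf("n-of-1 fit: participant %s, outcome %s\n", x$participant_id,
              x$outcome))
  cat(sprintf("  beta (LF-HC minus HF-LC): %.3f [%.3f, %.3f]\n",
              x$beta_mean, x$ci95[1], x$ci95[2]))
  cat(sprintf("  P(beta > %+.3f) = %.3f, P(beta < %+.3f) = %.3f\n",
              x$delta, x$p_above, -x$delta, x$p_below))
  cat(sprintf("  n per arm: %d HF-LC / %d LF-HC; split R-hat %.3f%s\n",
              x$n_obs["hflc"], x$n_obs["lfhc"], x$rhat,
              if (x$converged) "" else " (NOT CONVERGED)"))
  invisible(x)
}

as_summary_row <- function(fit) {
  tibble::tibble(
    participant_id = fit$participant_id, outcome = fit$outcome,
    beta_mean = fit$beta_mean, ci_lower = fit$ci95[1], ci_upper = fit$ci95[2],
    p_below = fit$p_below, p_above = fit$p_above,
    n_hflc = unname(fit$n_obs["hflc"]), n_lfhc = unname(fit$n_obs["lfhc"]),
    rhat = fit$rhat, converged = fit$converged, delta = fit$delta)
}

#' Fit the individual model for every participant and outcome
#'
#' @param series Outcome-series tibble (several participants/outcomes).
#' @param thresholds Named thresholds from [meaningful_thresholds()].
#' @param spec A [nof1_model_spec()]; each fit gets a deterministic child
#'   seed derived from `spec$seed`.
#' @param outcomes Outcomes to fit (default all present).
#' @return Tibble of posterior summaries, one row per participant-outcome;
#'   participants with insufficient data in an arm are skipped with a
#'   warning.
#' @export
fit_cohort <- function(series, thresholds = meaningful_thresholds(),
                       spec = nof1_model_spec(),
                       outcomes = unique(series$outcome)) {
  rows <- list()
  i <- 0L
  for (oc in outcomes) {
    delta <- thresholds[[oc]]
    if (is.null(delta)) stop_validation("no threshold supplied for outcome %s", oc)
    sub <- series[series$outcome == oc, , drop = FALSE]
    for (pid in unique(sub$participant_id)) {
      i <- i + 1L
      s <- sub[sub$participant_id == pid, , drop = FALSE]
      sp <- spec
      sp$seed <- child_seed(spec$seed, i)
      fit <- tryCatch(fit_individual(s, delta, sp),
                      nof1cgm_validation_error = function(e) {
                        rlang::warn(conditionMessage(e))
                        NULL
                      })
      if (!is.null(fit)) rows[[length(rows) + 1L]] <- as_summary_row(fit)
    }
  }
  dplyr::bind_rows(rows)
}

#' Classify responders from posterior summaries
#'
#' A participant is an HC-responder for an outcome when
#' `P(beta > +delta) > prob_threshold` (glycemia higher on the
#' high-carbohydrate diet), an HF-responder when
#' `P(beta < -delta) > prob_threshold`, and a nonresponder otherwise.
#'
#' @param posterior Tibble with columns `p_above` and `p_below` (proportions
#'   in `[0, 1]`), e.g. from [fit_cohort()].
#' @param prob_threshold Posterior-probability threshold (default 0.80).
#' @return The input with a `call` column added.
#' @export
classify_responders <- function(posterior, prob_threshold = 0.80) {
  assert_scalar_number(prob_threshold, "prob_threshold", 0.5, 1)
  call <- ifelse(posterior$p_above > prob_threshold, "HC-responder",
                 ifelse(posterior$p_below > prob_threshold, "HF-responder",
                        "nonresponder"))
  dplyr::mutate(posterior, call = call,
                prob_threshold = prob_threshold)
}

#' Summarize responder calls across outcomes
#'
#' Produces per-outcome counts and overall labels where a participant is an
#' HC-responder overall if called HC for MPG or MAGE (and analogously HF).
#' A participant called HC on one outcome and HF on the other is flagged for
#' manual review rather than silently labelled.
#'
#' @param calls Output of [classify_responders()] covering the outcomes of
#'   interest.
#' @param overall_outcomes Outcomes entering the overall union label
#'   (default MPG and MAGE).
#' @return List with `by_outcome` (counts per outcome), `overall`
#'   (per-participant overall label), `overall_counts`, and `conflicts`.
#' @export
summarize_cohort_calls <- function(calls, overall_outcomes = c("MPG", "MAGE")) {
  by_outcome <- dplyr::count(calls, .data$outcome, .data$call)
  sub <- calls[calls$outcome %in% overall_outcomes, , drop = FALSE]
  overall <- dplyr::summarise(
    dplyr::group_by(sub, .data$participant_id),
    any_hc = any(.data$call == "HC-responder"),
    any_hf = any(.data$call == "HF-responder"), .groups = "drop")
  overall$label <- ifelse(overall$any_hc & overall$any_hf, "conflict",
                          ifelse(overall$any_hc, "HC-responder",
                                 ifelse(overall$any_hf, "HF-responder",
                                        "nonresponder")))
  conflicts <- overall$participant_id[overall$label == "conflict"]
  if (length(conflicts)) {
    rlang::warn(sprintf("participant(s) %s are HC-responders on one outcome and HF-responders on another; flagged for manual review",
                        paste(conflicts, collapse = ", ")))
  }
  counts <- table(factor(overall$label,
                         levels = c("HC-responder", "HF-responder",
                                    "nonresponder", "conflict")))
  list(by_outcome = by_outcome,
       overall = overall[, c("participant_id", "label")],
       overall_counts = counts,
       conflicts = conflicts)
}

#' Carbohydrate dose-response contrasts
#'
#' For each participant, fits the individual model for each contrast of a
#' higher-carbohydrate day type (25, 65 or 75 percent of energy) against the
#' lowest (15 %E), on observations labelled with the day's carbohydrate
#' level, and summarizes whether the posterior mean differences are ordered
#' monotonically in carbohydrate dose.
#'
#' @param series Outcome-series tibble carrying `carb_pct` (use the MPG or
#'   MAGE series).
#' @param delta Meaningful-difference threshold for the outcome.
#' @param spec A [nof1_model_spec()].
#' @param reference Carbohydrate level of the reference day type (default
#'   15).
#' @param levels Higher-carbohydrate levels to contrast (default 25, 65,
#'   75).
#' @return List with `contrasts` (tibble of posterior summaries, one row per
#'   participant x level) and `monotonicity` (per-participant trend across
#'   levels).
#' @export
dose_response_fit <- function(series, delta, spec = nof1_model_spec(),
                              reference = 15, levels = c(25, 65, 75)) {
  rows <- list()
  i <- 0L
  for (pid in unique(series$participant_id)) {
    s <- series[series$participant_id == pid, , drop = FALSE]
    for (lv in levels) {
      i <- i + 1L
      sub <- s[s$carb_pct %in% c(reference, lv), , drop = FALSE]
      if (!any(sub$carb_pct == lv) || !any(sub$carb_pct == reference)) {
        rlang::warn(sprintf("participant %s: empty carbohydrate level for contrast %g vs %g; skipped",
                            pid, lv, reference))
        next
      }
      sub$treatment <- as.integer(sub$carb_pct == lv)
      sp <- spec
      sp$seed <- child_seed(spec$seed, 9000L + i)
      fit <- tryCatch(fit_individual(sub, delta, sp, participant_id = pid,
                                     outcome = unique(s$outcome)[1]),
                      nof1cgm_validation_error = function(e) {
                        rlang::warn(conditionMessage(e))
                        NULL
                      })
      if (is.null(fit)) next
      row <- as_summary_row(fit)
      row$carb_level <- lv
      row$reference <- reference
      rows[[length(rows) + 1L]] <- row
    }
  }
  contrasts <- dplyr::bind_rows(rows)
  monotonicity <- dplyr::summarise(
    dplyr::group_by(contrasts, .data$participant_id),
    n_levels = dplyr::n(),
    increasing = all(diff(.data$beta_mean[order(.data$carb_level)]) > 0),
    decreasing = all(diff(.data$beta_mean[order(.data$carb_level)]) < 0),
    .groups = "drop")
  list(contrasts = contrasts, monotonicity = monotonicity)
}
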