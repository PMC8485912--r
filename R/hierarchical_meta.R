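#' Sampler settings for the hierarchical (population-level) model
#'
#' Two-level normal model: observations
#' `y = alpha_i + beta_i * x + e`, `e ~ Normal(0, sigma^2)`; participant
#' intercepts `alpha_i ~ Normal(a0, tau_alpha^2)` and treatment effects
#' `beta_i ~ Normal(b0 + Z gamma, tau^2)` with covariates `Z` (age, sex,
#' BMI) centered/standardized so the diffuse priors are comparably flat.
#' All location parameters get `Normal(0, 1e6)` priors; all variances get
#' noninformative inverse-gamma priors.
#'
#' @param prior_var Prior variance for all location parameters.
#' @param tau_shape,tau_scale Inverse-gamma prior for the between-participant
#'   variances.
#' @param resid_shape,resid_scale Inverse-gamma prior for the residual
#'   variance.
#' @param chains,iter,burn MCMC settings.
#' @param prob_threshold Group-level posterior-probability threshold for a
#'   meaningful effect (default 0.90, stricter than the individual-level
#'   0.80).
#' @param ar1_rho Optional within-period residual AR(1) coefficient; when
#'   set, observations are quasi-differenced at this lag-1 correlation before
#'   fitting (default `NULL`, independent residuals).
#' @param rhat_max Convergence bound on the split-chain R-hat of the
#'   population effect.
#' @param seed Integer seed.
#' @return Object of class `nof1_hier_spec`.
#' @export
hier_spec <- function(prior_var = 1e6, tau_shape = 0.001, tau_scale = 0.001,
                      resid_shape = 0.001, resid_scale = 0.001,
                      chains = 4L, iter = 10000L, burn = 2000L,
                      prob_threshold = 0.90, ar1_rho = NULL,
                      rhat_max = 1.05, seed = NULL) {
  if (iter <= burn) stop_validation("iter must exceed burn")
  if (prob_threshold <= 0.5 || prob_threshold >= 1) {
    stop_validation("prob_threshold must lie in (0.5, 1)")
  }
  structure(list(prior_var = prior_var, tau_shape = tau_shape,
                 tau_scale = tau_scale, resid_shape = resid_shape,
                 resid_scale = resid_scale, chains = as.integer(chains),
                 iter = as.integer(iter), burn = as.integer(burn),
                 prob_threshold = prob_threshold, ar1_rho = ar1_rho,
                 rhat_max = rhat_max, seed = seed),
            class = "nof1_hier_spec")
}

# Standardize covariates; returns matrix (possibly zero columns) plus the
# names of any dropped singular columns.
build_covariates <- function(meta, ids) {
  m <- meta[match(ids, meta$participant_id), , drop = FALSE]
  cand <- list(age = m$age, sex = as.numeric(m$sex == "M"), bmi = m$bmi)
  keep <- list()
  dropped <- character()
  for (nm in names(cand)) {
    v <- cand[[nm]]
    if (is.null(v) || anyNA(v) || length(ids) < 2L || stats::sd(v) == 0) {
      dropped <- c(dropped, nm)
    } else {
      keep[[nm]] <- (v - mean(v)) / stats::sd(v)
    }
  }
  if (length(dropped)) {
    rlang::warn(sprintf("covariate(s) dropped as singular or missing: %s",
                        paste(dropped, collapse = ", ")))
  }
  if (!length(keep)) {
    matrix(numeric(0), nrow = length(ids), ncol = 0)
  } else {
    do.call(cbind, keep)
  }
}

# Per-participant sufficient statistics, optionally after AR(1)
# quasi-differencing within (participant, set, treatment) blocks.
hier_suffstats <- function(series, ids, ar1_rho = NULL) {
  stats_list <- vector("list", length(ids))
  for (j in seq_along(ids)) {
    s <- series[series$participant_id == ids[j], , drop = FALSE]
    s <- dplyr::arrange(s, .data$set, .data$treatment, .data$date)
    y <- s$value
    x <- as.numeric(s$treatment)
    cvec <- rep(1, length(y))
    if (!is.null(ar1_rho)) {
      rho <- ar1_rho
      block <- paste(s$set, s$treatment)
      first <- !duplicated(block)
      yl <- dplyr::lag(y)
      xl <- dplyr::lag(x)
      y <- ifelse(first, y * sqrt(1 - rho^2), y - rho * yl)
      x <- ifelse(first, x * sqrt(1 - rho^2), x - rho * xl)
      cvec <- ifelse(first, sqrt(1 - rho^2), 1 - rho)
    }
    d <- s$value[s$treatment == 1]
    h <- s$value[s$treatment == 0]
    stats_list[[j]] <- c(
      Scc = sum(cvec^2), Scx = sum(cvec * x), Sxx = sum(x^2),
      Scy = sum(cvec * y), Sxy = sum(x * y), Syy = sum(y^2),
      n = length(y),
      d_i = if (length(d) && length(h)) mean(d) - mean(h) else NA_real_)
  }
  do.call(rbind, stats_list)
}

#' Fit the Bayesian hierarchical model across participants
#'
#' Gibbs sampling with conjugate updates over participant intercepts and
#' treatment effects, the population-level coefficients, the
#' between-participant variances and the residual variance. The population
#' treatment effect is the intercept of the effect regression at
#' centered covariates; `p_meaningful` is the summed posterior mass beyond
#' the meaningful-difference threshold in both directions,
#' `P(effect > +delta) + P(effect < -delta)`.
#'
#' @param series Outcome-series tibble (one outcome; filter first or pass
#'   `outcome`).
#' @param meta Participant metadata tibble ([read_participant_meta()]
#'   schema). May be `NULL` for an unadjusted fit.
#' @param delta Meaningful-difference threshold on the outcome scale.
#' @param spec A [hier_spec()].
#' @param outcome Optional outcome name used to filter `series`.
#' @return Object of class `nof1_hier_fit`.
#' @export
fit_hierarchical <- function(series, meta = NULL, delta,
                             spec = hier_spec(), outcome = NULL) {
  if (!is.null(outcome) && "outcome" %in% names(series)) {
    series <- series[series$outcome == outcome, , drop = FALSE]
  } else if ("outcome" %in% names(series)) {
    outcome <- unique(series$outcome)
    if (length(outcome) > 1L) {
      stop_validation("series contains several outcomes; pass `outcome`")
    }
  }
  assert_scalar_number(delta, "delta", 1e-12)
  # require at least one completed cycle: both arms observed
  arms <- dplyr::summarise(dplyr::group_by(series, .data$participant_id),
                           ok = any(.data$treatment == 0) & any(.data$treatment == 1),
                           .groups = "drop")
  ids <- sort(arms$participant_id[arms$ok])
  if (length(ids) < 1L) stop_validation("no participant has observations in both arms")
  series <- series[series$participant_id %in% ids, , drop = FALSE]
  Z <- if (is.null(meta)) {
    matrix(numeric(0), nrow = length(ids), ncol = 0)
  } else {
    build_covariates(meta, ids)
  }
  st <- hier_suffstats(series, ids, spec$ar1_rho)
  W <- cbind(intercept = rep(1, length(ids)), Z)
  local_seed_if(spec$seed)
  res <- gibbs_hier(st, W, spec, delta)

  b0 <- res$theta[, 1, , drop = FALSE] # chains x kept
  b0_mat <- matrix(b0, nrow = spec$chains)
  bvec <- as.numeric(t(b0_mat))
  rhat <- split_rhat(b0_mat)
  p_above <- mean(bvec > delta)
  p_below <- mean(bvec < -delta)
  cov_names <- colnames(W)[-1]
  cov_tbl <- NULL
  if (length(cov_names)) {
    cov_tbl <- dplyr::bind_rows(lapply(seq_along(cov_names), function(k) {
      v <- as.numeric(res$theta[, k + 1, ])
      tibble::tibble(covariate = cov_names[k], mean = mean(v),
                     ci_lower = quantile(v, 0.025),
                     ci_upper = quantile(v, 0.975))
    }))
  }
  structure(list(
    outcome = outcome %||% NA_character_, delta = delta,
    effect_mean = mean(bvec),
    ci95 = unname(quantile(bvec, c(0.025, 0.975))),
    p_above = p_above, p_below = p_below,
    p_meaningful = p_above + p_below,
    p_dominant = max(p_above, p_below),
    tau_mean = mean(res$tau), tau_ci = unname(quantile(res$tau, c(0.025, 0.975))),
    tau_alpha_mean = mean(res$tau_alpha),
    sigma_mean = mean(res$sigma),
    covariates = cov_tbl,
    participant_effects = tibble::tibble(
      participant_id = ids,
      individual_estimate = unname(st[, "d_i"]),
      shrunken_mean = res$beta_mean,
      shrunken_sd = res$beta_sd,
      p_above = res$beta_above,
      p_below = res$beta_below),
    n_participants = length(ids),
    rhat = rhat, converged = rhat < spec$rhat_max,
    draws = list(effect = b0_mat, tau = res$tau),
    prob_threshold = spec$prob_threshold,
    spec = spec), class = "nof1_hier_fit")
}

#' @export
print.nof1_hier_fit <- function(x, ...) {
  cat(sprintf("Hierarchical n-of-1 meta-analysis: outcome %s, %d participants\n",
              x$outcome, x$n_participants))
  cat(sprintf("  population effect (LF-HC minus HF-LC): %.3f [%.3f, %.3f]\n",
              x$effect_mean, x$ci95[1], x$ci95[2]))
  cat(sprintf("  P(|effect| > %.3f) = %.3f (threshold %.2f); between-participant sd %.3f\n",
              x$delta, x$p_meaningful, x$prob_threshold, x$tau_mean))
  if (!x$converged) cat(sprintf("  WARNING: split R-hat %.3f\n", x$rhat))
  invisible(x)
}

# Vectorized Gibbs sampler for the two-level model on sufficient statistics.
gibbs_hier <- function(st, W, spec, delta) {
  N <- nrow(st)
  p <- ncol(W)
  ntot <- sum(st[, "n"])
  Scc <- st[, "Scc"]; Scx <- st[, "Scx"]; Sxx <- st[, "Sxx"]
  Scy <- st[, "Scy"]; Sxy <- st[, "Sxy"]; Syy <- st[, "Syy"]
  kept <- spec$iter - spec$burn
  theta_draws <- array(NA_real_, c(spec$chains, p, kept))
  tau_draws <- matrix(NA_real_, spec$chains, kept)
  tau_a_draws <- matrix(NA_real_, spec$chains, kept)
  sigma_draws <- matrix(NA_real_, spec$chains, kept)
  beta_sum <- numeric(N)
  beta_sum2 <- numeric(N)
  beta_above <- numeric(N)
  beta_below <- numeric(N)
  prior_prec <- 1 / spec$prior_var
  for (ch in seq_len(spec$chains)) {
    d0 <- ifelse(Sxx > 0, (Sxy - Scy / pmax(Scc, 1) * Scx) / pmax(Sxx, 1), 0)
    beta <- d0 + rnorm(N, 0, 0.1)
    alpha <- Scy / pmax(Scc, 1)
    theta <- c(mean(beta), rep(0, p - 1))
    tau2 <- max(var(beta), 0.01, na.rm = TRUE) * runif(1, 0.5, 2)
    tau2_a <- max(var(alpha), 0.01, na.rm = TRUE) * runif(1, 0.5, 2)
    sigma2 <- runif(1, 0.5, 2)
    a0 <- mean(alpha)
    for (it in seq_len(spec$iter)) {
      inv_s2 <- 1 / sigma2
      # population mean of intercepts, collapsed over alpha_i (blocked
      # update: avoids the random-walk degeneracy at small N)
      za <- (Scy - beta * Scx) / Scc
      wa <- 1 / (tau2_a + sigma2 / Scc)
      prec_a0 <- sum(wa) + prior_prec
      a0 <- rnorm(1, sum(wa * za) / prec_a0, sqrt(1 / prec_a0))
      # participant intercepts
      prec_a <- Scc * inv_s2 + 1 / tau2_a
      mu_a <- ((Scy - beta * Scx) * inv_s2 + a0 / tau2_a) / prec_a
      alpha <- rnorm(N, mu_a, sqrt(1 / prec_a))
      # population effect regression theta = (b0, gamma), collapsed over
      # beta_i: z_i | theta ~ N(W_i theta, tau2 + sigma2/Sxx_i)
      zb <- (Sxy - alpha * Scx) / Sxx
      wb <- 1 / (tau2 + sigma2 / Sxx)
      A <- crossprod(W, W * wb) + diag(prior_prec, p)
      bvec <- crossprod(W, wb * zb)
      U <- chol(A)
      mean_theta <- backsolve(U, forwardsolve(t(U), bvec))
      theta <- as.numeric(mean_theta + backsolve(U, rnorm(p)))
      # participant effects, centered on the covariate regression
      m_i <- as.numeric(W %*% theta)
      prec_b <- Sxx * inv_s2 + 1 / tau2
      mu_b <- ((Sxy - alpha * Scx) * inv_s2 + m_i / tau2) / prec_b
      beta <- rnorm(N, mu_b, sqrt(1 / prec_b))
      # variances
      tau2_a <- 1 / rgamma(1, spec$tau_shape + N / 2,
                           spec$tau_scale + sum((alpha - a0)^2) / 2)
      resid_b <- beta - as.numeric(W %*% theta)
      tau2 <- 1 / rgamma(1, spec$tau_shape + N / 2,
                         spec$tau_scale + sum(resid_b^2) / 2)
      ssr <- sum(Syy - 2 * alpha * Scy - 2 * beta * Sxy +
                   alpha^2 * Scc + 2 * alpha * beta * Scx + beta^2 * Sxx)
      sigma2 <- 1 / rgamma(1, spec$resid_shape + ntot / 2,
                           spec$resid_scale + max(ssr, 1e-12) / 2)
      if (it > spec$burn) {
        k <- it - spec$burn
        theta_draws[ch, , k] <- theta
        tau_draws[ch, k] <- sqrt(tau2)
        tau_a_draws[ch, k] <- sqrt(tau2_a)
        sigma_draws[ch, k] <- sqrt(sigma2)
        beta_sum <- beta_sum + beta
        beta_sum2 <- beta_sum2 + beta^2
        beta_above <- beta_above + (beta > delta)
        beta_below <- beta_below + (beta < -delta)
      }
    }
  }
  list(theta = theta_draws,
       tau = as.numeric(tau_draws), tau_alpha = as.numeric(tau_a_draws),
       sigma = as.numeric(sigma_draws),
       beta_mean = beta_sum / (kept * spec$chains),
       beta_sd = sqrt(pmax(0, beta_sum2 / (kept * spec$chains) -
                             (beta_sum / (kept * spec$chains))^2)),
       beta_above = beta_above / (kept * spec$chains),
       beta_below = beta_below / (kept * spec$chains))
}

#' Sensitivity-analysis participant subsets
#'
#' The four nested missing-data subsets: (1) all available participants,
#' (2) excluding early withdrawals, (3) additionally excluding participants
#' with under half their intervention meals yielding valid CGM, and
#' (4) additionally excluding participants with chronic disease or
#' prescription medication use.
#'
#' @param meta Participant metadata tibble.
#' @return Named list of four character vectors of participant ids.
#' @export
sensitivity_subsets <- function(meta) {
  s1 <- meta$participant_id
  s2 <- meta$participant_id[meta$completed_all_periods]
  s3 <- meta$participant_id[meta$completed_all_periods &
                              meta$valid_data_fraction >= 0.5]
  s4 <- meta$participant_id[meta$completed_all_periods &
                              meta$valid_data_fraction >= 0.5 &
                              !meta$chronic_disease_or_medication]
  list(all_available = s1, exclude_withdrawals = s2,
       complete_protocol = s3, complete_no_disease = s4)
}

#' Run the hierarchical fit over all sensitivity subsets
#'
#' @param series Outcome-series tibble for one outcome.
#' @param meta Participant metadata tibble.
#' @param delta Meaningful-difference threshold.
#' @param spec A [hier_spec()].
#' @param outcome Optional outcome filter.
#' @return Tibble with one row per subset: size, population effect, 95%
#'   credible interval, two-sided `p_meaningful` and the dominant single
#'   tail. Empty subsets are reported with `NA` results.
#' @export
run_sensitivity <- function(series, meta, delta, spec = hier_spec(),
                            outcome = NULL) {
  subsets <- sensitivity_subsets(meta)
  rows <- vector("list", length(subsets))
  for (k in seq_along(subsets)) {
    ids <- subsets[[k]]
    nm <- names(subsets)[k]
    sub <- series[series$participant_id %in% ids, , drop = FALSE]
    if (!nrow(sub)) {
      rows[[k]] <- tibble::tibble(subset = nm, n = 0L, effect_mean = NA_real_,
                                  ci_lower = NA_real_, ci_upper = NA_real_,
                                  p_meaningful = NA_real_,
                                  p_dominant = NA_real_)
      next
    }
    sp <- spec
    sp$seed <- child_seed(spec$seed, 70L + k)
    fit <- fit_hierarchical(sub, meta[meta$participant_id %in% ids, ],
                            delta = delta, spec = sp, outcome = outcome)
    rows[[k]] <- tibble::tibble(subset = nm, n = fit$n_participants,
                                effect_mean = fit$effect_mean,
                                ci_lower = fit$ci95[1], ci_upper = fit$ci95[2],
                                p_meaningful = fit$p_meaningful,
                                p_dominant = fit$p_dominant)
  }
  dplyr::bind_rows(rows)
}
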