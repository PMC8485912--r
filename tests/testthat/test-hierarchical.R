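make_cohort_series <- function(effects, sd = 0.3, n_per_arm = 54,
                               baseline = 5) {
  dplyr::bind_rows(lapply(seq_along(effects), function(i) {
    tibble::tibble(
      participant_id = sprintf("P%02d", i), outcome = "MPG",
      value = c(rnorm(n_per_arm, baseline, sd),
                rnorm(n_per_arm, baseline + effects[i], sd)),
      treatment = rep(c(0L, 1L), each = n_per_arm),
      set = rep(rep(1:3, length.out = n_per_arm), 2),
      date = as.Date("2020-01-01") + seq_len(2 * n_per_arm))
  }))
}

make_meta <- function(n, sexes = rep(c("M", "F"), length.out = n)) {
  tibble::tibble(participant_id = sprintf("P%02d", seq_len(n)),
                 age = 22 + (seq_len(n) %% 12), sex = sexes,
                 bmi = 20 + (seq_len(n) %% 8),
                 completed_all_periods = TRUE, valid_data_fraction = 1,
                 chronic_disease_or_medication = FALSE)
}

test_that("a null cohort yields an interval covering zero and small tails", {
  withr::local_seed(30)
  ser <- make_cohort_series(rep(0, 8))
  fit <- fit_hierarchical(ser, make_meta(8), delta = 0.167,
                          spec = quick_hier_spec(seed = 31))
  expect_true(fit$ci95[1] < 0 && fit$ci95[2] > 0)
  expect_lt(fit$p_meaningful, 0.1)
})

test_that("population effect and between-participant sd are recovered", {
  withr::local_seed(32)
  effects <- rnorm(12, 0.3, 0.15)
  ser <- make_cohort_series(effects)
  fit <- fit_hierarchical(ser, make_meta(12), delta = 0.167,
                          spec = quick_hier_spec(seed = 33))
  post_sd <- (fit$ci95[2] - fit$ci95[1]) / (2 * 1.96)
  expect_lt(abs(fit$effect_mean - 0.3), 3 * post_sd)
  expect_gt(fit$tau_mean, 0.15 / 2)
  expect_lt(fit$tau_mean, 0.15 * 2)
  # independent mixed-model cross-check of the population effect
  if (requireNamespace("lme4", quietly = TRUE)) {
    lmm <- lme4::lmer(value ~ treatment + (1 + treatment | participant_id),
                      data = ser)
    expect_equal(fit$effect_mean, unname(lme4::fixef(lmm)["treatment"]),
                 tolerance = 0.05)
  }
})

test_that("opposing responders cancel at the group level", {
  withr::local_seed(34)
  # strong individual effects in both directions, mean ~ 0
  ser <- make_cohort_series(c(0.5, 0.5, 0.5, -0.5, -0.5, -0.5, 0, 0))
  fit <- fit_hierarchical(ser, make_meta(8), delta = 0.167,
                          spec = quick_hier_spec(seed = 35))
  # many individual responders, yet low group-level meaningful probability
  expect_lt(fit$p_meaningful, 0.5)
  expect_lt(fit$p_meaningful, fit$prob_threshold)
})

test_that("shrinkage pulls participant effects toward the population mean", {
  withr::local_seed(36)
  ser <- make_cohort_series(c(-0.2, 0, 0.1, 0.3, 0.6), n_per_arm = 18)
  fit <- fit_hierarchical(ser, NULL, delta = 0.167,
                          spec = quick_hier_spec(seed = 37))
  pe <- fit$participant_effects
  toward <- sign(fit$effect_mean - pe$individual_estimate)
  moved <- sign(pe$shrunken_mean - pe$individual_estimate)
  # every posterior mean moves toward (or sits at) the population mean
  expect_true(all(moved == toward | abs(pe$shrunken_mean -
                                          pe$individual_estimate) < 0.02))

  # forced pooling: tight between-participant variance prior at ~1e-4
  pooled <- fit_hierarchical(ser, NULL, delta = 0.167,
                             spec = quick_hier_spec(seed = 38,
                                                    tau_shape = 1e6,
                                                    tau_scale = 100))
  expect_lt(max(abs(pooled$participant_effects$shrunken_mean -
                      pooled$effect_mean)), 0.03)
  # released pooling: variance prior pinned at ~10, effects stay individual
  free <- fit_hierarchical(ser, NULL, delta = 0.167,
                           spec = quick_hier_spec(seed = 39,
                                                  tau_shape = 1e6,
                                                  tau_scale = 1e7))
  expect_lt(max(abs(free$participant_effects$shrunken_mean -
                      free$participant_effects$individual_estimate)), 0.1)
})

test_that("participant order does not change the posterior", {
  withr::local_seed(40)
  ser <- make_cohort_series(c(0.2, -0.1, 0.4, 0.0))
  perm <- ser[sample(nrow(ser)), ]
  f1 <- fit_hierarchical(ser, make_meta(4), delta = 0.167,
                         spec = quick_hier_spec(seed = 41))
  f2 <- fit_hierarchical(perm, make_meta(4)[c(3, 1, 4, 2), ], delta = 0.167,
                         spec = quick_hier_spec(seed = 41))
  expect_equal(f1$effect_mean, f2$effect_mean)
  expect_equal(f1$ci95, f2$ci95)
  expect_equal(f1$participant_effects, f2$participant_effects)
})

test_that("a single participant reproduces the individual fit", {
  withr::local_seed(42)
  ser <- make_cohort_series(0.4)
  suppressWarnings(
    hier <- fit_hierarchical(ser, NULL, delta = 0.167,
                             spec = hier_spec(chains = 2, iter = 6000,
                                              burn = 1000, seed = 43)))
  indiv <- fit_individual(ser, delta = 0.167,
                          spec = nof1_model_spec(chains = 2, iter = 6000,
                                                 burn = 1000, seed = 44))
  # the participant-level posterior reproduces the individual fit; the
  # population effect itself is only weakly identified from one participant
  pe <- hier$participant_effects
  expect_equal(pe$shrunken_mean, indiv$beta_mean, tolerance = 0.05)
  expect_equal(pe$p_above, indiv$p_above, tolerance = 0.05)
  expect_equal(pe$p_below, indiv$p_below, tolerance = 0.05)
})

test_that("singular covariates are dropped with a warning, never a crash", {
  withr::local_seed(45)
  ser <- make_cohort_series(rep(0.1, 4))
  meta <- make_meta(4, sexes = rep("F", 4)) # one sex only
  expect_warning(
    fit <- fit_hierarchical(ser, meta, delta = 0.167,
                            spec = quick_hier_spec(seed = 46)),
    "sex")
  expect_false(is.null(fit$covariates))
  expect_setequal(fit$covariates$covariate, c("age", "bmi"))
})

test_that("sensitivity subsets are nested and sized as designed", {
  meta <- make_meta(30)
  meta$completed_all_periods[c(4, 17)] <- FALSE
  meta$valid_data_fraction[9] <- 0.31
  meta$chronic_disease_or_medication[22] <- TRUE
  s <- sensitivity_subsets(meta)
  expect_equal(lengths(s), c(all_available = 30L, exclude_withdrawals = 28L,
                             complete_protocol = 27L,
                             complete_no_disease = 26L))
  expect_false("P09" %in% s$complete_protocol)
  expect_true(all(s$complete_no_disease %in% s$complete_protocol))
  # with no flags at all the four subsets coincide
  clean <- make_meta(10)
  expect_true(all(vapply(sensitivity_subsets(clean),
                         identical, logical(1), clean$participant_id)))
})

test_that("run_sensitivity reports one row per subset", {
  withr::local_seed(47)
  ser <- make_cohort_series(rep(0.2, 6), n_per_arm = 18)
  meta <- make_meta(6)
  meta$completed_all_periods[6] <- FALSE
  out <- run_sensitivity(ser, meta, delta = 0.167,
                         spec = quick_hier_spec(seed = 48))
  expect_equal(nrow(out), 4L)
  expect_equal(out$n, c(6L, 5L, 5L, 5L))
  expect_true(all(out$p_meaningful >= 0 & out$p_meaningful <= 1))
  expect_true(all(out$p_dominant <= out$p_meaningful + 1e-12))
})
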