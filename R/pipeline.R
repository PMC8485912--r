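#' Default end-to-end pipeline configuration
#'
#' A nested list controlling every stage: the synthetic cohort (or input
#' directory), metric settings, thresholds, individual- and group-level
#' sampler settings, dose-response and power toggles. All fields can be
#' overridden in a JSON file read by [read_config()].
#'
#' @param seed Master integer seed; every stage derives its own stream.
#' @return Named list.
#' @export
default_config <- function(seed = 20191020L) {
  list(
    seed = as.integer(seed),
    input_dir = NULL, # read artifacts instead of simulating when set
    cohort = list(n_participants = 30L, n_sets = 3L, days_per_period = 6L,
                  mixture = c(HC = 9, HF = 6, non = 13) / 28,
                  effect_hc = 0.3, effect_hf = -0.3, noise_sd = 0.3,
                  ar1_rho = 0.7, missing_meal_prob = 0.02,
                  n_withdrawals = 2L, n_low_valid = 1L, n_flagged = 1L),
    metrics = list(coverage_min = 0.7, mage_direction = "both",
                   mage_smooth = FALSE),
    thresholds = list(MPG = 0.167, MAGE = 0.072, AUC24 = 13.889),
    individual = list(chains = 4L, iter = 10000L, burn = 2000L,
                      method = "observation", prob_threshold = 0.8),
    hierarchical = list(chains = 4L, iter = 10000L, burn = 2000L,
                        prob_threshold = 0.9, sensitivity = TRUE),
    dose_response = list(run = TRUE, outcome = "MPG"),
    power = list(run = TRUE, n_simulations = 200L, effect = 0.167,
                 between_sd = 0.1, residual_sd = 0.8),
    write_inputs = TRUE)
}

#' Read and validate a pipeline configuration file
#'
#' JSON fields override [default_config()]; unknown top-level fields raise
#' an error rather than being silently ignored.
#'
#' @param path JSON file path.
#' @return Configuration list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop_format("config file not found: %s", path)
  user <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  base <- default_config()
  unknown <- setdiff(names(user), names(base))
  if (length(unknown)) {
    stop_validation("unknown config field(s): %s", paste(unknown, collapse = ", "))
  }
  cfg <- utils::modifyList(base, user)
  if (!is.null(cfg$cohort$mixture)) {
    cfg$cohort$mixture <- stats::setNames(as.numeric(cfg$cohort$mixture),
                                          names(cfg$cohort$mixture) %||%
                                            c("HC", "HF", "non"))
  }
  for (f in c("seed")) assert_scalar_number(cfg[[f]], f)
  cfg
}

#' Run the full analysis pipeline
#'
#' Executes `simulate (or load) -> metrics -> individual fits -> responder
#' classification -> hierarchical meta-analysis (+ sensitivity subsets) ->
#' dose-response -> power` and writes all result tables, a markdown report
#' laid out like the trial's posterior-probability and responder tables, and
#' a run manifest with the configuration hash and seeds. The pipeline stops
#' at the first failing stage, leaving a `PIPELINE_FAILED` marker naming the
#' stage.
#'
#' @param config Configuration list (see [default_config()]).
#' @param out_dir Output directory.
#' @return Invisibly, a list with all in-memory results.
#' @export
run_pipeline <- function(config = default_config(), out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  stage <- "init"
  on_fail <- function(e) {
    writeLines(c(stage, conditionMessage(e)),
               file.path(out_dir, "PIPELINE_FAILED"))
    rlang::abort(sprintf("pipeline failed at stage '%s': %s", stage,
                         conditionMessage(e)), parent = e)
  }
  tryCatch({
    stage <- "simulate"
    if (!is.null(config$input_dir)) {
      data <- list(
        design = read_design(file.path(config$input_dir, "design.csv")),
        cgm = read_cgm(file.path(config$input_dir, "cgm.csv"),
                       unit_hint = "auto"),
        meta = read_participant_meta(file.path(config$input_dir, "meta.csv")))
      data$meals <- read_meal_log(file.path(config$input_dir, "meals.csv"),
                                  design = data$design)
      data$truth <- NULL
    } else {
      spec <- do.call(cohort_spec, c(config$cohort,
                                     list(seed = child_seed(config$seed, 1L))))
      data <- generate_cohort(spec)
    }

    stage <- "metrics"
    meal_metrics <- suppressWarnings(
      compute_meal_metrics(data$cgm, data$meals))
    daily_metrics <- compute_daily_metrics(
      data$cgm, data$meals, coverage_min = config$metrics$coverage_min,
      meal_metrics = meal_metrics,
      mage_direction = config$metrics$mage_direction,
      mage_smooth = config$metrics$mage_smooth)
    series <- build_outcome_series(meal_metrics, daily_metrics, data$design)

    stage <- "fit-individual"
    thresholds <- unlist(config$thresholds)
    ispec <- nof1_model_spec(chains = config$individual$chains,
                             iter = config$individual$iter,
                             burn = config$individual$burn,
                             method = config$individual$method,
                             seed = child_seed(config$seed, 2L))
    posterior <- fit_cohort(series, thresholds, ispec)

    stage <- "classify"
    calls <- classify_responders(posterior,
                                 config$individual$prob_threshold)
    call_summary <- summarize_cohort_calls(calls)

    stage <- "fit-group"
    hspec <- hier_spec(chains = config$hierarchical$chains,
                       iter = config$hierarchical$iter,
                       burn = config$hierarchical$burn,
                       prob_threshold = config$hierarchical$prob_threshold,
                       seed = child_seed(config$seed, 3L))
    group <- list()
    sensitivity <- list()
    for (oc in intersect(names(thresholds), unique(series$outcome))) {
      sp <- hspec
      sp$seed <- child_seed(config$seed, 30L + match(oc, names(thresholds)))
      group[[oc]] <- fit_hierarchical(series, data$meta,
                                      delta = thresholds[[oc]], spec = sp,
                                      outcome = oc)
      if (isTRUE(config$hierarchical$sensitivity)) {
        sensitivity[[oc]] <- dplyr::mutate(
          run_sensitivity(series[series$outcome == oc, ], data$meta,
                          delta = thresholds[[oc]], spec = sp, outcome = oc),
          outcome = oc, .before = 1)
      }
    }

    stage <- "dose-response"
    dose <- NULL
    if (isTRUE(config$dose_response$run)) {
      oc <- config$dose_response$outcome
      dspec <- ispec
      dspec$seed <- child_seed(config$seed, 4L)
      dose <- dose_response_fit(series[series$outcome == oc, ],
                                delta = thresholds[[oc]], spec = dspec)
    }

    stage <- "power"
    power <- NULL
    if (isTRUE(config$power$run)) {
      power <- run_power(power_config(
        n_participants = config$cohort$n_participants,
        n_sets = config$cohort$n_sets,
        obs_per_period = 3L * config$cohort$days_per_period,
        effect = config$power$effect,
        between_sd = config$power$between_sd,
        residual_sd = config$power$residual_sd,
        n_simulations = config$power$n_simulations,
        seed = child_seed(config$seed, 5L)))
    }

    stage <- "report"
    results <- list(meal_metrics = meal_metrics,
                    daily_metrics = daily_metrics,
                    outcome_series = series, posterior = posterior,
                    calls = calls)
    if (!is.null(dose)) results$dose_response <- dose$contrasts
    if (length(sensitivity)) {
      results$group_sensitivity <- dplyr::bind_rows(sensitivity)
    }
    if (isTRUE(config$write_inputs)) {
      results <- c(results, data[!vapply(data, is.null, logical(1))])
    }
    write_results(results, out_dir, config = config, seed = config$seed)
    group_json <- lapply(group, function(g) {
      list(outcome = g$outcome, effect_mean = g$effect_mean,
           ci95 = g$ci95, p_above = g$p_above, p_below = g$p_below,
           p_meaningful = g$p_meaningful, tau_mean = g$tau_mean,
           n_participants = g$n_participants, rhat = g$rhat)
    })
    jsonlite::write_json(group_json, file.path(out_dir, "group.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    if (!is.null(power)) {
      jsonlite::write_json(
        list(power = power$power, power_ci = power$power_ci,
             type1 = power$type1, type1_ci = power$type1_ci,
             n_simulations = power$n_simulations),
        file.path(out_dir, "power.json"), auto_unbox = TRUE, digits = NA,
        pretty = TRUE)
    }
    writeLines(render_report(posterior, calls, call_summary, group,
                             power, config),
               file.path(out_dir, "report.md"))
    invisible(list(data = data, meal_metrics = meal_metrics,
                   daily_metrics = daily_metrics, series = series,
                   posterior = posterior, calls = calls,
                   call_summary = call_summary, group = group,
                   sensitivity = sensitivity, dose = dose, power = power))
  }, error = on_fail)
}

# Markdown report laid out like the trial tables: per-participant posterior
# probabilities (percent) per outcome, responder counts, group results.
render_report <- function(posterior, calls, call_summary, group, power,
                          config) {
  fmt <- function(x, d = 1) formatC(x, digits = d, format = "f")
  lines <- c("# n-of-1 CGM analysis report", "",
             sprintf("Seed: %d. Individual responder threshold: %.0f%%; group threshold: %.0f%%.",
                     config$seed, 100 * config$individual$prob_threshold,
                     100 * config$hierarchical$prob_threshold), "",
             "## Individual posterior probabilities (%)", "",
             "| Participant | MPG <-d | MPG >+d | MAGE <-d | MAGE >+d | AUC24 <-d | AUC24 >+d |",
             "|---|---|---|---|---|---|---|")
  wide <- tidyr::pivot_wider(
    posterior[, c("participant_id", "outcome", "p_below", "p_above")],
    names_from = "outcome", values_from = c("p_below", "p_above"))
  for (r in seq_len(nrow(wide))) {
    g <- function(col) {
      if (col %in% names(wide)) fmt(100 * wide[[col]][r]) else "-"
    }
    lines <- c(lines, sprintf("| %s | %s | %s | %s | %s | %s | %s |",
                              wide$participant_id[r],
                              g("p_below_MPG"), g("p_above_MPG"),
                              g("p_below_MAGE"), g("p_above_MAGE"),
                              g("p_below_AUC24"), g("p_above_AUC24")))
  }
  lines <- c(lines, "", "## Responder counts", "")
  bo <- call_summary$by_outcome
  for (r in seq_len(nrow(bo))) {
    lines <- c(lines, sprintf("- %s: %s = %d", bo$outcome[r], bo$call[r],
                              bo$n[r]))
  }
  oc <- call_summary$overall_counts
  lines <- c(lines, sprintf(
    "- Overall (MPG or MAGE): %d HC-responders, %d HF-responders, %d nonresponders%s",
    oc[["HC-responder"]], oc[["HF-responder"]], oc[["nonresponder"]],
    if (oc[["conflict"]] > 0) sprintf(", %d conflicts", oc[["conflict"]]) else ""))
  lines <- c(lines, "", "## Group-level (hierarchical) results", "")
  for (g in group) {
    lines <- c(lines, sprintf(
      "- %s: effect %.3f [%.3f, %.3f]; P(meaningful) = %.1f%%",
      g$outcome, g$effect_mean, g$ci95[1], g$ci95[2], 100 * g$p_meaningful))
  }
  if (!is.null(power)) {
    lines <- c(lines, "", "## Power", "",
               sprintf("- Estimated power %.1f%% [%.1f%%, %.1f%%] over %d simulations; type-I error %.3f.",
                       100 * power$power, 100 * power$power_ci[1],
                       100 * power$power_ci[2], power$n_simulations,
                       power$type1))
  }
  lines
}

#' Forest plot of individual treatment effects
#'
#' Posterior means and 95% credible intervals per participant, ordered by
#' effect, with the meaningful-difference thresholds marked. Requires
#' ggplot2.
#'
#' @param posterior Posterior summary tibble from [fit_cohort()] (one
#'   outcome).
#' @param delta Threshold drawn as horizontal reference lines.
#' @return A ggplot object.
#' @export
plot_effect_forest <- function(posterior, delta = unique(posterior$delta)) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    rlang::abort("plot_effect_forest() requires the ggplot2 package")
  }
  df <- dplyr::arrange(posterior, .data$beta_mean)
  df$participant_id <- factor(df$participant_id,
                              levels = df$participant_id)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$participant_id,
                                   y = .data$beta_mean)) +
    ggplot2::geom_hline(yintercept = c(-delta, delta), linetype = "dotted") +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$ci_lower,
                                          ymax = .data$ci_upper)) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "LF-HC minus HF-LC difference (mmol/L)")
}
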