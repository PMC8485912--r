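#' Read a wide table of posterior tail probabilities
#'
#' Reads a CSV with one row per participant and, per outcome, the posterior
#' probabilities (in percent) that the LF-HC minus HF-LC difference lies
#' below the negative threshold and above the positive threshold
#' (`p_below_mpg, p_above_mpg, p_below_mage, p_above_mage, p_below_auc24,
#' p_above_auc24`). Returns the long format used by
#' [classify_responders()], with probabilities as proportions.
#'
#' A reference table of the published 28-participant trial probabilities
#' ships with the package:
#' `system.file("extdata", "published_trial_posteriors.csv",
#'  package = "nof1cgm")`.
#'
#' @param path CSV file path.
#' @return Tibble `participant_id, outcome, p_below, p_above`.
#' @export
read_probability_table <- function(path) {
  raw <- read_csv_quiet(path, readr::cols(
    participant_id = readr::col_character(),
    .default = readr::col_double()))
  out <- list()
  for (oc in c("mpg", "mage", "auc24")) {
    lo <- paste0("p_below_", oc)
    hi <- paste0("p_above_", oc)
    if (!all(c(lo, hi) %in% names(raw))) next
    out[[oc]] <- tibble::tibble(
      participant_id = raw$participant_id,
      outcome = toupper(oc),
      p_below = raw[[lo]] / 100,
      p_above = raw[[hi]] / 100)
  }
  if (!length(out)) stop_format("no p_below_*/p_above_* column pairs found in %s", path)
  res <- dplyr::bind_rows(out)
  if (any(res$p_below < 0 | res$p_below > 1 | res$p_above < 0 |
            res$p_above > 1, na.rm = TRUE)) {
    stop_validation("probabilities must lie in [0, 100] percent")
  }
  res
}
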