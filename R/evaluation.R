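# Hit rate and capture rate: precision and recall of identifying, from
# predicted life expectancy, the patients who die (or are delisted as too
# sick) within an analysis period tau.

#' Metrics configuration
#'
#' @param tau analysis period in years (> 0).
#' @param min_correct suppression threshold: reports with fewer correctly
#'   identified patients are flagged suppressed (default 15).
#' @param censor_policy only `"exclude_censored_before_tau"` is implemented:
#'   patients censored before tau without a death are removed from both
#'   denominators, since their tau-year status is unknown.
#' @return an object of class `metrics_config`.
#' @export
metrics_config <- function(tau, min_correct = 15,
                           censor_policy = "exclude_censored_before_tau") {
  stopifnot(tau > 0, min_correct >= 0)
  censor_policy <- match.arg(censor_policy, "exclude_censored_before_tau")
  structure(list(tau = tau, min_correct = min_correct,
                 censor_policy = censor_policy),
            class = "metrics_config")
}

#' Hit rate and capture rate of survival predictions
#'
#' Identified patients are those with predicted life expectancy `<= tau`
#' (inclusive). Deaths are death-or-delisting outcomes with time `<= tau`.
#' Hit rate = correctly identified / identified (precision); capture rate =
#' correctly identified / deaths within tau (recall). Undefined rates (empty
#' denominator) are returned as `NA` with an explicit flag, never silently 0.
#'
#' @param predicted_le data frame with `patient_id` and `predicted_le`
#'   (years).
#' @param outcomes data frame with `patient_id`, `outcome_type`,
#'   `outcome_time`; keyed identically to `predicted_le`.
#' @param config a [metrics_config()].
#' @return an object of class `metrics_report`: counts `n_identified`,
#'   `n_died_within_tau`, `n_correct`, rates `hit_rate` and `capture_rate`,
#'   flags `hit_rate_undefined`, `capture_rate_undefined`, `suppressed`, and
#'   the evaluation settings.
#' @export
evaluate_predictions <- function(predicted_le, outcomes, config) {
  stopifnot(inherits(config, "metrics_config"))
  df <- merge(predicted_le, outcomes, by = "patient_id")
  if (nrow(df) != nrow(predicted_le) || nrow(df) != nrow(outcomes)) {
    stop("predictions and outcomes must be keyed identically", call. = FALSE)
  }
  tau <- config$tau
  excluded <- df$outcome_type == "censored" & df$outcome_time < tau
  df <- df[!excluded, , drop = FALSE]
  if (nrow(df) == 0) stop("empty evaluation population", call. = FALSE)
  identified <- df$predicted_le <= tau
  died <- df$outcome_type == "death_or_delisting" & df$outcome_time <= tau
  n_id <- sum(identified)
  n_died <- sum(died)
  n_correct <- sum(identified & died)
  structure(list(
    n_population = nrow(df), n_excluded = sum(excluded),
    n_identified = n_id, n_died_within_tau = n_died, n_correct = n_correct,
    hit_rate = if (n_id > 0) n_correct / n_id else NA_real_,
    capture_rate = if (n_died > 0) n_correct / n_died else NA_real_,
    hit_rate_undefined = n_id == 0,
    capture_rate_undefined = n_died == 0,
    suppressed = n_correct < config$min_correct,
    tau = tau, censor_policy = config$censor_policy
  ), class = "metrics_report")
}

#' Brute-force confusion recount
#'
#' Independent per-patient loop producing the identified / died / correct
#' counts under the same censoring policy as [evaluate_predictions()]. Used
#' as an oracle in testing; the two must agree exactly.
#'
#' @param predicted_le,outcomes as in [evaluate_predictions()].
#' @param tau analysis period in years.
#' @return named integer vector: `n_identified`, `n_died_within_tau`,
#'   `n_correct`.
#' @export
oracle_confusion <- function(predicted_le, outcomes, tau) {
  le <- predicted_le$predicted_le[match(outcomes$patient_id,
                                        predicted_le$patient_id)]
  n_id <- 0L; n_died <- 0L; n_corr <- 0L
  for (i in seq_len(nrow(outcomes))) {
    type <- outcomes$outcome_type[i]
    time <- outcomes$outcome_time[i]
    if (type == "censored" && time < tau) next
    id_i <- le[i] <= tau
    died_i <- type == "death_or_delisting" && time <= tau
    if (id_i) n_id <- n_id + 1L
    if (died_i) n_died <- n_died + 1L
    if (id_i && died_i) n_corr <- n_corr + 1L
  }
  c(n_identified = n_id, n_died_within_tau = n_died, n_correct = n_corr)
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(
    "tau = %g yr | identified %d, died %d, correct %d | hit %s, capture %s%s\n",
    x$tau, x$n_identified, x$n_died_within_tau, x$n_correct,
    if (x$hit_rate_undefined) "undef" else sprintf("%.3f", x$hit_rate),
    if (x$capture_rate_undefined) "undef" else sprintf("%.3f", x$capture_rate),
    if (x$suppressed) " [suppressed: < min_correct]" else ""))
  invisible(x)
}
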