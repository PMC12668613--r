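# Equipoise engine: compare each active patient's status-quo life expectancy
# on the waitlist with the life expectancy of accepting a xenograft assumed to
# survive n years, where
#
#   LE_xeno(n) = n + p_relist * LE_after_relisting
#
# and LE_after_relisting is the expected remaining life after rejoining the
# allotransplant waitlist when the xenograft fails (see the incentive-scenario
# recursion). A patient is viable (reaches clinical equipoise) at a given n
# when LE_xeno strictly exceeds the status-quo life expectancy. The CPRA score
# is assumed unchanged after xenograft failure; covariates are frozen at their
# snapshot values.

#' Xenograft survival assumptions
#'
#' @param n_grid assumed xenograft survival values (years) for the sensitivity
#'   analysis; default `{0.5, 1, 1.5, 2, 3, 4, 5}`.
#' @param q percentile used by the highest-priority scenario (default 75).
#' @param cpra_policy only `"fixed"` is implemented: the CPRA is held at its
#'   pre-xenograft value after graft failure. The knob exists so sensitization
#'   shifts can be injected later.
#' @return an object of class `xeno_assumptions`.
#' @export
xeno_assumptions <- function(n_grid = c(0.5, 1, 1.5, 2, 3, 4, 5), q = 75,
                             cpra_policy = "fixed") {
  stopifnot(all(n_grid > 0), !is.unsorted(n_grid), q > 0, q <= 100)
  cpra_policy <- match.arg(cpra_policy, "fixed")
  structure(list(n_grid = n_grid, q = q, cpra_policy = cpra_policy),
            class = "xeno_assumptions")
}

#' Probability of relisting after graft failure
#'
#' The probability that a patient rejoins the waitlist after their graft fails
#' is proxied by relisting behaviour following allograft failure observed in
#' the registry. Two estimate levels: `"individual"` fits a logistic model of
#' relisting on patient covariates among graft failures and predicts per
#' patient; `"cohort"` returns the empirical fraction relisted among graft
#' failures in `records` (after any cohort filtering by the caller).
#'
#' @param records registry patient records containing `graft_failed` and
#'   `relisted` indicators.
#' @param patients patients to predict for (individual level); defaults to
#'   `records`.
#' @param level `"individual"` or `"cohort"`.
#' @param covariates covariates for the logistic model.
#' @return data frame with columns `patient_id`, `probability`, `level`,
#'   `n_events` (individual), or a one-row data frame with `patient_id = NA`
#'   (cohort).
#' @export
estimate_relist_probability <- function(records, patients = records,
                                        level = c("individual", "cohort"),
                                        covariates = c("age_at_listing",
                                                       "diabetes", "cpra")) {
  level <- match.arg(level)
  failures <- records[records$graft_failed %in% 1L, , drop = FALSE]
  if (nrow(failures) == 0) {
    stop("zero graft failures in stratum; fall back to the parent cohort",
         call. = FALSE)
  }
  if (level == "cohort") {
    return(data.frame(patient_id = NA_integer_,
                      probability = mean(failures$relisted),
                      level = "cohort", n_events = nrow(failures)))
  }
  f <- stats::reformulate(covariates, response = "relisted")
  fit <- suppressWarnings(
    stats::glm(f, data = failures, family = stats::binomial()))
  p <- stats::predict(fit, newdata = patients, type = "response")
  data.frame(patient_id = patients$patient_id, probability = unname(p),
             level = "individual", n_events = nrow(failures))
}

#' Life expectancy with a xenotransplant
#'
#' `n` years of assumed xenograft function plus, with the relisting
#' probability, the expected life after rejoining the allotransplant waitlist.
#' All arguments are vectorised.
#'
#' @param n assumed xenograft survival in years (> 0).
#' @param relist_probability probability of rejoining the waitlist after
#'   xenograft failure, in `[0, 1]`.
#' @param le_relist expected life years after relisting (>= 0).
#' @return life expectancy with a xenotransplant, in years; always >= `n`.
#' @export
le_with_xeno <- function(n, relist_probability, le_relist) {
  if (any(n <= 0)) stop("n must be positive", call. = FALSE)
  if (any(relist_probability < 0 | relist_probability > 1)) {
    stop("relist probability must lie in [0, 1]", call. = FALSE)
  }
  if (any(le_relist < 0)) stop("le_relist must be non-negative", call. = FALSE)
  n + relist_probability * le_relist
}

#' Identify patients reaching clinical equipoise
#'
#' For every active patient and every `n` in the sensitivity grid, compares
#' the status-quo life expectancy (restricted mean of the predicted waitlist
#' survival curve at the patient's own covariates, including elapsed waiting
#' time) with `n + p_relist * le_relist`. Viability uses a strict inequality:
#' exact ties are not viable.
#'
#' @param patients active patient records (an error is raised if any inactive
#'   patient is present; filter first).
#' @param death_model fitted waitlist-death model.
#' @param assumptions an [xeno_assumptions()] object.
#' @param relist_probability per-patient relisting probabilities (recycled if
#'   scalar).
#' @param le_relist per-patient life expectancy after relisting, either a
#'   vector (independent of n, the base scenario) or a matrix with one column
#'   per value of `n_grid`.
#' @return data frame: `patient_id`, `n`, `le_status_quo`, `le_xeno`,
#'   `viable`.
#' @export
identify_viable <- function(patients, death_model, assumptions,
                            relist_probability, le_relist) {
  if (any(patients$active %in% 0L)) {
    stop("inactive patients present; exclude them before the equipoise analysis",
         call. = FALSE)
  }
  stopifnot(inherits(assumptions, "xeno_assumptions"))
  np <- nrow(patients)
  relist_probability <- rep_len(relist_probability, np)
  S <- predict_curve_matrix(death_model, patients)
  le_sq <- trapz_rows(death_model$grid, S)
  if (is.matrix(le_relist)) {
    stopifnot(nrow(le_relist) == np,
              ncol(le_relist) == length(assumptions$n_grid))
  } else {
    le_relist <- matrix(rep_len(le_relist, np), nrow = np,
                        ncol = length(assumptions$n_grid))
  }
  out <- do.call(rbind, lapply(seq_along(assumptions$n_grid), function(j) {
    n <- assumptions$n_grid[j]
    le_x <- le_with_xeno(n, relist_probability, le_relist[, j])
    data.frame(patient_id = patients$patient_id, n = n, le_status_quo = le_sq,
               le_xeno = le_x, viable = le_x > le_sq)
  }))
  rownames(out) <- NULL
  out
}

#' Sensitivity table over the xenograft-survival grid
#'
#' Aggregates equipoise results to (optionally per-cohort) viable counts and
#' fractions per value of n.
#'
#' @param results output of [identify_viable()].
#' @param n_grid expected grid; an error is raised if any value is missing
#'   from the results.
#' @param membership optional logical matrix (patients x cohorts, column names
#'   = cohort ids) aligned with the distinct patients in `results`; when given
#'   the table is produced per cohort.
#' @return data frame with `n`, `count_viable`, `n_patients`,
#'   `fraction_viable` (and `cohort_id` when membership is supplied), sorted
#'   by n.
#' @export
sensitivity_table <- function(results, n_grid = sort(unique(results$n)),
                              membership = NULL) {
  have <- sort(unique(results$n))
  miss <- setdiff(n_grid, have)
  if (length(miss) > 0) {
    stop("results missing n = ", paste(miss, collapse = ", "), call. = FALSE)
  }
  one <- function(res, cohort_id = NA) {
    agg <- do.call(rbind, lapply(sort(n_grid), function(n) {
      sub <- res[res$n == n, ]
      data.frame(cohort_id = cohort_id, n = n, count_viable = sum(sub$viable),
                 n_patients = nrow(sub),
                 fraction_viable = if (nrow(sub)) mean(sub$viable) else NA_real_)
    }))
    agg
  }
  if (is.null(membership)) {
    out <- one(results)
    out$cohort_id <- NULL
    return(out)
  }
  ids <- unique(results$patient_id)
  stopifnot(nrow(membership) == length(ids))
  do.call(rbind, lapply(colnames(membership), function(cid) {
    keep <- ids[membership[, cid]]
    one(results[results$patient_id %in% keep, , drop = FALSE], cohort_id = cid)
  }))
}
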