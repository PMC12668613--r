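# Survival model fitting and per-patient curve prediction for the three
# targets of the analysis: death-or-delisting on the waitlist, time to
# (deceased-donor) transplant, and death after a transplant. Backends: Cox
# proportional hazards (survival::coxph, Efron ties), random survival forest
# (ranger), and Kaplan-Meier (covariate-free). Time-to-transplant is modelled
# as the "survival" of the transplant-free state with death treated as
# censoring; a competing-risks cumulative-incidence variant is available in
# km_with_band(competing = TRUE).

model_targets <- c("waitlist_death", "time_to_transplant", "post_transplant_death")

#' Default covariate list per modelling target
#' @param target one of `waitlist_death`, `time_to_transplant`,
#'   `post_transplant_death`.
#' @return character vector of covariate names.
#' @export
default_covariates <- function(target) {
  switch(match.arg(target, model_targets),
    waitlist_death = c("age_at_listing", "diabetes", "blood_type",
                       "previous_transplant", "cpra", "albumin", "sdi",
                       "waiting_time_elapsed", "chf"),
    time_to_transplant = c("age_at_listing", "diabetes", "blood_type",
                           "previous_transplant", "cpra",
                           "waiting_time_elapsed"),
    post_transplant_death = c("age_at_tx", "diabetes", "previous_transplant",
                              "donor_quality")
  )
}

# response (time, event) per target; post-transplant target subsets to
# transplanted patients and clocks from the transplant
surv_frame <- function(records, target) {
  target <- match.arg(target, model_targets)
  if (target == "post_transplant_death") {
    records <- records[!is.na(records$post_tx_time), , drop = FALSE]
    if (nrow(records) == 0) stop("estimation error: no transplanted patients",
                                 call. = FALSE)
    records$age_at_tx <- records$age_at_listing + records$waiting_time_elapsed +
      records$outcome_time
    records$time <- records$post_tx_time
    records$event <- as.integer(records$post_tx_event)
  } else {
    ev <- if (target == "waitlist_death") "death_or_delisting" else "transplant"
    records$time <- records$outcome_time
    records$event <- as.integer(records$outcome_type == ev)
  }
  records
}

prep_covariates <- function(df, covariates) {
  missing <- setdiff(covariates, names(df))
  if ("age_at_tx" %in% missing &&
      all(c("age_at_listing", "waiting_time_elapsed") %in% names(df))) {
    df$age_at_tx <- df$age_at_listing + df$waiting_time_elapsed +
      (df$outcome_time %||% 0)
    missing <- setdiff(missing, "age_at_tx")
  }
  if (length(missing) > 0) {
    stop("missing covariate: ", missing[1], call. = FALSE)
  }
  if ("blood_type" %in% covariates) {
    df$blood_type <- factor(df$blood_type, levels = c("A", "B", "AB", "O"))
  }
  df
}

#' Fit a survival model
#'
#' @param records patient records (active patients only; rows flagged inactive
#'   must be filtered by the caller, mirroring the exclusion of inactive
#'   candidates from the study population).
#' @param target one of `waitlist_death`, `time_to_transplant`,
#'   `post_transplant_death`.
#' @param backend `"cox"` (proportional hazards, Efron ties), `"rsf"` (random
#'   survival forest via ranger, seeded) or `"km"` (covariate-free
#'   Kaplan-Meier).
#' @param covariates covariate names; defaults per target.
#' @param horizon curve horizon in years; curves are carried at their last
#'   estimated value out to the horizon (no tail extrapolation).
#' @param step curve grid step in years.
#' @param seed seed recorded in the model and used by the forest.
#' @param num_trees forest size for the rsf backend.
#' @param min_node_size minimum terminal node size for the rsf backend;
#'   event times are discretised to the curve grid before growing the forest
#'   (consistent with the monthly reporting grid and much cheaper than
#'   per-observation event times).
#' @return an object of class `xeno_surv_model`.
#' @export
fit_model <- function(records, target, backend = c("cox", "rsf", "km"),
                      covariates = default_covariates(target), horizon = 25,
                      step = 1 / 12, seed = 1, num_trees = 300,
                      min_node_size = 50) {
  backend <- match.arg(backend)
  target <- match.arg(target, model_targets)
  dat <- surv_frame(records, target)
  n_events <- sum(dat$event)
  if (n_events == 0) stop("estimation error: zero events for target ", target,
                          call. = FALSE)
  if (n_events < 50) {
    warning("only ", n_events, " events for target ", target,
            "; estimates will be unstable", call. = FALSE)
  }
  if (any(dat$active %in% 0L)) {
    stop("inactive patients present; exclude them before fitting", call. = FALSE)
  }
  grid <- time_grid(horizon, step)
  model <- structure(
    list(backend = backend, target = target, covariates = covariates,
         horizon = horizon, step = step, grid = grid, seed = seed,
         n_events = n_events),
    class = "xeno_surv_model"
  )
  if (backend == "km") {
    fit <- survival::survfit(survival::Surv(dat$time, dat$event) ~ 1)
    model$S0grid <- step_eval(c(0, fit$time), c(1, fit$surv), grid)
    return(model)
  }
  dat <- prep_covariates(dat, covariates)
  f <- stats::reformulate(covariates, response = "Surv(time, event)")
  environment(f) <- new.env(parent = asNamespace("survival"))
  if (backend == "cox") {
    fit <- survival::coxph(f, data = dat, ties = "efron", x = TRUE, y = TRUE,
                           model = FALSE)
    if (anyNA(stats::coef(fit))) {
      bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
      drop_cov <- unique(unlist(lapply(covariates, function(v) {
        if (any(startsWith(bad, v))) v else NULL
      })))
      warning("collinear covariate dropped: ", paste(drop_cov, collapse = ", "),
              call. = FALSE)
      covariates <- setdiff(covariates, drop_cov)
      model$covariates <- covariates
      f <- stats::reformulate(covariates, response = "Surv(time, event)")
      environment(f) <- new.env(parent = asNamespace("survival"))
      fit <- survival::coxph(f, data = dat, ties = "efron", x = TRUE, y = TRUE,
                             model = FALSE)
    }
    bh <- survival::basehaz(fit, centered = TRUE)
    model$fit <- fit
    model$H0grid <- step_eval(c(0, bh$time), c(0, bh$hazard), grid)
    model$train_sd <- covariate_sds(dat, covariates)
  } else {
    dat$time <- ceiling(dat$time / step) * step
    fit <- ranger::ranger(f, data = dat, num.trees = num_trees, seed = seed,
                          min.node.size = min_node_size, num.threads = 1)
    model$fit <- fit
  }
  model
}

# right-continuous step-function evaluation (carry last value forward)
step_eval <- function(x, y, xout) {
  y[pmax(findInterval(xout + 1e-12, x), 1L)]
}

covariate_sds <- function(dat, covariates) {
  mm <- stats::model.matrix(stats::reformulate(covariates), data = dat)
  apply(mm[, -1, drop = FALSE], 2, stats::sd)
}

#' Constant-hazard parametric model
#'
#' A fully specified exponential model: every patient gets the curve
#' `S(t) = exp(-rate * t)`. Useful for scenario analyses with known hazards
#' and for validating the semi-Markov recursion against closed forms.
#'
#' @param rate per-year hazard.
#' @param target modelling target label.
#' @param horizon,step curve grid.
#' @return an object of class `xeno_surv_model` with backend `"exponential"`.
#' @export
constant_hazard_model <- function(rate, target = "waitlist_death", horizon = 25,
                                  step = 1 / 12) {
  stopifnot(rate >= 0)
  grid <- time_grid(horizon, step)
  structure(
    list(backend = "exponential", target = match.arg(target, model_targets),
         covariates = character(), horizon = horizon, step = step, grid = grid,
         seed = NA_integer_, n_events = NA_integer_, rate = rate,
         S0grid = exp(-rate * grid)),
    class = "xeno_surv_model"
  )
}

#' Predicted survival curves for a set of patients
#'
#' Matrix of per-patient survival probabilities of the model's target event on
#' the model grid (rows = patients). For the `time_to_transplant` target this
#' is the transplant-free probability; use [as_incidence()] on single curves
#' or `1 - S` on the matrix for the cumulative transplant probability.
#'
#' @param model a fitted `xeno_surv_model`.
#' @param newdata patient data frame containing the model covariates.
#' @return numeric matrix `nrow(newdata) x length(model$grid)`.
#' @export
predict_curve_matrix <- function(model, newdata) {
  stopifnot(inherits(model, "xeno_surv_model"))
  n <- nrow(newdata)
  G <- length(model$grid)
  if (model$backend %in% c("km", "exponential")) {
    return(matrix(model$S0grid, nrow = n, ncol = G, byrow = TRUE))
  }
  newdata <- prep_covariates(as.data.frame(newdata), model$covariates)
  if (model$backend == "cox") {
    lp <- unname(stats::predict(model$fit, newdata = newdata, type = "lp"))
    S <- exp(-outer(exp(lp), model$H0grid))
  } else {
    pr <- stats::predict(model$fit, data = newdata, num.threads = 1)
    ut <- pr$unique.death.times
    sv <- pr$survival
    if (is.null(dim(sv))) sv <- matrix(sv, nrow = 1)
    idx <- pmax(findInterval(model$grid + 1e-12, ut), 0L) + 1L
    S <- cbind(1, sv)[, idx, drop = FALSE]
    # enforce monotonicity against numerical jitter in the forest estimates
    S <- t(apply(S, 1, cummin))
  }
  S[, 1] <- 1
  pmin(pmax(S, 0), 1)
}

#' Predicted curve for one patient
#'
#' @param model a fitted `xeno_surv_model`.
#' @param patient a one-row data frame (or list coercible to one) with the
#'   model covariates; an error names any missing covariate.
#' @return a [survival_curve()] of the target event-free probability.
#' @export
predict_curve <- function(model, patient) {
  patient <- as.data.frame(patient)
  if (nrow(patient) != 1L) stop("predict_curve expects a single patient",
                                call. = FALSE)
  S <- predict_curve_matrix(model, patient)
  survival_curve(model$grid, drop(S), horizon = model$horizon)
}

#' Kaplan-Meier curve with 95% confidence band
#'
#' Product-limit estimate with Greenwood-based log-log confidence bounds. For
#' the `time_to_transplant` target returns one-minus-KM of the transplant
#' event with death treated as censoring (the default), or the competing-risks
#' cumulative incidence (Aalen-Johansen) when `competing = TRUE`. Results
#' based on fewer than `min_events` events are flagged `suppressed` (the
#' suppression rule applied to all small-count reporting).
#'
#' @param records patient records.
#' @param target `waitlist_death` or `time_to_transplant`.
#' @param competing use the competing-risks cumulative incidence for the
#'   transplant target instead of censoring death.
#' @param min_events suppression threshold (default 15).
#' @param conf_level confidence level for the band.
#' @param horizon,step output grid.
#' @return an object of class `curve_with_band`: fields `curve`, `lower`,
#'   `upper`, `n_events`, `suppressed`.
#' @export
km_with_band <- function(records, target = c("waitlist_death", "time_to_transplant"),
                         competing = FALSE, min_events = 15, conf_level = 0.95,
                         horizon = 25, step = 1 / 12) {
  target <- match.arg(target)
  grid <- time_grid(horizon, step)
  if (competing && target == "time_to_transplant") {
    state <- factor(ifelse(records$outcome_type == "censored", "censor",
                           records$outcome_type),
                    levels = c("censor", "death_or_delisting", "transplant"))
    fit <- survival::survfit(survival::Surv(records$outcome_time, state) ~ 1,
                             conf.int = conf_level)
    col <- which(colnames(fit$pstate) == "transplant")
    inc <- step_eval(c(0, fit$time), c(0, fit$pstate[, col]), grid)
    lo <- step_eval(c(0, fit$time), c(0, replace_na(fit$lower[, col], 0)), grid)
    hi <- step_eval(c(0, fit$time), c(0, replace_na(fit$upper[, col], 0)), grid)
    n_events <- sum(records$outcome_type == "transplant")
    curve <- incidence_curve(grid, cummax(inc), horizon)
    return(new_curve_with_band(curve, pmin(lo, inc), pmax(hi, inc), n_events,
                               n_events < min_events, conf_level))
  }
  dat <- surv_frame(records, target)
  n_events <- sum(dat$event)
  fit <- survival::survfit(survival::Surv(dat$time, dat$event) ~ 1,
                           conf.type = "log-log", conf.int = conf_level)
  S <- step_eval(c(0, fit$time), c(1, fit$surv), grid)
  lo <- step_eval(c(0, fit$time), c(1, replace_na(fit$lower, 1)), grid)
  hi <- step_eval(c(0, fit$time), c(1, replace_na(fit$upper, 1)), grid)
  if (target == "time_to_transplant") {
    curve <- incidence_curve(grid, 1 - S, horizon)
    new_curve_with_band(curve, pmin(1 - hi, 1 - S), pmax(1 - lo, 1 - S),
                        n_events, n_events < min_events, conf_level)
  } else {
    curve <- survival_curve(grid, S, horizon)
    new_curve_with_band(curve, pmin(lo, S), pmax(hi, S), n_events,
                        n_events < min_events, conf_level)
  }
}

replace_na <- function(x, value) {
  x[is.na(x)] <- value
  x
}

new_curve_with_band <- function(curve, lower, upper, n_events, suppressed,
                                conf_level) {
  vals <- curve$probabilities %||% curve$cumulative_probability
  stopifnot(all(lower <= vals + 1e-8), all(upper >= vals - 1e-8))
  structure(list(curve = curve, lower = pmin(pmax(lower, 0), 1),
                 upper = pmin(pmax(upper, 0), 1), n_events = n_events,
                 suppressed = suppressed, conf_level = conf_level),
            class = "curve_with_band")
}
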