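# Counterfactual allocation-incentive scenarios. Life expectancy after
# rejoining the waitlist when the xenograft fails is computed by a
# discrete-time semi-Markov recursion over the monthly grid: the patient
# waits (facing death/delisting and transplant hazards derived from the
# fitted per-patient curves), and on transplantation collects the
# post-transplant life expectancy for their covariates and age at transplant,
# truncated at the horizon. Scenarios modify the transplant process only:
#
#   base                  waiting-time credit resets to 0 at relisting
#   inactive_accrual      credit w0 + n carried back onto the waitlist
#   living_donor_priority transplant hazard multiplied (default 5x)
#   highest_priority      immediate transplant; the q-th percentile (default
#                         75) of post-transplant LE over the ABO-compatible
#                         donor pool
#
# The relisting death curve uses waiting-time 0 in every scenario, so
# scenarios differ only in transplant access.

scenario_names <- c("base", "inactive_accrual", "living_donor_priority",
                    "highest_priority")

#' Incentive scenario parameters
#'
#' @param scenario scenario identifier.
#' @param q percentile of post-transplant life expectancy used by the
#'   highest-priority scenario (nearest-rank convention).
#' @param priority_multiplier transplant-hazard multiplier for the
#'   living-donor-priority scenario; must be >= 1, and 1 reduces the scenario
#'   to base exactly.
#' @param time_step,horizon recursion grid in years.
#' @return an object of class `scenario_params`.
#' @export
scenario_params <- function(scenario = scenario_names, q = 75,
                            priority_multiplier = 5, time_step = 1 / 12,
                            horizon = 25) {
  scenario <- match.arg(scenario)
  stopifnot(priority_multiplier >= 1, q > 0, q <= 100)
  structure(list(scenario = scenario, q = q,
                 priority_multiplier = priority_multiplier,
                 time_step = time_step, horizon = horizon),
            class = "scenario_params")
}

#' Discrete-time semi-Markov life expectancy
#'
#' Core recursion shared by all waiting scenarios. Works on per-patient curve
#' matrices over a common grid: discrete death and transplant hazards are
#' read off the curves interval by interval, the probability of being alive
#' and still waiting is propagated, and expected life years accumulate from
#' (i) person-time spent waiting (trapezoidal) and (ii) transplant mass in
#' each interval times the post-transplant life expectancy at the interval
#' midpoint. With exponential inputs on a monthly grid the result agrees with
#' the two-state closed form to well under 1%.
#'
#' @param S_wait matrix (patients x grid) of waitlist survival (death or
#'   delisting) probabilities.
#' @param F_tx matrix (patients x grid) of cumulative transplant incidence.
#' @param post_le_mid matrix (patients x (grid length - 1)) of post-transplant
#'   life expectancy for a transplant in each interval (evaluated at interval
#'   midpoints, truncated at the horizon).
#' @param step grid step in years.
#' @param tx_multiplier per-interval transplant hazard multiplier `m`,
#'   applied as `1 - (1 - h)^m` so that `m = 1` is exactly the identity.
#' @return numeric vector of expected life years, one per patient.
#' @export
semi_markov_le <- function(S_wait, F_tx, post_le_mid, step, tx_multiplier = 1) {
  G <- ncol(S_wait)
  stopifnot(ncol(F_tx) == G, ncol(post_le_mid) == G - 1,
            nrow(F_tx) == nrow(S_wait), nrow(post_le_mid) == nrow(S_wait))
  Sl <- S_wait[, -G, drop = FALSE]
  hd <- 1 - S_wait[, -1, drop = FALSE] / ifelse(Sl > 0, Sl, 1)
  hd[Sl <= 0] <- 1
  Fl <- F_tx[, -G, drop = FALSE]
  htx <- (F_tx[, -1, drop = FALSE] - Fl) / ifelse(Fl < 1, 1 - Fl, 1)
  htx[Fl >= 1] <- 0
  htx <- pmin(pmax(htx, 0), 1)
  hd <- pmin(pmax(hd, 0), 1)
  if (tx_multiplier != 1) htx <- 1 - (1 - htx)^tx_multiplier
  n <- nrow(S_wait)
  W <- matrix(0, n, G)
  W[, 1] <- 1
  for (j in seq_len(G - 1)) {
    W[, j + 1] <- W[, j] * (1 - hd[, j]) * (1 - htx[, j])
  }
  le_wait <- rowSums((W[, -G, drop = FALSE] + W[, -1, drop = FALSE]) / 2) * step
  mass <- W[, -G, drop = FALSE] * htx * (1 - hd / 2)
  le_tx <- rowSums(mass * post_le_mid)
  le_wait + le_tx
}

# Post-transplant life expectancy at each recursion interval midpoint:
# evaluated exactly on a coarse transplant-time grid (every tau_step years,
# with age at transplant advanced and the integral truncated at horizon - tau)
# and linearly interpolated to the midpoints. Covariates other than age are
# frozen at their snapshot values; the xenograft years are not added to age so
# the base-scenario result does not depend on n.
post_le_midpoints <- function(post_model, patients, grid, donor_quality,
                              tau_step = 0.5) {
  horizon <- max(grid)
  step <- grid[2] - grid[1]
  stopifnot(abs(round(tau_step / step) * step - tau_step) < 1e-9)
  taus <- seq(0, horizon, by = tau_step)
  n <- nrow(patients)
  LE <- matrix(0, n, length(taus))
  nd <- as.data.frame(patients)
  nd$donor_quality <- donor_quality
  for (k in seq_along(taus)) {
    tau <- taus[k]
    nd$age_at_tx <- patients$age_at_listing + patients$waiting_time_elapsed + tau
    S <- predict_curve_matrix(post_model, nd)
    keep <- grid <= horizon - tau + 1e-9
    if (sum(keep) >= 2) {
      LE[, k] <- trapz_rows(grid[keep], S[, keep, drop = FALSE])
    }
  }
  mids <- (grid[-length(grid)] + grid[-1]) / 2
  k <- findInterval(mids, taus)
  k <- pmin(k, length(taus) - 1L)
  w <- (mids - taus[k]) / tau_step
  LE[, k, drop = FALSE] * rep(1 - w, each = n) +
    LE[, k + 1L, drop = FALSE] * rep(w, each = n)
}

#' Life expectancy after relisting under an incentive scenario
#'
#' Runs the semi-Markov recursion for each patient under the given scenario.
#' For `highest_priority` the waiting phase is skipped entirely and the
#' result is [highest_priority_le()].
#'
#' @param patients patient records.
#' @param models named list with fitted `waitlist_death`,
#'   `time_to_transplant` and `post_transplant_death` models sharing a grid.
#' @param scenario a [scenario_params()] object.
#' @param n assumed xenograft survival in years; enters only through the
#'   waiting-time credit of the `inactive_accrual` scenario.
#' @param donors donor pool; required for `highest_priority` and for the
#'   default reference donor quality.
#' @param ref_donor_quality donor quality assumed for transplants inside the
#'   recursion; defaults to the mean quality of the donor pool.
#' @return numeric vector of expected life years after relisting.
#' @export
le_after_relisting <- function(patients, models, scenario = scenario_params("base"),
                               n = 0, donors = NULL, ref_donor_quality = NULL) {
  stopifnot(inherits(scenario, "scenario_params"))
  check_model_grids(models, scenario)
  if (scenario$scenario == "highest_priority") {
    if (is.null(donors)) stop("highest_priority requires a donor pool", call. = FALSE)
    return(highest_priority_le(patients, donors, models$post_transplant_death,
                               q = scenario$q))
  }
  ref_donor_quality <- ref_donor_quality %||%
    (if (!is.null(donors)) mean(donors$quality) else 0.6)
  grid <- models$waitlist_death$grid
  relisted <- as.data.frame(patients)
  relisted$waiting_time_elapsed <- 0
  S_d <- predict_curve_matrix(models$waitlist_death, relisted)
  tx_credit <- switch(scenario$scenario,
    base = 0,
    inactive_accrual = patients$waiting_time_elapsed + n,
    living_donor_priority = 0
  )
  tx_frame <- relisted
  tx_frame$waiting_time_elapsed <- tx_credit
  F_tx <- 1 - predict_curve_matrix(models$time_to_transplant, tx_frame)
  mult <- if (scenario$scenario == "living_donor_priority") {
    scenario$priority_multiplier
  } else 1
  post_mid <- post_le_midpoints(models$post_transplant_death, patients, grid,
                                ref_donor_quality)
  semi_markov_le(S_d, F_tx, post_mid, step = grid[2] - grid[1],
                 tx_multiplier = mult)
}

check_model_grids <- function(models, scenario) {
  need <- c("waitlist_death", "time_to_transplant", "post_transplant_death")
  miss <- setdiff(need, names(models))
  if (length(miss) > 0) stop("models list missing: ", paste(miss, collapse = ", "),
                             call. = FALSE)
  g <- models$waitlist_death$grid
  for (nm in need) {
    if (length(models[[nm]]$grid) != length(g) ||
        any(abs(models[[nm]]$grid - g) > 1e-9)) {
      stop("grid/horizon mismatch across models", call. = FALSE)
    }
  }
  if (abs((g[2] - g[1]) - scenario$time_step) > 1e-9 ||
      abs(max(g) - scenario$horizon) > 1e-9) {
    stop("grid/horizon mismatch between models and scenario", call. = FALSE)
  }
  invisible(TRUE)
}

#' Highest-priority life expectancy (q-th percentile over compatible donors)
#'
#' Models the extreme incentive in which a failed-xenograft patient goes to
#' the top of the list: the ABO-compatible donor pool is identified, the
#' post-transplant life expectancy is computed for a match with each donor
#' (immediate transplant), and the q-th percentile (nearest rank) of that
#' distribution is returned.
#'
#' @param patients patient records.
#' @param donors donor pool with `blood_type` and `quality`.
#' @param post_model fitted post-transplant survival model.
#' @param q percentile in (0, 100]; nearest-rank.
#' @return numeric vector of expected life years, one per patient.
#' @export
highest_priority_le <- function(patients, donors, post_model, q = 75) {
  stopifnot(q > 0, q <= 100)
  n <- nrow(patients)
  grid <- post_model$grid
  comp <- outer(patients$blood_type, donors$blood_type,
                function(r, d) abo_compatible(d, r))
  if (any(rowSums(comp) == 0)) {
    stop("empty blood-compatible donor pool for patient ",
         patients$patient_id[which(rowSums(comp) == 0)[1]], call. = FALSE)
  }
  nd <- as.data.frame(patients)
  nd$age_at_tx <- patients$age_at_listing + patients$waiting_time_elapsed
  if (post_model$backend == "cox" &&
      "donor_quality" %in% post_model$covariates) {
    # LE depends on donors only through the donor-quality term of the linear
    # predictor, so evaluate LE(lp) once on a fine grid and look it up
    nd$donor_quality <- 0
    lp0 <- unname(stats::predict(post_model$fit,
                                 newdata = prep_covariates(nd, post_model$covariates),
                                 type = "lp"))
    bq <- stats::coef(post_model$fit)[["donor_quality"]]
    lp_pd <- outer(lp0, bq * donors$quality, "+")
    lp_grid <- seq(min(lp_pd) - 1e-6, max(lp_pd) + 1e-6, length.out = 512)
    le_grid <- trapz_rows(grid, exp(-exp(lp_grid) %o% post_model$H0grid))
    LE <- matrix(stats::approx(lp_grid, le_grid, xout = lp_pd)$y, n)
  } else {
    LE <- matrix(0, n, nrow(donors))
    for (d in seq_len(nrow(donors))) {
      nd$donor_quality <- donors$quality[d]
      S <- predict_curve_matrix(post_model, nd)
      LE[, d] <- trapz_rows(grid, S)
    }
  }
  vapply(seq_len(n), function(i) {
    vals <- sort(LE[i, comp[i, ]])
    vals[max(1L, ceiling(q / 100 * length(vals)))]
  }, numeric(1))
}

#' Fraction of patients incentivized per cohort, scenario and n
#'
#' For each cohort, scenario and value of the assumed xenograft survival n,
#' the fraction of cohort members reaching equipoise, i.e. with
#' `n + p_relist * le_after_relisting(scenario, n) > le_status_quo`. The base
#' scenario is always included so deltas are well defined. Cohorts smaller
#' than `min_cohort` members are flagged suppressed.
#'
#' @param patients active patient records.
#' @param membership cohort membership matrix aligned with `patients`.
#' @param models fitted model list (see [le_after_relisting()]).
#' @param assumptions an [xeno_assumptions()] object.
#' @param donors donor pool.
#' @param relist_probability per-patient relisting probabilities.
#' @param scenarios scenario names to evaluate (base is added if absent).
#' @param cohort_ids cohorts to report (default the four main cohorts).
#' @param priority_multiplier,min_cohort see [scenario_params()] and the
#'   suppression rule.
#' @return data frame: `cohort_id`, `scenario`, `n`, `n_patients`,
#'   `fraction_incentivized`, `delta_vs_base` (percentage points),
#'   `suppressed`.
#' @export
incentivized_fractions <- function(patients, membership, models, assumptions,
                                   donors, relist_probability,
                                   scenarios = scenario_names,
                                   cohort_ids = 1:4, priority_multiplier = 5,
                                   min_cohort = 15) {
  scenarios <- union("base", match.arg(scenarios, scenario_names,
                                       several.ok = TRUE))
  grid <- models$waitlist_death$grid
  step <- grid[2] - grid[1]
  horizon <- max(grid)
  np <- nrow(patients)
  relist_probability <- rep_len(relist_probability, np)
  le_sq <- trapz_rows(grid, predict_curve_matrix(models$waitlist_death, patients))
  n_grid <- assumptions$n_grid
  # le_after_relisting per scenario: a matrix patients x n_grid (only the
  # inactive-accrual scenario actually varies with n)
  le_rel <- list()
  for (sc in scenarios) {
    sp <- scenario_params(sc, q = assumptions$q,
                          priority_multiplier = priority_multiplier,
                          time_step = step, horizon = horizon)
    if (sc == "inactive_accrual") {
      le_rel[[sc]] <- vapply(n_grid, function(n) {
        le_after_relisting(patients, models, sp, n = n, donors = donors)
      }, numeric(np))
    } else {
      v <- le_after_relisting(patients, models, sp, donors = donors)
      le_rel[[sc]] <- matrix(v, np, length(n_grid))
    }
  }
  rows <- list()
  for (cid in cohort_ids) {
    keep <- membership[, as.character(cid)]
    size <- sum(keep)
    for (sc in scenarios) {
      for (j in seq_along(n_grid)) {
        n <- n_grid[j]
        lx <- le_with_xeno(n, relist_probability[keep], le_rel[[sc]][keep, j])
        frac <- if (size > 0) mean(lx > le_sq[keep]) else NA_real_
        rows[[length(rows) + 1L]] <- data.frame(
          cohort_id = cid, scenario = sc, n = n, n_patients = size,
          fraction_incentivized = frac, suppressed = size < min_cohort)
      }
    }
  }
  out <- do.call(rbind, rows)
  base <- out[out$scenario == "base", c("cohort_id", "n", "fraction_incentivized")]
  names(base)[3] <- "base_fraction"
  out <- merge(out, base, by = c("cohort_id", "n"), sort = FALSE)
  out$delta_vs_base <- 100 * (out$fraction_incentivized - out$base_fraction)
  out$base_fraction <- NULL
  out[order(out$cohort_id, match(out$scenario, scenario_names), out$n), ]
}
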