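# Synthetic waitlist registry generator. Produces seeded patient, donor,
# center and offer tables with known ground-truth parameters so that every
# downstream stage (model fitting, equipoise, cohorts, incentives, evaluation)
# can be tested without restricted registry data.
#
# Time convention: the clock starts at the prediction snapshot. Each patient
# has already waited `waiting_time_elapsed` years (a covariate); `outcome_time`
# is years from the snapshot to the earliest of death/delisting, transplant,
# censoring, or the administrative horizon. Death and transplant are competing
# risks generated as independent latent proportional-hazards (Weibull) times.

#' Ground-truth configuration for the synthetic registry
#'
#' All hazards are Weibull proportional-hazards models with cumulative hazard
#' `H(t) = base_rate * t^shape * exp(lp)`, where the linear predictor `lp` is
#' built from the named log-hazard-ratio vector in `coefs` (continuous
#' covariates are centred internally; see `centering_constants()`). The default
#' shape of 1 gives exponential (memoryless) baselines.
#'
#' @param n_patients,n_centers,n_donors table sizes; all must be positive.
#' @param seed integer seed; the generator splits it into independent
#'   per-table streams, so the same seed reproduces the bundle bit-for-bit.
#' @param death_hazard,transplant_hazard,post_tx_hazard lists with elements
#'   `base_rate` (per-year baseline hazard), `shape` (Weibull shape) and
#'   `coefs` (named log-hazard-ratio vector). Blood-group effects are encoded
#'   as indicator coefficients `blood_B`, `blood_O`, `blood_AB` (A reference);
#'   the post-transplant model may use `age_at_tx` and `donor_quality`.
#' @param graft_failure_rate per-year hazard of xeno/allograft failure after a
#'   transplant (exponential).
#' @param relist_logit_coefs named log-odds vector (with `intercept`) for the
#'   probability of relisting after graft failure.
#' @param censor_rate per-year administrative censoring hazard.
#' @param horizon_years administrative horizon in years from the snapshot.
#' @param time_step curve grid step in years; must divide the horizon evenly.
#' @param offer_params list: `marginal_offer_rate` (marginal organ offers per
#'   patient-year), `marginal_quality_threshold` (donor quality below which an
#'   organ counts as marginal), `acceptance_shape` and `screen_shape` (Beta
#'   parameters for per-center acceptance and opt-in screen propensities).
#' @param covariates list of covariate-distribution knobs (see defaults).
#' @return an object of class `generator_config`.
#' @export
generator_config <- function(
    n_patients = 10000,
    n_centers = 30,
    n_donors = 1500,
    seed = 1,
    death_hazard = list(
      base_rate = 0.10, shape = 1,
      coefs = c(age_at_listing = 0.035, diabetes = 0.55, cpra = 0.002,
                albumin = -0.40, sdi = 0.004, waiting_time_elapsed = 0.06)
    ),
    transplant_hazard = list(
      base_rate = 0.15, shape = 1,
      coefs = c(age_at_listing = -0.012, diabetes = -0.25,
                previous_transplant = -0.20, cpra = -0.022,
                blood_B = -0.45, blood_O = -0.35, blood_AB = 0.10,
                waiting_time_elapsed = 0.10)
    ),
    post_tx_hazard = list(
      base_rate = 0.03, shape = 1,
      coefs = c(age_at_tx = 0.045, diabetes = 0.30,
                previous_transplant = 0.20, donor_quality = -1.2)
    ),
    graft_failure_rate = 0.06,
    relist_logit_coefs = c(intercept = 0.5, age_at_listing = -0.04,
                           diabetes = -0.40, cpra = -0.01),
    censor_rate = 0.015,
    horizon_years = 25,
    time_step = 1 / 12,
    offer_params = list(marginal_offer_rate = 0.8,
                        marginal_quality_threshold = 0.35,
                        acceptance_shape = c(2, 4),
                        screen_shape = c(5, 2)),
    covariates = list(
      age_band_probs = c(0.30, 0.45, 0.25),  # 18-49 / 50-64 / 65+
      diabetes_prob = 0.45,
      blood_type_probs = c(A = 0.34, B = 0.14, AB = 0.04, O = 0.48),
      previous_transplant_prob = 0.12,
      cpra_zero_prob = 0.60,
      cpra_high_prob = 0.05,      # mass at >= 99.5 so the very-high-CPRA cohort is populated
      comorbidity_probs = c(chf = 0.12, ashd = 0.10, tobacco = 0.08, cancer = 0.05),
      waiting_time_mean = 2,
      waiting_time_cap = 10,
      active_prob = 0.90
    )) {
  cfg <- structure(
    list(n_patients = n_patients, n_centers = n_centers, n_donors = n_donors,
         seed = seed, death_hazard = death_hazard,
         transplant_hazard = transplant_hazard, post_tx_hazard = post_tx_hazard,
         graft_failure_rate = graft_failure_rate,
         relist_logit_coefs = relist_logit_coefs, censor_rate = censor_rate,
         horizon_years = horizon_years, time_step = time_step,
         offer_params = offer_params, covariates = covariates),
    class = "generator_config"
  )
  validate_generator_config(cfg)
  cfg
}

validate_generator_config <- function(cfg) {
  counts <- c(cfg$n_patients, cfg$n_centers, cfg$n_donors)
  if (any(counts <= 0) || any(counts != round(counts))) {
    stop("configuration error: all counts must be positive integers", call. = FALSE)
  }
  for (nm in c("death_hazard", "transplant_hazard", "post_tx_hazard")) {
    h <- cfg[[nm]]
    if (h$base_rate < 0 || h$shape <= 0) {
      stop("configuration error: ", nm, " must have base_rate >= 0 and shape > 0",
           call. = FALSE)
    }
  }
  if (cfg$censor_rate < 0 || cfg$graft_failure_rate < 0) {
    stop("configuration error: rates must be non-negative", call. = FALSE)
  }
  time_grid(cfg$horizon_years, cfg$time_step)  # errors if step does not divide
  invisible(cfg)
}

# Centering constants for continuous covariates: the ground-truth linear
# predictor is coef * (x - center), so fitted Cox coefficients are directly
# comparable to the config coefficients (centering only rescales the baseline).
centering_constants <- function() {
  c(age_at_listing = 50, age_at_tx = 50, albumin = 4, sdi = 50, bmi = 28,
    cpra = 0, waiting_time_elapsed = 0, donor_quality = 0)
}

#' Ground-truth linear predictor
#'
#' Applies a named log-hazard-ratio (or log-odds) vector to a patient table.
#' Blood type enters through `blood_B` / `blood_O` / `blood_AB` indicators
#' (type A as reference); `intercept` is added as-is.
#'
#' @param df data frame with the referenced covariate columns.
#' @param coefs named numeric vector.
#' @return numeric linear predictor, one value per row.
#' @export
linear_predictor <- function(df, coefs) {
  centers <- centering_constants()
  lp <- rep(0, nrow(df))
  for (nm in names(coefs)) {
    b <- coefs[[nm]]
    if (nm == "intercept") {
      lp <- lp + b
    } else if (grepl("^blood_", nm)) {
      lp <- lp + b * as.numeric(df$blood_type == sub("^blood_", "", nm))
    } else {
      if (is.null(df[[nm]])) stop("linear_predictor: missing covariate '", nm, "'",
                                  call. = FALSE)
      ctr <- if (nm %in% names(centers)) centers[[nm]] else 0
      lp <- lp + b * (df[[nm]] - ctr)
    }
  }
  lp
}

# Weibull PH latent event time: H(t) = base * t^shape * exp(lp), inverted at a
# unit exponential draw. shape 1 reduces to an exponential with rate base*e^lp.
draw_ph_time <- function(lp, base_rate, shape) {
  n <- length(lp)
  if (base_rate <= 0) return(rep(Inf, n))
  e <- stats::rexp(n)
  (e / (base_rate * exp(lp)))^(1 / shape)
}

sample_patients <- function(cfg) {
  n <- cfg$n_patients
  cv <- cfg$covariates
  set.seed(subseed(cfg$seed, "patients"))
  band <- sample.int(3L, n, replace = TRUE, prob = cv$age_band_probs)
  age <- numeric(n)
  age[band == 1L] <- stats::runif(sum(band == 1L), 18, 50)
  age[band == 2L] <- stats::runif(sum(band == 2L), 50, 64)
  age[band == 3L] <- stats::runif(sum(band == 3L), 65, 82)
  cpra_class <- sample.int(3L, n, replace = TRUE,
                           prob = c(cv$cpra_zero_prob,
                                    1 - cv$cpra_zero_prob - cv$cpra_high_prob,
                                    cv$cpra_high_prob))
  cpra <- numeric(n)
  cpra[cpra_class == 2L] <- stats::rbeta(sum(cpra_class == 2L), 1.2, 2.5) * 99.4
  cpra[cpra_class == 3L] <- stats::runif(sum(cpra_class == 3L), 99.5, 100)
  com <- vapply(cv$comorbidity_probs,
                function(p) stats::rbinom(n, 1L, p), integer(n))
  df <- data.frame(
    patient_id = seq_len(n),
    center_id = sample.int(cfg$n_centers, n, replace = TRUE),
    age_at_listing = round(age, 6),
    diabetes = stats::rbinom(n, 1L, cv$diabetes_prob),
    blood_type = sample(names(cv$blood_type_probs), n, replace = TRUE,
                        prob = cv$blood_type_probs),
    previous_transplant = stats::rbinom(n, 1L, cv$previous_transplant_prob),
    cpra = round(cpra, 6),
    bmi = round(pmin(pmax(stats::rnorm(n, 28, 5), 15), 50), 6),
    albumin = round(pmin(pmax(stats::rnorm(n, 3.9, 0.6), 1.5), 5.5), 6),
    sdi = round(stats::rbeta(n, 2, 2) * 100, 6),
    waiting_time_elapsed = round(
      pmin(stats::rexp(n, 1 / cv$waiting_time_mean), cv$waiting_time_cap), 6),
    active = stats::rbinom(n, 1L, cv$active_prob),
    stringsAsFactors = FALSE
  )
  cbind(df, as.data.frame(com))
}

sample_donors <- function(cfg) {
  set.seed(subseed(cfg$seed, "donors"))
  data.frame(
    donor_id = seq_len(cfg$n_donors),
    blood_type = sample(names(cfg$covariates$blood_type_probs), cfg$n_donors,
                        replace = TRUE, prob = cfg$covariates$blood_type_probs),
    quality = round(stats::rbeta(cfg$n_donors, 3, 2), 6),
    stringsAsFactors = FALSE
  )
}

sample_centers <- function(cfg) {
  set.seed(subseed(cfg$seed, "centers"))
  op <- cfg$offer_params
  data.frame(
    center_id = seq_len(cfg$n_centers),
    acceptance_propensity = round(
      stats::rbeta(cfg$n_centers, op$acceptance_shape[1], op$acceptance_shape[2]), 6),
    screen_propensity = round(
      stats::rbeta(cfg$n_centers, op$screen_shape[1], op$screen_shape[2]), 6)
  )
}

#' Generate a synthetic waitlist registry bundle
#'
#' Draws patients, donors, center propensities and a marginal-organ offer log
#' from the ground-truth configuration. Latent death/delisting and transplant
#' times come from independent proportional-hazards models; the observed
#' outcome is the earliest of death, transplant, censoring and the horizon.
#' Transplanted patients get a blood-compatible donor, a post-transplant
#' survival time (depending on donor quality and age at transplant), a graft
#' failure indicator, and — among graft failures — a relisting indicator from
#' the logistic ground truth. Identical seeds give identical bundles.
#'
#' @param config a [generator_config()].
#' @return a list of class `registry_bundle` with elements `patients`,
#'   `donors`, `centers`, `offers` and `ground_truth`.
#' @export
generate_registry <- function(config) {
  validate_generator_config(config)
  patients <- sample_patients(config)
  donors <- sample_donors(config)
  centers <- sample_centers(config)

  # competing latent event times, measured from the snapshot
  set.seed(subseed(config$seed, "misc"))
  t_death <- draw_ph_time(linear_predictor(patients, config$death_hazard$coefs),
                          config$death_hazard$base_rate, config$death_hazard$shape)
  t_tx <- draw_ph_time(linear_predictor(patients, config$transplant_hazard$coefs),
                       config$transplant_hazard$base_rate,
                       config$transplant_hazard$shape)
  t_cens <- rexp_safe(nrow(patients), config$censor_rate)
  h <- config$horizon_years
  t_obs <- pmin(t_death, t_tx, t_cens, h)
  type <- rep("censored", nrow(patients))
  type[t_obs == t_tx] <- "transplant"
  type[t_obs == t_death] <- "death_or_delisting"  # death wins exact ties (prob. 0)
  patients$outcome_type <- type
  patients$outcome_time <- round(pmax(t_obs, 1e-6), 6)

  # post-transplant trajectory for transplanted patients
  set.seed(subseed(config$seed, "posttx"))
  patients$donor_id <- NA_integer_
  patients$donor_quality <- NA_real_
  patients$post_tx_time <- NA_real_
  patients$post_tx_event <- NA_integer_
  patients$graft_failed <- NA_integer_
  patients$relisted <- NA_integer_
  txd <- which(patients$outcome_type == "transplant")
  if (length(txd) > 0) {
    patients$donor_id[txd] <- assign_compatible_donors(
      patients$blood_type[txd], donors)
    patients$donor_quality[txd] <- donors$quality[patients$donor_id[txd]]
    ptab <- patients[txd, ]
    ptab$age_at_tx <- ptab$age_at_listing + ptab$waiting_time_elapsed +
      ptab$outcome_time
    t_pd <- draw_ph_time(linear_predictor(ptab, config$post_tx_hazard$coefs),
                         config$post_tx_hazard$base_rate,
                         config$post_tx_hazard$shape)
    t_pc <- pmin(rexp_safe(length(txd), config$censor_rate), h)
    patients$post_tx_time[txd] <- round(pmax(pmin(t_pd, t_pc), 1e-6), 6)
    patients$post_tx_event[txd] <- as.integer(t_pd <= t_pc)
    t_fail <- rexp_safe(length(txd), config$graft_failure_rate)
    patients$graft_failed[txd] <- as.integer(t_fail < pmin(t_pd, t_pc))
  }
  set.seed(subseed(config$seed, "relist"))
  failed <- which(patients$graft_failed %in% 1L)
  if (length(failed) > 0) {
    p_rel <- stats::plogis(
      linear_predictor(patients[failed, ], config$relist_logit_coefs))
    patients$relisted[failed] <- stats::rbinom(length(failed), 1L, p_rel)
  }

  offers <- generate_offers(config, patients, donors, centers)
  structure(list(patients = patients, donors = donors, centers = centers,
                 offers = offers, ground_truth = config),
            class = "registry_bundle")
}

# sample a blood-compatible donor id for each recipient blood type (ABO rules:
# O donors to anyone; A->A/AB; B->B/AB; AB->AB)
assign_compatible_donors <- function(recipient_bt, donors) {
  out <- integer(length(recipient_bt))
  for (bt in unique(recipient_bt)) {
    ok <- donors$donor_id[abo_compatible(donors$blood_type, bt)]
    if (length(ok) == 0) stop("no blood-compatible donor in the pool for type ", bt,
                              call. = FALSE)
    idx <- recipient_bt == bt
    out[idx] <- ok[sample.int(length(ok), sum(idx), replace = TRUE)]
  }
  out
}

#' ABO compatibility
#'
#' @param donor_bt,recipient_bt character vectors of blood types.
#' @return logical: can the recipient receive from the donor?
#' @export
abo_compatible <- function(donor_bt, recipient_bt) {
  donor_bt == "O" | donor_bt == recipient_bt |
    (donor_bt %in% c("A", "B") & recipient_bt == "AB")
}

# Offer log: marginal organs (donor quality below the threshold) arrive to each
# patient at `marginal_offer_rate` per patient-year while the patient is on the
# list; non-marginal offers arrive at the same rate and are flagged marginal =
# 0 so that acceptance-rate denominators can be restricted correctly. An offer
# is `seen` with the center's opt-in screen propensity and can only be accepted
# if seen (accepted => seen holds by construction).
generate_offers <- function(cfg, patients, donors, centers) {
  set.seed(subseed(cfg$seed, "offers"))
  op <- cfg$offer_params
  marg_pool <- donors$donor_id[donors$quality < op$marginal_quality_threshold]
  nonmarg_pool <- setdiff(donors$donor_id, marg_pool)
  exposure <- pmin(patients$outcome_time, cfg$horizon_years)
  n_marg <- stats::rpois(nrow(patients), op$marginal_offer_rate * exposure)
  n_non <- stats::rpois(nrow(patients), op$marginal_offer_rate * exposure)
  if (length(marg_pool) == 0) n_marg[] <- 0L
  if (length(nonmarg_pool) == 0) n_non[] <- 0L
  pat_idx <- c(rep(seq_len(nrow(patients)), n_marg),
               rep(seq_len(nrow(patients)), n_non))
  marginal <- c(rep(1L, sum(n_marg)), rep(0L, sum(n_non)))
  if (length(pat_idx) == 0) {
    return(data.frame(offer_id = integer(), center_id = integer(),
                      patient_id = integer(), donor_id = integer(),
                      marginal = integer(), seen = integer(),
                      accepted = integer()))
  }
  donor_id <- integer(length(pat_idx))
  if (sum(n_marg) > 0) {
    donor_id[marginal == 1L] <-
      marg_pool[sample.int(length(marg_pool), sum(n_marg), replace = TRUE)]
  }
  if (sum(n_non) > 0) {
    donor_id[marginal == 0L] <-
      nonmarg_pool[sample.int(length(nonmarg_pool), sum(n_non), replace = TRUE)]
  }
  center_id <- patients$center_id[pat_idx]
  seen <- stats::rbinom(length(pat_idx), 1L,
                        centers$screen_propensity[center_id])
  acc_p <- centers$acceptance_propensity[center_id] *
    ifelse(marginal == 1L, 1, 0.5)
  accepted <- seen * stats::rbinom(length(pat_idx), 1L, acc_p)
  ord <- order(pat_idx, marginal, donor_id)
  data.frame(
    offer_id = seq_along(pat_idx),
    center_id = center_id[ord],
    patient_id = patients$patient_id[pat_idx][ord],
    donor_id = donor_id[ord],
    marginal = marginal[ord],
    seen = seen[ord],
    accepted = accepted[ord]
  )
}
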