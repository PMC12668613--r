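# Shared fixtures (memoised so expensive bundles/models are built once per
# test run) and independent oracles used across test files.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# default-parameter bundle of moderate size, plus fitted cox models
shared_bundle <- function() {
  memo("bundle2500", generate_registry(generator_config(n_patients = 2500,
                                                        n_donors = 500,
                                                        seed = 42)))
}

shared_active <- function() {
  b <- shared_bundle()
  b$patients[b$patients$active == 1L, , drop = FALSE]
}

shared_models <- function() {
  memo("models2500", {
    act <- shared_active()
    list(
      waitlist_death = fit_model(act, "waitlist_death", "cox"),
      time_to_transplant = fit_model(act, "time_to_transplant", "cox"),
      post_transplant_death = fit_model(act, "post_transplant_death", "cox")
    )
  })
}

# a single synthetic patient with overridable covariates
make_patient <- function(...) {
  base <- data.frame(
    patient_id = 1L, center_id = 1L, age_at_listing = 55, diabetes = 1L,
    blood_type = "O", previous_transplant = 0L, cpra = 0, bmi = 28,
    albumin = 4, sdi = 50, waiting_time_elapsed = 0, active = 1L,
    chf = 0L, ashd = 0L, tobacco = 0L, cancer = 0L,
    stringsAsFactors = FALSE)
  over <- list(...)
  for (nm in names(over)) base[[nm]] <- over[[nm]]
  base
}

# brute-force product-limit estimator (independent of survival::survfit)
km_product_limit <- function(time, event, eval_times) {
  ut <- sort(unique(time[event == 1]))
  S <- 1
  surv_at <- function(t) {
    s <- 1
    for (u in ut[ut <= t]) {
      d <- sum(time == u & event == 1)
      n_risk <- sum(time >= u)
      s <- s * (1 - d / n_risk)
    }
    s
  }
  vapply(eval_times, surv_at, numeric(1))
}

# closed-form horizon-truncated life expectancy of the two-state
# wait -> transplant -> post model with constant hazards
closed_le_twostate <- function(mu_w, lambda_tx, mu_p, horizon) {
  a <- mu_w + lambda_tx
  wait <- (1 - exp(-a * horizon)) / a
  post <- stats::integrate(function(s) {
    lambda_tx * exp(-a * s) * (1 - exp(-mu_p * (horizon - s))) / mu_p
  }, 0, horizon, rel.tol = 1e-10)$value
  wait + post
}

constant_models <- function(mu_w, lambda_tx, mu_p, horizon = 25, step = 1 / 12) {
  list(
    waitlist_death = constant_hazard_model(mu_w, "waitlist_death", horizon, step),
    time_to_transplant = constant_hazard_model(lambda_tx, "time_to_transplant",
                                               horizon, step),
    post_transplant_death = constant_hazard_model(mu_p, "post_transplant_death",
                                                  horizon, step)
  )
}
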