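# Incentive scenarios: the semi-Markov recursion against closed forms and
# limits, the highest-priority percentile construction, and the scenario
# ordering of incentivized fractions.

test_that("with zero transplant hazard the recursion is the waitlist integral", {
  H <- 25; st <- 1 / 12
  models <- constant_models(0.3, 0, 0.1, H, st)
  pat <- make_patient()
  le <- le_after_relisting(pat, models, scenario_params("base"))
  expect_equal(le, (1 - exp(-0.3 * H)) / 0.3, tolerance = 1e-3)
})

test_that("immediate certain transplant collapses to the post-transplant LE", {
  st <- 1 / 12; g <- time_grid(25, st)
  G <- length(g)
  S_wait <- matrix(1, 1, G)
  F_tx <- matrix(c(0, rep(1, G - 1)), 1, G)   # all mass in the first interval
  post <- matrix(12, 1, G - 1)
  le <- semi_markov_le(S_wait, F_tx, post, st)
  expect_equal(le, 12, tolerance = st)
})

test_that("recursion matches the two-state closed form for constant hazards", {
  models <- constant_models(0.5, 0.5, 0.1)
  le <- le_after_relisting(make_patient(), models, scenario_params("base"))
  expect_equal(le, closed_le_twostate(0.5, 0.5, 0.1, 25), tolerance = 0.02 * le)
})

test_that("priority multiplier one reduces the living-donor scenario to base exactly", {
  models <- shared_models()
  act <- shared_active()[1:40, ]
  b <- shared_bundle()
  base <- le_after_relisting(act, models, scenario_params("base"),
                             donors = b$donors)
  m1 <- le_after_relisting(act, models,
                           scenario_params("living_donor_priority",
                                           priority_multiplier = 1),
                           donors = b$donors)
  expect_identical(base, m1)
})

test_that("life after relisting is monotone in the priority multiplier", {
  models <- shared_models()
  act <- shared_active()[1:40, ]
  b <- shared_bundle()
  prev <- le_after_relisting(act, models, scenario_params("base"),
                             donors = b$donors)
  for (m in c(1.5, 2, 3, 5, 8)) {
    cur <- le_after_relisting(act, models,
                              scenario_params("living_donor_priority",
                                              priority_multiplier = m),
                              donors = b$donors)
    expect_true(all(cur >= prev - 1e-9))
    prev <- cur
  }
})

test_that("recursion output is bounded by its structural envelopes", {
  models <- shared_models()
  act <- shared_active()[1:40, ]
  b <- shared_bundle()
  le <- le_after_relisting(act, models, scenario_params("base"),
                           donors = b$donors)
  # below: waiting forever; above: best-donor immediate transplant + horizon
  S_d <- predict_curve_matrix(models$waitlist_death,
                              transform(act, waiting_time_elapsed = 0))
  le_wait_only <- trapz_rows(models$waitlist_death$grid, S_d)
  best <- highest_priority_le(act, b$donors, models$post_transplant_death,
                              q = 100)
  expect_true(all(le >= le_wait_only - 1e-6))
  expect_true(all(le <= pmax(best, le_wait_only) + 1e-6))
})

test_that("highest-priority LE: ABO filtering, nearest-rank percentile, q-monotone", {
  models <- shared_models()
  post <- models$post_transplant_death
  donors <- data.frame(donor_id = 1:40, blood_type = rep("O", 40),
                       quality = seq(0.02, 0.98, length.out = 40))
  pat <- make_patient()
  # brute-force oracle: LE per donor, sorted, nearest rank
  le_d <- vapply(seq_len(nrow(donors)), function(d) {
    nd <- pat
    nd$age_at_tx <- pat$age_at_listing + pat$waiting_time_elapsed
    nd$donor_quality <- donors$quality[d]
    life_expectancy(predict_curve(post, nd))
  }, numeric(1))
  got75 <- highest_priority_le(pat, donors, post, q = 75)
  expect_equal(got75, sort(le_d)[ceiling(0.75 * 40)], tolerance = 1e-6)
  # single compatible donor: that donor's LE for any q
  one <- donors[7, , drop = FALSE]
  for (q in c(10, 75, 100)) {
    expect_equal(highest_priority_le(pat, one, post, q = q), le_d[7],
                 tolerance = 1e-6)
  }
  # monotone in q
  qs <- c(10, 25, 50, 75, 90, 100)
  vals <- vapply(qs, function(q) highest_priority_le(pat, donors, post, q),
                 numeric(1))
  expect_true(all(diff(vals) >= -1e-9))
  # an O patient cannot receive from an A-only pool
  poolA <- data.frame(donor_id = 1, blood_type = "A", quality = 0.5)
  expect_error(highest_priority_le(make_patient(blood_type = "O"), poolA, post),
               "compatible")
  # an AB patient can
  expect_silent(highest_priority_le(make_patient(blood_type = "AB"), poolA, post))
})

test_that("incentivized fractions respect the scenario ordering with base deltas", {
  b <- shared_bundle()
  act <- shared_active()
  models <- shared_models()
  agg <- aggressiveness(b$patients, b$offers)
  M <- cohort_membership(act, agg)
  keep <- rowSums(M[, c("1", "2"), drop = FALSE]) > 0
  assum <- xeno_assumptions(n_grid = c(1, 2, 5))
  rep_df <- incentivized_fractions(act[keep, ], M[keep, , drop = FALSE],
                                   models, assum, donors = b$donors,
                                   relist_probability = 0.6,
                                   cohort_ids = c(1, 2))
  for (cid in c(1, 2)) for (n in assum$n_grid) {
    f <- function(sc) rep_df$fraction_incentivized[
      rep_df$cohort_id == cid & rep_df$scenario == sc & rep_df$n == n]
    expect_lte(f("base"), f("inactive_accrual") + 1e-12)
    expect_lte(f("inactive_accrual"), f("living_donor_priority") + 1e-12)
    expect_lte(f("living_donor_priority"), f("highest_priority") + 1e-12)
  }
  base_rows <- rep_df[rep_df$scenario == "base", ]
  expect_true(all(base_rows$delta_vs_base == 0))
  # deltas equal recomputed differences
  for (k in which(rep_df$scenario != "base")[1:5]) {
    r <- rep_df[k, ]
    b0 <- rep_df$fraction_incentivized[rep_df$cohort_id == r$cohort_id &
                                         rep_df$n == r$n &
                                         rep_df$scenario == "base"]
    expect_equal(r$delta_vs_base, 100 * (r$fraction_incentivized - b0),
                 tolerance = 1e-9)
  }
  expect_true(all(rep_df$fraction_incentivized >= 0 &
                    rep_df$fraction_incentivized <= 1))
})

test_that("small cohorts are flagged suppressed", {
  b <- shared_bundle()
  act <- shared_active()[1:40, ]
  agg <- aggressiveness(b$patients, b$offers)
  M <- cohort_membership(act, agg)[, c("1", "11"), drop = FALSE]
  rep_df <- incentivized_fractions(act, M, shared_models(),
                                   xeno_assumptions(n_grid = 2),
                                   donors = b$donors, relist_probability = 0.5,
                                   scenarios = "base", cohort_ids = c(1, 11))
  expect_true(all(rep_df$suppressed[rep_df$n_patients < 15]))
})

test_that("mismatched grids are rejected", {
  models <- constant_models(0.3, 0.2, 0.1, horizon = 25)
  models$post_transplant_death <- constant_hazard_model(0.1, horizon = 20)
  expect_error(le_after_relisting(make_patient(), models,
                                  scenario_params("base")),
               "mismatch")
})
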