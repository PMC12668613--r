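# Equipoise engine: the xenotransplant life-expectancy formula, relisting
# probability estimates, viability identification against a brute-force
# re-comparison, and the sensitivity table.

test_that("le_with_xeno follows n + p * le_relist with its boundary cases", {
  expect_equal(le_with_xeno(2, 0, 10), 2)
  expect_equal(le_with_xeno(2, 0.5, 4), 4)
  grid <- c(0.5, 1, 1.5, 2, 3, 4, 5)
  out <- le_with_xeno(grid, 0.4, 6)
  expect_true(all(diff(out) > 0))
  expect_true(all(out >= grid))
  expect_error(le_with_xeno(-1, 0.5, 4), "positive")
  expect_error(le_with_xeno(1, 1.5, 4), "\\[0, 1\\]")
  expect_error(le_with_xeno(1, 0.5, -4), "non-negative")
})

test_that("le_with_xeno is linear in p and le_relist (finite differences)", {
  f <- function(p, le) le_with_xeno(2, p, le)
  expect_equal(f(0.6, 8) - f(0.5, 8), 0.1 * 8)
  expect_equal(f(0.5, 9) - f(0.5, 8), 0.5 * 1)
})

test_that("relisting probability: boundaries and cohort-level recovery", {
  rec <- make_patient()[rep(1, 50), ]
  rec$patient_id <- 1:50
  rec$graft_failed <- rep(c(1L, NA), 25)
  rec$relisted <- ifelse(rec$graft_failed %in% 1L, 1L, NA)
  expect_equal(estimate_relist_probability(rec, level = "cohort")$probability, 1)
  rec$relisted[rec$graft_failed %in% 1L] <- 0L
  est <- estimate_relist_probability(rec, level = "cohort")
  expect_equal(est$probability, 0)
  expect_equal(est$n_events, 25L)
  rec$graft_failed <- NA_integer_
  expect_error(estimate_relist_probability(rec, level = "cohort"),
               "parent cohort")
})

test_that("cohort relisting estimate matches the logistic ground truth", {
  # intercept -0.5 and no covariate effects: relisting probability is
  # expit(-0.5) for everyone; the empirical fraction must recover it
  cfg <- generator_config(
    n_patients = 20000, n_centers = 5, n_donors = 200, seed = 31,
    transplant_hazard = list(base_rate = 0.5, shape = 1, coefs = c(diabetes = 0)),
    graft_failure_rate = 0.5,
    relist_logit_coefs = c(intercept = -0.5))
  b <- generate_registry(cfg)
  est <- estimate_relist_probability(b$patients, level = "cohort")
  expect_gt(est$n_events, 2000)
  expect_equal(est$probability, stats::plogis(-0.5), tolerance = 0.02)
})

test_that("individual relisting estimates lie in [0,1] and track covariates", {
  act <- shared_active()
  est <- estimate_relist_probability(act, patients = act, level = "individual")
  expect_true(all(est$probability >= 0 & est$probability <= 1))
  expect_equal(nrow(est), nrow(act))
})

test_that("identify_viable matches a brute-force per-patient comparison", {
  act <- shared_active()[1:400, ]
  models <- shared_models()
  assum <- xeno_assumptions()
  p_rel <- rep(0.5, nrow(act))
  le_rel <- le_after_relisting(act, models, scenario_params("base"),
                               donors = shared_bundle()$donors)
  res <- identify_viable(act, models$waitlist_death, assum, p_rel, le_rel)
  # oracle: recompute both LE numbers outside the engine, patient by patient
  for (i in sample(nrow(act), 30)) {
    le_sq <- life_expectancy(predict_curve(models$waitlist_death, act[i, ]))
    for (n in assum$n_grid) {
      row <- res[res$patient_id == act$patient_id[i] & res$n == n, ]
      expect_equal(row$le_status_quo, le_sq, tolerance = 1e-9)
      expect_equal(row$le_xeno, n + 0.5 * le_rel[i], tolerance = 1e-9)
      expect_identical(row$viable, row$le_xeno > le_sq)
    }
  }
})

test_that("viability is strict and bounded below by n", {
  act <- shared_active()[1:50, ]
  models <- shared_models()
  assum <- xeno_assumptions(n_grid = c(1, 2))
  S <- predict_curve_matrix(models$waitlist_death, act)
  le_sq <- sapply(seq_len(nrow(act)), function(i)
    life_expectancy(survival_curve(models$waitlist_death$grid, S[i, ])))
  # engineer exact ties at n = 2: p = 0, le_xeno = n
  tie_idx <- which(abs(le_sq - 2) < 1.5)[1]
  res <- identify_viable(act, models$waitlist_death, assum,
                         relist_probability = 0,
                         le_relist = 0)
  expect_true(all(res$le_xeno == rep(c(1, 2), each = nrow(act))))
  got <- res[res$n == 2, ]
  expect_identical(got$viable, got$le_xeno > got$le_status_quo)
  # patient with le_status_quo < n and p = 0 is viable
  short <- got[got$le_status_quo < 2, ]
  expect_true(all(short$viable))
  # exact tie is non-viable
  res_tie <- identify_viable(act[1, ], models$waitlist_death,
                             xeno_assumptions(n_grid = le_sq[1]),
                             relist_probability = 0, le_relist = 0)
  expect_false(res_tie$viable)
})

test_that("inactive patients are rejected by the engine", {
  act <- shared_active()[1:10, ]
  act$active[3] <- 0L
  expect_error(identify_viable(act, shared_models()$waitlist_death,
                               xeno_assumptions(), 0.5, 5),
               "inactive")
})

test_that("viable sets are nested over n in the base scenario", {
  act <- shared_active()[1:300, ]
  models <- shared_models()
  le_rel <- le_after_relisting(act, models, scenario_params("base"),
                               donors = shared_bundle()$donors)
  res <- identify_viable(act, models$waitlist_death, xeno_assumptions(),
                         rep(0.6, nrow(act)), le_rel)
  grid <- xeno_assumptions()$n_grid
  for (j in seq_along(grid)[-1]) {
    v_small <- res$patient_id[res$n == grid[j - 1] & res$viable]
    v_large <- res$patient_id[res$n == grid[j] & res$viable]
    expect_true(all(v_small %in% v_large))
  }
})

test_that("p_relist = 1 with le_relist = le_status_quo makes everyone viable", {
  act <- shared_active()[1:100, ]
  models <- shared_models()
  S <- predict_curve_matrix(models$waitlist_death, act)
  le_sq <- apply(S, 1, function(s)
    life_expectancy(survival_curve(models$waitlist_death$grid, s)))
  res <- identify_viable(act, models$waitlist_death,
                         xeno_assumptions(n_grid = c(0.5, 2)),
                         relist_probability = 1,
                         le_relist = matrix(le_sq, nrow = length(le_sq), ncol = 2))
  expect_true(all(res$viable))
})

test_that("sensitivity table tallies viable flags and validates the grid", {
  act <- shared_active()[1:200, ]
  models <- shared_models()
  res <- identify_viable(act, models$waitlist_death, xeno_assumptions(),
                         0.5, 4)
  tab <- sensitivity_table(res)
  expect_equal(tab$n, sort(xeno_assumptions()$n_grid))
  for (k in seq_len(nrow(tab))) {
    expect_equal(tab$count_viable[k],
                 sum(res$viable[res$n == tab$n[k]]))
  }
  expect_true(all(diff(tab$fraction_viable) >= 0))  # base: le_relist fixed
  expect_true(all(tab$fraction_viable >= 0 & tab$fraction_viable <= 1))
  expect_error(sensitivity_table(res, n_grid = c(xeno_assumptions()$n_grid, 9)),
               "missing n = 9")
  # all-viable limit
  res$viable <- TRUE
  expect_true(all(sensitivity_table(res)$fraction_viable == 1))
})
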