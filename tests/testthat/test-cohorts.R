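# Cohort definitions/assignment, center aggressiveness, and the cohort
# report.

test_that("assignment follows the cohort table", {
  agg <- data.frame(center_id = 1:3,
                    acceptance_rate = c(0.6, 0.3, 0.1),
                    offer_seen_rate = c(0.9, 0.5, 0.2),
                    score = c(0.54, 0.15, 0.02),
                    tertile = c("top", "middle", "bottom"))
  p1 <- make_patient(diabetes = 1L, blood_type = "O", age_at_listing = 55,
                     waiting_time_elapsed = 4, cpra = 0, center_id = 1L)
  expect_setequal(assign_cohorts(p1, agg), c(1L, 3L, 9L))
  p2 <- make_patient(diabetes = 0L, age_at_listing = 30, cpra = 0)
  expect_length(assign_cohorts(p2, agg), 0)
  p3 <- make_patient(diabetes = 0L, age_at_listing = 40, cpra = 99.7)
  expect_identical(assign_cohorts(p3, agg), 11L)
  # bottom-tertile center, short wait
  p4 <- make_patient(diabetes = 1L, blood_type = "B", age_at_listing = 70,
                     waiting_time_elapsed = 1, center_id = 3L)
  expect_setequal(assign_cohorts(p4, agg), c(2L, 6L, 8L))
  # age 64 falls outside [50, 64); age 65 is 65+
  expect_length(intersect(assign_cohorts(
    make_patient(diabetes = 1L, blood_type = "O", age_at_listing = 64.5,
                 center_id = 1L), agg), c(1L, 2L)), 0)
})

test_that("tertile-dependent cohorts require a known center", {
  p <- make_patient(diabetes = 1L, blood_type = "O", age_at_listing = 55,
                    center_id = 99L)
  agg <- data.frame(center_id = 1L, acceptance_rate = 1, offer_seen_rate = 1,
                    score = 1, tertile = "top")
  expect_error(cohort_membership(p, agg), "tertile unknown")
  expect_error(cohort_membership(p, NULL), "tertile unknown")
})

test_that("cohort nesting holds on a generated bundle", {
  act <- shared_active()
  agg <- aggressiveness(shared_bundle()$patients, shared_bundle()$offers)
  M <- cohort_membership(act, agg)
  expect_true(all(M[, "3"] <= M[, "1"]))
  expect_true(all(M[, "4"] <= M[, "2"]))
  expect_true(all(M[, "5"] <= M[, "1"]))
  expect_true(all(M[, "6"] <= M[, "2"]))
  expect_true(all(M[, "9"] <= M[, "1"]))
  expect_true(all(M[, "10"] <= M[, "2"]))
  # 3 and 5 partition 1 up to the measure-zero boundary w = 3
  expect_true(all((M[, "3"] | M[, "5"]) == M[, "1"]))
  expect_true(all(colSums(M) > 0))  # every cohort populated at n = 2500
})

test_that("acceptance rate counts marginal offers only", {
  offers <- data.frame(
    offer_id = 1:6, center_id = c(1, 1, 1, 1, 2, 2),
    patient_id = c(1, 1, 2, 2, 3, 3), donor_id = 1:6,
    marginal = c(1, 1, 1, 0, 1, 1), seen = c(1, 1, 0, 1, 1, 1),
    accepted = c(1, 0, 0, 1, 0, 0))
  expect_equal(acceptance_rate(offers, 1), 1 / 3)   # the non-marginal accept ignored
  expect_equal(acceptance_rate(offers, 2), 0)
  all_acc <- offers; all_acc$accepted <- all_acc$marginal; all_acc$seen <- 1
  expect_equal(acceptance_rate(all_acc, 1), 1)
  empty <- acceptance_rate(offers[offers$marginal == 0, ], 1)
  expect_true(is.na(empty) && isTRUE(attr(empty, "undefined")))
})

test_that("offer-seen rate averages per-patient national fractions", {
  patients <- make_patient()[rep(1, 2), ]
  patients$patient_id <- 1:2
  patients$center_id <- 1L
  # 5 national marginal offers; patient 1 sees 1 of them, patient 2 sees 3
  offers <- data.frame(
    offer_id = 1:5, center_id = c(1, 1, 1, 1, 2),
    patient_id = c(1, 2, 2, 2, 3), donor_id = 1:5,
    marginal = 1L, seen = c(1, 1, 1, 1, 0), accepted = 0L)
  expect_equal(offer_seen_rate(offers, patients, 1), mean(c(1 / 5, 3 / 5)))
  offers$seen <- 0L
  expect_equal(offer_seen_rate(offers, patients, 1), 0)
  und <- offer_seen_rate(offers, patients, 5)
  expect_true(is.na(und) && isTRUE(attr(und, "undefined")))
})

test_that("aggressiveness is the product of its components, with rank tertiles", {
  b <- shared_bundle()
  agg <- aggressiveness(b$patients, b$offers)
  ok <- !is.na(agg$score)
  expect_equal(agg$score[ok],
               agg$acceptance_rate[ok] * agg$offer_seen_rate[ok])
  expect_true(all(agg$score[ok] <= agg$acceptance_rate[ok] + 1e-12))
  expect_true(all(agg$score[ok] <= agg$offer_seen_rate[ok] + 1e-12))
  # independent recount of one center's acceptance rate
  cid <- agg$center_id[which(ok)[1]]
  m <- b$offers[b$offers$center_id == cid & b$offers$marginal == 1L, ]
  expect_equal(agg$acceptance_rate[agg$center_id == cid],
               sum(m$accepted) / nrow(m))
})

test_that("nine distinct scores split into tertiles of three", {
  patients <- make_patient()[rep(1, 9), ]
  patients$patient_id <- 1:9
  patients$center_id <- 1:9
  offers <- do.call(rbind, lapply(1:9, function(cc) data.frame(
    offer_id = (cc - 1) * 10 + 1:10, center_id = cc, patient_id = cc,
    donor_id = 1, marginal = 1L, seen = 1L,
    accepted = c(rep(1L, cc), rep(0L, 10 - cc)))))
  agg <- aggressiveness(patients, offers)
  expect_equal(as.integer(table(agg$tertile)[c("top", "middle", "bottom")]),
               c(3L, 3L, 3L))
  # highest acceptance centers are top
  expect_setequal(agg$center_id[agg$tertile == "top"], 7:9)
})

test_that("cohort report assembles curves, size and sensitivity rows", {
  act <- shared_active()
  b <- shared_bundle()
  agg <- aggressiveness(b$patients, b$offers)
  M <- cohort_membership(act, agg)
  models <- shared_models()
  le_rel <- le_after_relisting(act[M[, "1"], ], models, scenario_params("base"),
                               donors = b$donors)
  eq <- identify_viable(act[M[, "1"], ], models$waitlist_death,
                        xeno_assumptions(), 0.5, le_rel)
  rep1 <- cohort_report(1, act, M, equipoise = eq)
  expect_equal(rep1$size, sum(M[, "1"]))
  expect_s3_class(rep1$survival$curve, "survival_curve")
  expect_s3_class(rep1$transplant$curve, "incidence_curve")
  expect_equal(nrow(rep1$sensitivity), 7)
  expect_true(all(diff(rep1$sensitivity$fraction_viable) >= 0))
  M0 <- M; M0[, "11"] <- FALSE
  expect_error(cohort_report(11, act, M0), "empty cohort")
})
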