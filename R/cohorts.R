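# Cohort definitions and assignment, and the center "aggressiveness" score.
# The eleven cohorts single out waitlisted candidates with low survival and
# low transplant rates: diabetics of blood type B or O in the 50-64 and 65+
# age bands, refined by elapsed waiting time (< 3 vs >= 3 years) or by the
# aggressiveness tertile of their listing center, plus the very highly
# sensitized (CPRA >= 99.5). Cohorts overlap by construction (3 and 5 refine
# 1; 4 and 6 refine 2; and so on).

#' The eleven cohort definitions
#'
#' Conjunctive predicates; age intervals are half-open `[lo, hi)` and `65+`
#' means age >= 65.
#'
#' @return data frame with one row per cohort: `cohort_id`,
#'   `diabetes_required`, `blood_types`, `age_lo`, `age_hi`,
#'   `waiting_time_condition` (`">=3"`, `"<3"` or NA), `center_tertile`
#'   (`"top"`, `"bottom"` or NA), `cpra_min`.
#' @export
cohort_definitions <- function() {
  base <- function(id, age_lo, age_hi, wait = NA, tertile = NA) {
    data.frame(cohort_id = id, diabetes_required = TRUE, blood_types = "B,O",
               age_lo = age_lo, age_hi = age_hi, waiting_time_condition = wait,
               center_tertile = tertile, cpra_min = NA_real_)
  }
  rbind(
    base(1, 50, 64), base(2, 65, Inf),
    base(3, 50, 64, wait = ">=3"), base(4, 65, Inf, wait = ">=3"),
    base(5, 50, 64, wait = "<3"), base(6, 65, Inf, wait = "<3"),
    base(7, 50, 64, tertile = "bottom"), base(8, 65, Inf, tertile = "bottom"),
    base(9, 50, 64, tertile = "top"), base(10, 65, Inf, tertile = "top"),
    data.frame(cohort_id = 11, diabetes_required = FALSE, blood_types = NA,
               age_lo = NA_real_, age_hi = NA_real_,
               waiting_time_condition = NA, center_tertile = NA,
               cpra_min = 99.5)
  )
}

#' Cohort membership matrix
#'
#' @param patients patient records.
#' @param aggressiveness output of [aggressiveness()]; required whenever a
#'   tertile-conditioned cohort (7-10) is evaluated. An error is raised if a
#'   patient's center has no tertile.
#' @return logical matrix `nrow(patients) x 11` with column names `"1".."11"`.
#' @export
cohort_membership <- function(patients, aggressiveness = NULL) {
  defs <- cohort_definitions()
  tert <- rep(NA_character_, nrow(patients))
  if (!is.null(aggressiveness)) {
    m <- match(patients$center_id, aggressiveness$center_id)
    tert <- aggressiveness$tertile[m]
  }
  M <- matrix(FALSE, nrow(patients), nrow(defs),
              dimnames = list(NULL, defs$cohort_id))
  for (i in seq_len(nrow(defs))) {
    d <- defs[i, ]
    ok <- rep(TRUE, nrow(patients))
    if (isTRUE(d$diabetes_required)) ok <- ok & patients$diabetes == 1L
    if (!is.na(d$blood_types)) {
      ok <- ok & patients$blood_type %in% strsplit(d$blood_types, ",")[[1]]
    }
    if (!is.na(d$age_lo)) {
      ok <- ok & patients$age_at_listing >= d$age_lo &
        patients$age_at_listing < d$age_hi
    }
    if (!is.na(d$waiting_time_condition)) {
      ok <- ok & if (d$waiting_time_condition == ">=3") {
        patients$waiting_time_elapsed >= 3
      } else {
        patients$waiting_time_elapsed < 3
      }
    }
    if (!is.na(d$center_tertile)) {
      need <- ok  # tertile only consulted where the other conditions hold
      if (any(need & is.na(tert))) {
        stop("center tertile unknown for center ",
             patients$center_id[which(need & is.na(tert))[1]],
             "; compute aggressiveness first", call. = FALSE)
      }
      ok <- ok & !is.na(tert) & tert == d$center_tertile
    }
    if (!is.na(d$cpra_min)) ok <- ok & patients$cpra >= d$cpra_min
    M[, i] <- ok
  }
  M
}

#' Cohorts a single patient belongs to
#'
#' @param patient one-row patient data frame.
#' @param aggressiveness see [cohort_membership()].
#' @return integer vector of cohort ids (possibly empty).
#' @export
assign_cohorts <- function(patient, aggressiveness = NULL) {
  M <- cohort_membership(as.data.frame(patient), aggressiveness)
  as.integer(colnames(M)[M[1, ]])
}

#' Marginal-organ acceptance rate of a center
#'
#' Accepted marginal organs divided by marginal organs offered to the center's
#' patients. `NA` (flagged undefined) when the center received no marginal
#' offers.
#'
#' @param offers offer log.
#' @param center center id.
#' @return value in `[0, 1]`, or `NA` with attribute `undefined = TRUE`.
#' @export
acceptance_rate <- function(offers, center) {
  m <- offers[offers$center_id == center & offers$marginal == 1L, , drop = FALSE]
  if (nrow(m) == 0) return(structure(NA_real_, undefined = TRUE))
  sum(m$accepted) / nrow(m)
}

#' Offer-seen rate of a center
#'
#' For each of the center's patients: the fraction of the national marginal
#' organ universe the patient saw (seen marginal offers over all marginal
#' offers made nationally), averaged across the center's patients. Patients
#' with no offers contribute 0. `NA`-flagged when the center has no patients
#' or no marginal organ was offered nationally.
#'
#' @param offers national offer log.
#' @param patients patient roster (defines who is listed at the center).
#' @param center center id.
#' @return value in `[0, 1]`, or flagged `NA`.
#' @export
offer_seen_rate <- function(offers, patients, center) {
  roster <- patients$patient_id[patients$center_id == center]
  if (length(roster) == 0) return(structure(NA_real_, undefined = TRUE))
  national <- sum(offers$marginal == 1L)
  if (national == 0) return(structure(NA_real_, undefined = TRUE))
  m <- offers[offers$marginal == 1L & offers$seen == 1L &
                offers$patient_id %in% roster, , drop = FALSE]
  seen_per_patient <- table(factor(m$patient_id, levels = roster))
  mean(as.numeric(seen_per_patient) / national)
}

#' Center aggressiveness scores with tertile classification
#'
#' Aggressiveness = marginal-organ acceptance rate x offer-seen rate,
#' capturing both a center's willingness to transplant marginal organs and
#' its patients' exposure to such offers. Centers with an undefined component
#' are flagged and excluded from the tertile ranking. Tertiles are assigned
#' by descending score; ties are broken by center id, and when the number of
#' rankable centers is not divisible by 3 the extra centers go to the top
#' (then middle) tertile.
#'
#' @param patients patient roster.
#' @param offers national offer log.
#' @return data frame: `center_id`, `acceptance_rate`, `offer_seen_rate`,
#'   `score`, `tertile` (`"top"`, `"middle"`, `"bottom"`, or NA when
#'   undefined).
#' @export
aggressiveness <- function(patients, offers) {
  centers <- sort(unique(patients$center_id))
  acc <- vapply(centers, function(cc) as.numeric(acceptance_rate(offers, cc)),
                numeric(1))
  seen <- vapply(centers, function(cc)
    as.numeric(offer_seen_rate(offers, patients, cc)), numeric(1))
  score <- acc * seen
  tertile <- rep(NA_character_, length(centers))
  ok <- which(!is.na(score))
  if (length(ok) > 0) {
    ord <- ok[order(-score[ok], centers[ok])]
    m <- length(ord)
    k <- m %/% 3
    sizes <- c(top = k + (m %% 3 > 0), middle = k + (m %% 3 > 1), bottom = k)
    tertile[ord] <- rep(c("top", "middle", "bottom"), times = sizes)
  }
  data.frame(center_id = centers, acceptance_rate = acc,
             offer_seen_rate = seen, score = score, tertile = tertile)
}

#' Cohort report: curves, size, and sensitivity rows
#'
#' Kaplan-Meier survival and time-to-transplant curves with 95% bands for one
#' cohort, its size, and (when equipoise results are supplied) its viable
#' fractions per n. Curves with fewer than `min_events` events are flagged
#' suppressed.
#'
#' @param cohort_id cohort id (1-11).
#' @param records patient records.
#' @param membership cohort membership matrix from [cohort_membership()]
#'   aligned with `records`.
#' @param equipoise optional [identify_viable()] results for `records`.
#' @param min_events suppression threshold.
#' @param horizon,step curve grid.
#' @return list: `cohort_id`, `size`, `survival` and `transplant`
#'   (`curve_with_band`), `sensitivity` (or NULL).
#' @export
cohort_report <- function(cohort_id, records, membership, equipoise = NULL,
                          min_events = 15, horizon = 25, step = 1 / 12) {
  keep <- membership[, as.character(cohort_id)]
  if (!any(keep)) stop("empty cohort ", cohort_id, call. = FALSE)
  members <- records[keep, , drop = FALSE]
  sens <- NULL
  if (!is.null(equipoise)) {
    sens <- sensitivity_table(
      equipoise[equipoise$patient_id %in% members$patient_id, , drop = FALSE])
    sens$suppressed <- sens$count_viable < min_events
  }
  list(cohort_id = cohort_id, size = nrow(members),
       survival = km_with_band(members, "waitlist_death",
                               min_events = min_events, horizon = horizon,
                               step = step),
       transplant = km_with_band(members, "time_to_transplant",
                                 min_events = min_events, horizon = horizon,
                                 step = step),
       sensitivity = sens)
}
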