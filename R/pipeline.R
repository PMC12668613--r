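# End-to-end pipeline: simulate -> fit -> equipoise -> cohorts -> incentives
# -> evaluate, with a YAML config, per-stage CSV/JSON artifacts and a run
# manifest carrying file digests for reproducibility checks. All randomness
# flows from the single config seed through named sub-streams.

pipeline_stages <- c("simulate", "fit", "equipoise", "cohorts", "incentives",
                     "evaluate", "all")

#' Default pipeline configuration
#'
#' @return nested list mirroring the YAML config layout.
#' @export
default_pipeline_config <- function() {
  list(
    seed = 1,
    generator = list(n_patients = 10000, n_centers = 30, n_donors = 1500),
    model = list(backend = "cox", horizon = 25, steps_per_year = 12,
                 num_trees = 300, importance_backend_pair = c("rsf", "cox"),
                 importance_train = 4000, importance_eval = 1000,
                 importance_num_trees = 150, importance_repeats = 10),
    assumptions = list(n_grid = c(0.5, 1, 1.5, 2, 3, 4, 5), q = 75),
    scenarios = list(set = scenario_names, priority_multiplier = 5,
                     cohort_ids = 1:4),
    relist = list(level = "individual"),
    metrics = list(taus = c(1, 2, 3), min_correct = 15)
  )
}

config_error <- function(path, msg) {
  stop(structure(class = c("xenoeq_config_error", "error", "condition"),
                 list(message = paste0("invalid config: ", path, " ", msg),
                      call = NULL)))
}

missing_artifact_error <- function(path) {
  stop(structure(class = c("xenoeq_missing_artifact", "error", "condition"),
                 list(message = paste0("missing upstream artifact: ", path,
                                       "; run the earlier stages first"),
                      call = NULL)))
}

#' Load and validate a pipeline configuration
#'
#' Reads a YAML file, overlays it on [default_pipeline_config()], and
#' validates: unknown keys are rejected with their field path; required
#' fields must be present and well formed.
#'
#' @param path YAML file, or `NULL` for the defaults.
#' @return validated config list.
#' @export
load_pipeline_config <- function(path = NULL) {
  cfg <- default_pipeline_config()
  if (!is.null(path)) {
    if (!file.exists(path)) config_error(path, "file not found")
    user <- yaml::read_yaml(path)
    cfg <- merge_config(cfg, user, prefix = NULL)
  }
  validate_pipeline_config(cfg)
  cfg
}

merge_config <- function(base, user, prefix) {
  for (nm in names(user)) {
    path <- paste(c(prefix, nm), collapse = ".")
    if (!nm %in% names(base)) config_error(path, "is not a known field")
    if (is.list(base[[nm]]) && !is.null(names(base[[nm]]))) {
      if (!is.list(user[[nm]])) config_error(path, "must be a mapping")
      base[[nm]] <- merge_config(base[[nm]], user[[nm]], prefix = c(prefix, nm))
    } else {
      base[[nm]] <- user[[nm]]
    }
  }
  base
}

validate_pipeline_config <- function(cfg) {
  if (is.null(cfg$assumptions$n_grid) || length(cfg$assumptions$n_grid) == 0) {
    config_error("assumptions.n_grid", "is required")
  }
  if (is.unsorted(cfg$assumptions$n_grid) || any(cfg$assumptions$n_grid <= 0)) {
    config_error("assumptions.n_grid", "must be positive and sorted")
  }
  if (!cfg$model$backend %in% c("cox", "rsf", "km")) {
    config_error("model.backend", "must be one of cox, rsf, km")
  }
  if (!cfg$relist$level %in% c("individual", "cohort")) {
    config_error("relist.level", "must be individual or cohort")
  }
  if (cfg$model$steps_per_year <= 0 ||
      cfg$model$steps_per_year != round(cfg$model$steps_per_year)) {
    config_error("model.steps_per_year", "must be a positive integer")
  }
  bad <- setdiff(cfg$scenarios$set, scenario_names)
  if (length(bad) > 0) config_error("scenarios.set", paste("unknown:", bad[1]))
  invisible(cfg)
}

#' Run pipeline stages
#'
#' @param stage one of `simulate`, `fit`, `equipoise`, `cohorts`,
#'   `incentives`, `evaluate`, or `all` (chains every stage in order).
#' @param config validated config list (from [load_pipeline_config()]); or
#'   give `config_path`.
#' @param config_path YAML config file.
#' @param out_dir output directory for all artifacts.
#' @param seed optional override of the config seed.
#' @return the run manifest, invisibly.
#' @export
run_pipeline <- function(stage = "all", config = NULL, config_path = NULL,
                         out_dir, seed = NULL) {
  stage <- match.arg(stage, pipeline_stages)
  cfg <- config %||% load_pipeline_config(config_path)
  validate_pipeline_config(cfg)
  if (!is.null(seed)) cfg$seed <- seed
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stages <- if (stage == "all") setdiff(pipeline_stages, "all") else stage
  for (s in stages) {
    fn <- get(paste0("stage_", s), mode = "function")
    message("[xenoeq] stage ", s, " ...")
    fn(cfg, out_dir)
    update_manifest(cfg, out_dir, s)
  }
  invisible(read_manifest(out_dir))
}

step_of <- function(cfg) 1 / cfg$model$steps_per_year

stage_simulate <- function(cfg, out_dir) {
  gargs <- cfg$generator
  gargs$seed <- cfg$seed
  gargs$horizon_years <- cfg$model$horizon
  gargs$time_step <- step_of(cfg)
  bundle <- generate_registry(do.call(generator_config, gargs))
  write_registry(bundle, file.path(out_dir, "registry"))
}

load_registry <- function(out_dir) {
  path <- file.path(out_dir, "registry")
  if (!file.exists(file.path(path, "patients.csv"))) missing_artifact_error(path)
  read_registry(path)
}

active_patients <- function(bundle) {
  bundle$patients[bundle$patients$active == 1L, , drop = FALSE]
}

stage_fit <- function(cfg, out_dir) {
  bundle <- load_registry(out_dir)
  active <- active_patients(bundle)
  h <- cfg$model$horizon; st <- step_of(cfg)
  bk <- cfg$model$backend
  models <- list(
    waitlist_death = fit_model(active, "waitlist_death", bk, horizon = h,
                               step = st, seed = subseed(cfg$seed, "model"),
                               num_trees = cfg$model$num_trees),
    time_to_transplant = fit_model(active, "time_to_transplant", bk,
                                   horizon = h, step = st,
                                   seed = subseed(cfg$seed, "model"),
                                   num_trees = cfg$model$num_trees),
    post_transplant_death = fit_model(active, "post_transplant_death", "cox",
                                      horizon = h, step = st,
                                      seed = subseed(cfg$seed, "model"))
  )
  models$relist <- tryCatch(
    stats::glm(relisted ~ age_at_listing + diabetes + cpra,
               data = active[active$graft_failed %in% 1L, , drop = FALSE],
               family = stats::binomial()),
    error = function(e) NULL)
  saveRDS(structure(models, version = "1"),
          file.path(out_dir, "models.rds"))

  # variable-importance tables from the forest/Cox backend pair, fitted on a
  # seeded training subsample and permuted on a disjoint evaluation
  # subsample, and the top-3 union that defines the cohort variables
  set.seed(subseed(cfg$seed, "model"))
  idx <- sample.int(nrow(active))
  n_train <- min(cfg$model$importance_train, ceiling(nrow(active) * 0.7))
  n_eval <- min(cfg$model$importance_eval, nrow(active) - n_train)
  train <- active[idx[seq_len(n_train)], , drop = FALSE]
  held <- active[idx[n_train + seq_len(n_eval)], , drop = FALSE]
  imp_rows <- list(); union_rows <- list()
  for (tgt in c("waitlist_death", "time_to_transplant")) {
    tabs <- list()
    for (b in cfg$model$importance_backend_pair) {
      m <- fit_model(train, tgt, b, horizon = h, step = st,
                     seed = subseed(cfg$seed, "model"),
                     num_trees = cfg$model$importance_num_trees)
      tab <- variable_importance(m, held,
                                 n_repeats = cfg$model$importance_repeats,
                                 seed = subseed(cfg$seed, "model"))
      tab$target <- tgt; tab$backend <- b
      tabs[[b]] <- tab
      imp_rows[[paste(tgt, b)]] <- tab
    }
    union_rows[[tgt]] <- data.frame(
      target = tgt, variable = top_k_union(tabs[[1]], tabs[[2]], 3))
  }
  utils::write.csv(do.call(rbind, imp_rows),
                   file.path(out_dir, "importance.csv"), row.names = FALSE)
  utils::write.csv(do.call(rbind, union_rows),
                   file.path(out_dir, "top3_union.csv"), row.names = FALSE)
}

load_models <- function(out_dir) {
  f <- file.path(out_dir, "models.rds")
  if (!file.exists(f)) missing_artifact_error(f)
  readRDS(f)
}

relist_probabilities <- function(cfg, models, bundle, active) {
  if (cfg$relist$level == "cohort" || is.null(models$relist)) {
    est <- estimate_relist_probability(active, level = "cohort")
    rep(est$probability, nrow(active))
  } else {
    unname(stats::predict(models$relist, newdata = active, type = "response"))
  }
}

stage_equipoise <- function(cfg, out_dir) {
  bundle <- load_registry(out_dir)
  models <- load_models(out_dir)
  active <- active_patients(bundle)
  p_rel <- relist_probabilities(cfg, models, bundle, active)
  sp <- scenario_params("base", q = cfg$assumptions$q,
                        time_step = step_of(cfg), horizon = cfg$model$horizon)
  le_rel <- le_after_relisting(active, models, sp, donors = bundle$donors)
  assum <- xeno_assumptions(n_grid = cfg$assumptions$n_grid,
                            q = cfg$assumptions$q)
  res <- identify_viable(active, models$waitlist_death, assum,
                         relist_probability = p_rel, le_relist = le_rel)
  res$le_status_quo <- round(res$le_status_quo, 6)
  res$le_xeno <- round(res$le_xeno, 6)
  utils::write.csv(res, file.path(out_dir, "equipoise.csv"), row.names = FALSE)
  utils::write.csv(sensitivity_table(res, assum$n_grid),
                   file.path(out_dir, "sensitivity.csv"), row.names = FALSE)
}

stage_cohorts <- function(cfg, out_dir) {
  bundle <- load_registry(out_dir)
  active <- active_patients(bundle)
  agg <- aggressiveness(bundle$patients, bundle$offers)
  utils::write.csv(agg, file.path(out_dir, "aggressiveness.csv"),
                   row.names = FALSE)
  M <- cohort_membership(active, agg)
  assign <- data.frame(
    patient_id = rep(active$patient_id, ncol(M))[as.vector(M)],
    cohort_id = rep(as.integer(colnames(M)), each = nrow(M))[as.vector(M)])
  assign <- assign[order(assign$patient_id, assign$cohort_id), ]
  utils::write.csv(assign, file.path(out_dir, "cohort_assignments.csv"),
                   row.names = FALSE)
  eqf <- file.path(out_dir, "equipoise.csv")
  if (!file.exists(eqf)) missing_artifact_error(eqf)
  eq <- utils::read.csv(eqf)
  curve_rows <- list(); sens_rows <- list(); summary_rows <- list()
  for (cid in seq_len(ncol(M))) {
    size <- sum(M[, cid])
    summary_rows[[cid]] <- data.frame(cohort_id = cid, size = size)
    if (size == 0) next
    rep_c <- cohort_report(cid, active, M, equipoise = eq,
                           min_events = cfg$metrics$min_correct,
                           horizon = cfg$model$horizon, step = step_of(cfg))
    if (!is.null(rep_c$sensitivity)) {
      sens_rows[[cid]] <- rep_c$sensitivity
    }
    if (cid %in% cfg$scenarios$cohort_ids) {
      for (what in c("survival", "transplant")) {
        cb <- rep_c[[what]]
        vals <- cb$curve$probabilities %||% cb$curve$cumulative_probability
        curve_rows[[paste(cid, what)]] <- data.frame(
          cohort_id = cid, curve = what, time = cb$curve$times,
          value = round(vals, 6), lower = round(cb$lower, 6),
          upper = round(cb$upper, 6), n_events = cb$n_events,
          suppressed = cb$suppressed)
      }
    }
  }
  utils::write.csv(do.call(rbind, summary_rows),
                   file.path(out_dir, "cohort_summary.csv"), row.names = FALSE)
  utils::write.csv(do.call(rbind, sens_rows),
                   file.path(out_dir, "cohort_sensitivity.csv"),
                   row.names = FALSE)
  utils::write.csv(do.call(rbind, curve_rows),
                   file.path(out_dir, "cohort_curves.csv"), row.names = FALSE)
}

stage_incentives <- function(cfg, out_dir) {
  bundle <- load_registry(out_dir)
  models <- load_models(out_dir)
  active <- active_patients(bundle)
  agg <- aggressiveness(bundle$patients, bundle$offers)
  M <- cohort_membership(active, agg)
  p_rel <- relist_probabilities(cfg, models, bundle, active)
  assum <- xeno_assumptions(n_grid = cfg$assumptions$n_grid,
                            q = cfg$assumptions$q)
  # restrict the heavy recursion to members of the reported cohorts
  keep <- rowSums(M[, as.character(cfg$scenarios$cohort_ids), drop = FALSE]) > 0
  rep_df <- incentivized_fractions(
    active[keep, , drop = FALSE], M[keep, , drop = FALSE], models, assum,
    donors = bundle$donors, relist_probability = p_rel[keep],
    scenarios = cfg$scenarios$set, cohort_ids = cfg$scenarios$cohort_ids,
    priority_multiplier = cfg$scenarios$priority_multiplier,
    min_cohort = cfg$metrics$min_correct)
  rep_df$fraction_incentivized <- round(rep_df$fraction_incentivized, 6)
  rep_df$delta_vs_base <- round(rep_df$delta_vs_base, 6)
  utils::write.csv(rep_df, file.path(out_dir, "incentives.csv"),
                   row.names = FALSE)
}

stage_evaluate <- function(cfg, out_dir) {
  bundle <- load_registry(out_dir)
  eqf <- file.path(out_dir, "equipoise.csv")
  if (!file.exists(eqf)) missing_artifact_error(eqf)
  eq <- utils::read.csv(eqf)
  preds <- unique(eq[, c("patient_id", "le_status_quo")])
  names(preds)[2] <- "predicted_le"
  outcomes <- active_patients(bundle)[, c("patient_id", "outcome_type",
                                          "outcome_time")]
  reports <- lapply(cfg$metrics$taus, function(tau) {
    r <- evaluate_predictions(preds, outcomes,
                              metrics_config(tau, cfg$metrics$min_correct))
    if (r$suppressed) message("[xenoeq] metrics at tau=", tau,
                              " suppressed (n_correct < ",
                              cfg$metrics$min_correct, ")")
    unclass(r)
  })
  names(reports) <- paste0("tau_", cfg$metrics$taus)
  jsonlite::write_json(reports, file.path(out_dir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA)
}

manifest_path <- function(out_dir) file.path(out_dir, "manifest.json")

read_manifest <- function(out_dir) {
  f <- manifest_path(out_dir)
  if (file.exists(f)) jsonlite::read_json(f) else list(stages = list())
}

update_manifest <- function(cfg, out_dir, stage) {
  man <- read_manifest(out_dir)
  man$config_hash <- substr(tools::md5sum(
    write_temp_json(cfg))[[1]], 1, 32)
  man$seed <- cfg$seed
  man$package_version <- as.character(utils::packageVersion("xenoeq"))
  files <- setdiff(list.files(out_dir, recursive = TRUE),
                   c("manifest.json"))
  files <- files[grepl("\\.(csv|json)$", files)]
  digests <- as.list(tools::md5sum(file.path(out_dir, files)))
  names(digests) <- files
  man$stages[[stage]] <- list(completed_at = format(Sys.time(), tz = "UTC"))
  man$artifacts <- digests
  jsonlite::write_json(man, manifest_path(out_dir), auto_unbox = TRUE)
  invisible(man)
}

write_temp_json <- function(x) {
  f <- tempfile(fileext = ".json")
  jsonlite::write_json(x, f, auto_unbox = TRUE, digits = NA)
  f
}

#' Artifact digests of a pipeline run
#'
#' md5 digests of every CSV/JSON artifact (manifest excluded), for
#' determinism checks: two runs with the same config and seed must agree.
#'
#' @param out_dir pipeline output directory.
#' @return named character vector of digests.
#' @export
pipeline_digests <- function(out_dir) {
  files <- setdiff(list.files(out_dir, recursive = TRUE), "manifest.json")
  files <- files[grepl("\\.(csv|json)$", files)]
  d <- tools::md5sum(file.path(out_dir, sort(files)))
  names(d) <- sort(files)
  d
}
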