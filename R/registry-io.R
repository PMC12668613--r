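# Plain-text serialisation of a registry bundle: one CSV per table plus a JSON
# sidecar holding the ground-truth generator configuration. Booleans are
# written as 0/1 and times carry 6 decimal digits (the generator already
# rounds, so the round trip is lossless).

required_registry_columns <- function() {
  list(
    patients = c("patient_id", "center_id", "age_at_listing", "diabetes",
                 "blood_type", "previous_transplant", "cpra", "bmi", "albumin",
                 "sdi", "waiting_time_elapsed", "active", "outcome_type",
                 "outcome_time"),
    donors = c("donor_id", "blood_type", "quality"),
    centers = c("center_id", "acceptance_propensity", "screen_propensity"),
    offers = c("offer_id", "center_id", "patient_id", "donor_id", "marginal",
               "seen", "accepted")
  )
}

#' Write a registry bundle to a directory
#'
#' Writes `patients.csv`, `donors.csv`, `centers.csv`, `offers.csv` and
#' `config.json` (the ground-truth generator configuration) under `path`.
#'
#' @param bundle a `registry_bundle`.
#' @param path directory; created if absent.
#' @return `path`, invisibly.
#' @export
write_registry <- function(bundle, path) {
  stopifnot(inherits(bundle, "registry_bundle"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  for (tab in c("patients", "donors", "centers", "offers")) {
    utils::write.csv(bundle[[tab]], file.path(path, paste0(tab, ".csv")),
                     row.names = FALSE)
  }
  jsonlite::write_json(config_to_list(bundle$ground_truth),
                       file.path(path, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a registry bundle from a directory
#'
#' Inverse of [write_registry()]. Validates the schema of every table and
#' raises a format error naming the first offending column.
#'
#' @param path directory written by [write_registry()].
#' @return a `registry_bundle`.
#' @export
read_registry <- function(path) {
  req <- required_registry_columns()
  tabs <- list()
  for (tab in names(req)) {
    f <- file.path(path, paste0(tab, ".csv"))
    if (!file.exists(f)) stop("format error: missing file ", f, call. = FALSE)
    df <- utils::read.csv(f, stringsAsFactors = FALSE)
    missing <- setdiff(req[[tab]], names(df))
    if (length(missing) > 0) {
      stop("format error: ", tab, ".csv missing column '", missing[1], "'",
           call. = FALSE)
    }
    tabs[[tab]] <- df
  }
  cfgf <- file.path(path, "config.json")
  if (!file.exists(cfgf)) stop("format error: missing file ", cfgf, call. = FALSE)
  cfg <- config_from_list(jsonlite::read_json(cfgf, simplifyVector = TRUE))
  structure(list(patients = tabs$patients, donors = tabs$donors,
                 centers = tabs$centers, offers = tabs$offers,
                 ground_truth = cfg),
            class = "registry_bundle")
}

config_to_list <- function(cfg) {
  out <- unclass(cfg)
  for (nm in c("death_hazard", "transplant_hazard", "post_tx_hazard")) {
    out[[nm]]$coefs <- as.list(out[[nm]]$coefs)
  }
  out$relist_logit_coefs <- as.list(out$relist_logit_coefs)
  out$covariates <- lapply(out$covariates, function(x) {
    if (is.numeric(x) && !is.null(names(x))) as.list(x) else x
  })
  out
}

config_from_list <- function(lst) {
  relist <- function(x) {
    if (is.list(x)) unlist(x) else x
  }
  for (nm in c("death_hazard", "transplant_hazard", "post_tx_hazard")) {
    lst[[nm]]$coefs <- relist(lst[[nm]]$coefs)
  }
  lst$relist_logit_coefs <- relist(lst$relist_logit_coefs)
  for (nm in c("blood_type_probs", "comorbidity_probs")) {
    lst$covariates[[nm]] <- relist(lst$covariates[[nm]])
  }
  do.call(generator_config, lst)
}
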