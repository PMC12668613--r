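# Variable importance and the top-k union used to choose cohort-defining
# variables: forests are scored by permutation importance on Harrell's
# concordance; Cox models by absolute standardized coefficients.

#' Variable importance for a fitted survival model
#'
#' For the rsf backend: permutation importance on the concordance index,
#' computed on `records` (ideally held-out), averaging `n_repeats` independent
#' permutations per variable. For the cox backend: the absolute standardized
#' coefficient `|beta| * sd(x)` (maximum over dummy columns for factors). The
#' km backend carries no covariates and is unsupported.
#'
#' @param model a fitted `xeno_surv_model` (cox or rsf).
#' @param records evaluation records.
#' @param n_repeats permutation repeats per variable (rsf backend).
#' @param seed seed for the permutations.
#' @return data frame with columns `variable`, `score`, `rank` (rank 1 = most
#'   important; ties broken by variable name for determinism).
#' @export
variable_importance <- function(model, records, n_repeats = 10, seed = 1) {
  stopifnot(inherits(model, "xeno_surv_model"))
  if (!model$backend %in% c("cox", "rsf")) {
    stop("unsupported backend for variable importance: ", model$backend,
         call. = FALSE)
  }
  dat <- prep_covariates(surv_frame(records, model$target), model$covariates)
  if (model$backend == "cox") {
    beta <- stats::coef(model$fit)
    sds <- model$train_sd[names(beta)]
    per_col <- abs(beta) * sds
    score <- vapply(model$covariates, function(v) {
      max(per_col[startsWith(names(per_col), v)])
    }, numeric(1))
  } else {
    set.seed(seed)
    y <- survival::Surv(dat$time, dat$event)
    risk0 <- rsf_risk(model$fit, dat)
    c0 <- concordance_of(y, risk0)
    score <- vapply(model$covariates, function(v) {
      mean(vapply(seq_len(n_repeats), function(r) {
        perm <- dat
        perm[[v]] <- perm[[v]][sample.int(nrow(perm))]
        c0 - concordance_of(y, rsf_risk(model$fit, perm))
      }, numeric(1)))
    }, numeric(1))
  }
  ord <- order(-score, model$covariates)
  data.frame(variable = model$covariates[ord], score = unname(score[ord]),
             rank = seq_along(score), row.names = NULL)
}

rsf_risk <- function(fit, dat) {
  chf <- stats::predict(fit, data = dat, num.threads = 1)$chf
  chf[, ncol(chf)]
}

concordance_of <- function(y, risk) {
  survival::concordance(y ~ risk, reverse = TRUE)$concordance
}

#' Union of the top-k variables of two importance tables
#'
#' The cohort-defining variable set is the union of the k best-ranked
#' variables from two model backends (e.g. forest and Cox).
#'
#' @param table_a,table_b importance tables from [variable_importance()]; must
#'   rank the same variable universe.
#' @param k how many top variables to take from each table.
#' @return character vector (set) of size between `k` and `2k`.
#' @export
top_k_union <- function(table_a, table_b, k = 3) {
  if (!setequal(table_a$variable, table_b$variable)) {
    stop("importance tables rank different variable universes", call. = FALSE)
  }
  if (k > nrow(table_a)) stop("k exceeds the number of variables", call. = FALSE)
  union(table_a$variable[table_a$rank <= k], table_b$variable[table_b$rank <= k])
}
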