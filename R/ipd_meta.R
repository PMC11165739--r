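# Two-stage fixed-effect individual-participant-data meta-analysis:
# inverse-variance pooling of per-cohort AUC / concordance estimates,
# by default on the logit scale so pooled CIs stay inside (0, 1).

#' Fixed-effect inverse-variance pooling
#'
#' Estimates are transformed (default: logit), pooled with weights
#' proportional to inverse variance on the transform scale, and the CI
#' back-transformed.
#'
#' @param estimates per-cohort point estimates.
#' @param ses standard errors *on the transform scale* (for
#'   `transform = "identity"` these are ordinary SEs; use
#'   [meta_from_validation()] to derive logit-scale SEs from CI
#'   half-widths).
#' @param transform `"logit"` or `"identity"`.
#' @param labels optional cohort labels.
#' @param outcome,metric labels carried into the result.
#' @return object of class `meta_result`: per-cohort table, pooled
#'   estimate, SE and 95% CI (back-transformed), weights summing to 1.
#' @export
pool_fixed <- function(estimates, ses, transform = c("logit", "identity"),
                       labels = NULL, outcome = "outcome", metric = "metric") {
  transform <- match.arg(transform)
  stopifnot(length(estimates) == length(ses), all(ses > 0))
  labels <- labels %||% paste0("cohort", seq_along(estimates))
  if (transform == "logit") {
    if (any(estimates <= 0 | estimates >= 1)) {
      stop("estimate at or outside (0, 1): use transform = \"identity\"", call. = FALSE)
    }
    z <- stats::qlogis(estimates)
    back <- stats::plogis
  } else {
    z <- estimates
    back <- identity
  }
  w <- 1 / ses^2
  w <- w / sum(w)
  pooled_z <- sum(w * z)
  pooled_se <- sqrt(1 / sum(1 / ses^2))
  structure(list(
    outcome = outcome, metric = metric, transform = transform,
    cohorts = data.frame(label = labels, estimate = estimates, se = ses,
                         weight = w, stringsAsFactors = FALSE),
    pooled = back(pooled_z),
    pooled_se = pooled_se,
    ci = c(back(pooled_z - 1.96 * pooled_se), back(pooled_z + 1.96 * pooled_se))
  ), class = "meta_result")
}

#' @export
print.meta_result <- function(x, ...) {
  cat(sprintf("Fixed-effect IPD-MA (%s scale) %s/%s: pooled %.3f (95%% CI %.3f-%.3f)\n",
              x$transform, x$outcome, x$metric, x$pooled, x$ci[1], x$ci[2]))
  print(x$cohorts, row.names = FALSE)
  invisible(x)
}

#' Pool leaving one cohort out
#'
#' @param estimates,ses,labels per-cohort inputs as in [pool_fixed()].
#' @param drop cohort label to exclude.
#' @param ... passed to [pool_fixed()].
#' @return `meta_result` on the remaining cohorts.
#' @export
leave_cohort_out <- function(estimates, ses, labels, drop, ...) {
  if (!drop %in% labels) stop(sprintf("unknown cohort label '%s'", drop), call. = FALSE)
  keep <- labels != drop
  if (sum(keep) < 2L) stop("dropping would leave fewer than 2 cohorts", call. = FALSE)
  pool_fixed(estimates[keep], ses[keep], labels = labels[keep], ...)
}

#' Pool validation results across cohorts
#'
#' Takes rows of per-cohort [stratified_validation()] output for one
#' (outcome, metric, stratum) cell, converts each cohort's 95% CI to a
#' logit-scale SE (half-width of the transformed CI divided by 1.96), and
#' pools fixed-effect.
#'
#' @param results data.frame of ValidationResult rows from >= 2 cohorts.
#' @param outcome,metric,stratum cell selectors.
#' @param drop optional cohort label to leave out.
#' @return `meta_result`.
#' @export
meta_from_validation <- function(results, outcome, metric, stratum = "overall",
                                 drop = NULL) {
  sel <- results$outcome == outcome & results$metric == metric &
    results$stratum == stratum
  rows <- results[sel, , drop = FALSE]
  if (nrow(rows) < 2L) stop("need at least 2 cohort estimates to pool", call. = FALSE)
  eps <- 1e-6
  est <- pmin(pmax(rows$estimate, eps), 1 - eps)
  lo <- pmin(pmax(rows$ci_lo, eps), 1 - eps)
  hi <- pmin(pmax(rows$ci_hi, eps), 1 - eps)
  se_z <- (stats::qlogis(hi) - stats::qlogis(lo)) / (2 * 1.96)
  se_z[se_z <= 0] <- eps
  if (is.null(drop)) {
    pool_fixed(est, se_z, labels = rows$cohort, outcome = outcome, metric = metric)
  } else {
    leave_cohort_out(est, se_z, rows$cohort, drop, outcome = outcome, metric = metric)
  }
}
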