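# Predictive mean matching for systematically missing gait speed.
#
# Type-1 PMM: a linear predictor is fitted on donors (records with the
# target observed), predicted means are computed for donors and
# recipients, and each recipient receives the *observed* value of one of
# the k donors whose predicted means are closest to its own.  Imputed
# values are therefore always real observed values.

# default matching covariates: age, sex, education, 5y mortality, and the
# other four indicators
.pmm_default_covariates <- c("age", "sex", "education", "mort_5y",
                             "mmse", "n_chronic", "iadl", "padl")

# build the PMM design matrix; mort_5y derived from outcomes when asked for
.pmm_design <- function(table, covariates) {
  df <- table
  if ("mort_5y" %in% covariates && is.null(df$mort_5y)) {
    df$mort_5y <- as.integer(!is.na(df$death_event) & df$death_event == 1 &
                               df$death_time <= 5)
  }
  df <- df[, covariates, drop = FALSE]
  for (v in names(df)) if (is.character(df[[v]])) df[[v]] <- factor(df[[v]])
  ok <- stats::complete.cases(df)
  X <- stats::model.matrix(~ ., data = df[ok, , drop = FALSE])
  list(X = X, complete = ok, frame = df)
}

#' Fit a predictive mean matching model
#'
#' @param table cohort data.frame pooled over all cohorts (donors come
#'   from every cohort with the target observed).
#' @param target name of the variable to impute (default `"gait_speed"`).
#' @param covariates matching covariates; the default uses age, sex,
#'   education, 5-year mortality and the other four indicators.
#' @param k number of donors among which the imputed value is drawn.
#' @return object of class `pmm_model` with coefficients, donor predicted
#'   means and donor observed values.
#' @export
fit_pmm <- function(table, target = "gait_speed",
                    covariates = .pmm_default_covariates, k = 5L) {
  stopifnot(k >= 1L)
  y <- table[[target]]
  if (is.null(y)) stop(sprintf("target '%s' not present", target), call. = FALSE)
  des <- .pmm_design(table, covariates)
  donor <- !is.na(y) & des$complete
  if (sum(donor) < k) {
    stop(sprintf("only %d donors with observed '%s'; need at least k = %d",
                 sum(donor), target, k), call. = FALSE)
  }
  Xd <- stats::model.matrix(~ ., data = des$frame[donor, , drop = FALSE])
  yd <- y[donor]
  qr_fit <- qr(Xd)
  if (qr_fit$rank < ncol(Xd)) {
    warning("collinear covariate set; using least-norm (pseudoinverse) solution")
    sv <- svd(Xd)
    pos <- sv$d > max(sv$d) * 1e-10
    beta <- sv$v[, pos, drop = FALSE] %*% ((crossprod(sv$u[, pos, drop = FALSE], yd)) / sv$d[pos])
    beta <- drop(beta)
  } else {
    beta <- qr.coef(qr_fit, yd)
  }
  names(beta) <- colnames(Xd)
  structure(list(
    target = target, covariates = covariates, k = as.integer(k),
    coefficients = beta,
    donor_pred = drop(Xd %*% beta),
    donor_values = yd,
    donor_ids = table$participant_id[donor]
  ), class = "pmm_model")
}

#' Impute missing target values by predictive mean matching
#'
#' Each recipient (missing target, complete covariates) is matched to the
#' `k` donors with the closest predicted mean; one of them is drawn
#' uniformly (seeded by the session RNG) and its observed value imputed.
#' Recipients with missing covariates are left missing and reported via
#' the `n_unimputable` attribute.  Imputed rows are flagged in the
#' `<target>_imputed` provenance column (`gait_imputed` for gait).
#'
#' @param model fitted [fit_pmm()] model.
#' @param table cohort data.frame containing the recipients.
#' @return the table with imputations applied.
#' @export
impute_pmm <- function(model, table) {
  stopifnot(inherits(model, "pmm_model"))
  y <- table[[model$target]]
  des <- .pmm_design(table, model$covariates)
  recip <- which(is.na(y) & des$complete)
  unimputable <- sum(is.na(y) & !des$complete)
  flag_col <- if (model$target == "gait_speed") "gait_imputed" else paste0(model$target, "_imputed")
  if (is.null(table[[flag_col]])) table[[flag_col]] <- 0L
  if (length(recip)) {
    Xr <- stats::model.matrix(~ ., data = des$frame[recip, , drop = FALSE])
    # model.matrix may drop factor levels absent among recipients; align
    Xr <- Xr[, intersect(colnames(Xr), names(model$coefficients)), drop = FALSE]
    beta <- model$coefficients[colnames(Xr)]
    pred <- drop(Xr %*% beta)
    k <- min(model$k, length(model$donor_values))
    for (j in seq_along(recip)) {
      d <- abs(model$donor_pred - pred[j])
      nearest <- order(d, model$donor_ids)[seq_len(k)]  # deterministic tie-break
      pick <- nearest[sample.int(k, 1L)]
      y[recip[j]] <- model$donor_values[pick]
    }
    table[[model$target]] <- y
    table[[flag_col]][recip] <- 1L
  }
  attr(table, "n_unimputable") <- unimputable
  table
}
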