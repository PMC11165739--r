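# Predictive-capacity assessment: logistic AUC with DeLong intervals,
# Cox regression with Harrell's C, age/sex stratification, calibration.

.vresult <- function(cohort, outcome, metric, est, lo, hi, stratum, n, n_events,
                     note = NA_character_) {
  data.frame(cohort = cohort, outcome = outcome, metric = metric,
             estimate = est, ci_lo = lo, ci_hi = hi, stratum = stratum,
             n = n, n_events = n_events, note = note, stringsAsFactors = FALSE)
}

# midrank helper used by the DeLong machinery
.midranks <- function(x) rank(x, ties.method = "average")

#' AUC from an unadjusted logistic regression
#'
#' Fits `outcome ~ score` by logistic regression and reports the AUC of
#' the fitted probabilities — identical to the AUC of the raw score when
#' the fitted slope is positive-monotone, by ROC invariance to monotone
#' transforms.  The 95% CI is DeLong's, computed from the structural
#' components of the Mann-Whitney statistic.
#'
#' @param score numeric risk/health score (missing values dropped with a
#'   logged count).
#' @param outcome_flag binary 0/1 outcome vector.
#' @param cohort,outcome,stratum labels carried into the result row.
#' @param higher_risk direction: `TRUE` if larger scores indicate more
#'   risk.  For the HAT (higher = healthier) use `FALSE`; the score is
#'   negated internally so the AUC refers to predicting the event.
#' @return one-row `data.frame` (a `ValidationResult`).
#' @export
auc_logistic <- function(score, outcome_flag, cohort = "all", outcome = "outcome",
                         stratum = "overall", higher_risk = FALSE) {
  keep <- !is.na(score) & !is.na(outcome_flag)
  n_dropped <- sum(!keep)
  score <- score[keep]; y <- as.integer(outcome_flag[keep])
  if (length(unique(y)) < 2L) {
    stop(sprintf("outcome '%s' has a single class in stratum '%s'", outcome, stratum),
         call. = FALSE)
  }
  risk <- if (higher_risk) score else -score
  glm_fit <- stats::glm(y ~ risk, family = stats::binomial())
  prob <- stats::fitted(glm_fit)
  # AUC of fitted probabilities equals AUC of `risk` (monotone link);
  # compute on the linear predictor for numerical stability
  cases <- risk[y == 1]; controls <- risk[y == 0]
  m <- length(cases); n0 <- length(controls)
  r_all <- .midranks(c(cases, controls))
  auc <- (sum(r_all[seq_len(m)]) - m * (m + 1) / 2) / (m * n0)
  # DeLong structural components
  v10 <- (.midranks(c(cases, controls))[seq_len(m)] - .midranks(cases)) / n0
  v01 <- 1 - (.midranks(c(controls, cases))[seq_len(n0)] - .midranks(controls)) / m
  s10 <- stats::var(v10); s01 <- stats::var(v01)
  se <- sqrt(s10 / m + s01 / n0)
  lo <- max(0, auc - 1.96 * se); hi <- min(1, auc + 1.96 * se)
  res <- .vresult(cohort, outcome, "AUC", auc, lo, hi, stratum,
                  length(y), sum(y),
                  note = if (n_dropped) sprintf("%d missing scores dropped", n_dropped) else NA)
  attr(res, "glm") <- glm_fit
  attr(res, "fitted_prob") <- prob
  res
}

#' Harrell's concordance index from an unadjusted Cox regression
#'
#' Fits `Surv(time, event) ~ score` (for the record; higher HAT is
#' expected protective) and computes Harrell's C for the *risk* ordering
#' over usable pairs: a pair is usable if the smaller time is an event;
#' pairs tied on time are excluded unless exactly one member is an event;
#' tied scores contribute 1/2.  The CI is asymptotic (Noether-type) from
#' the U-statistic variance of the per-subject concordance components.
#'
#' @param score numeric score; `higher_risk = FALSE` (default) treats
#'   larger values as protective.
#' @param time,event_flag survival time and 0/1 event indicator.
#' @param cohort,outcome,stratum labels carried into the result.
#' @param higher_risk direction flag, as in [auc_logistic()].
#' @return one-row `data.frame` with the Cox fit in an attribute.
#' @export
harrell_c <- function(score, time, event_flag, cohort = "all",
                      outcome = "time_to_death", stratum = "overall",
                      higher_risk = FALSE) {
  keep <- !is.na(score) & !is.na(time) & !is.na(event_flag)
  score <- score[keep]; time <- time[keep]; ev <- as.integer(event_flag[keep])
  if (any(time < 0)) stop("negative survival times", call. = FALSE)
  if (sum(ev) < 1L) stop("no events; concordance undefined", call. = FALSE)
  risk <- if (higher_risk) score else -score
  cox <- survival::coxph(survival::Surv(time, ev) ~ risk)

  cc <- .concordance_pairs(risk, time, ev)
  C <- (cc$concordant + 0.5 * cc$tied) / cc$usable
  # delta-method variance of the ratio of U-statistics from per-subject sums
  num_i <- cc$per_subject_num; den_i <- cc$per_subject_den
  u <- num_i - C * den_i
  se <- sqrt(sum(u^2)) / (cc$usable / 2)
  lo <- max(0, C - 1.96 * se); hi <- min(1, C + 1.96 * se)
  res <- .vresult(cohort, outcome, "HarrellC", C, lo, hi, stratum,
                  length(ev), sum(ev))
  attr(res, "cox") <- cox
  res
}

# pairwise concordance counts, chunked to bound memory at O(chunk * n).
# returns totals and per-subject numerator/denominator sums (each pair
# counted once per member).
.concordance_pairs <- function(risk, time, event, chunk = 512L) {
  n <- length(risk)
  concordant <- tied <- usable <- 0
  num_i <- den_i <- numeric(n)
  for (s in seq(1L, n, by = chunk)) {
    idx <- s:min(s + chunk - 1L, n)
    dt <- outer(time[idx], time, "-")          # t_i - t_j
    dr <- outer(risk[idx], risk, "-")
    ei <- matrix(event[idx], length(idx), n)
    ej <- matrix(event, length(idx), n, byrow = TRUE)
    self <- outer(idx, seq_len(n), "==")
    # usable: earlier time is an event; ties on time usable iff exactly one event
    use <- (!self) & (((dt < 0) & (ei == 1)) | ((dt > 0) & (ej == 1)) |
                        ((dt == 0) & ((ei + ej) == 1L)))
    # shorter-surviving (or the event member on time ties) should have higher risk
    hi_first <- ((dt < 0) & (ei == 1)) | ((dt == 0) & (ei == 1) & (ej == 0))
    conc <- use & ((hi_first & (dr > 0)) | (!hi_first & (dr < 0)))
    tie <- use & (dr == 0)
    usable <- usable + sum(use)
    concordant <- concordant + sum(conc)
    tied <- tied + sum(tie)
    num_i[idx] <- num_i[idx] + rowSums(conc + 0.5 * tie)
    den_i[idx] <- den_i[idx] + rowSums(use)
    # symmetric contribution to the j side
    num_i <- num_i + colSums(conc + 0.5 * tie)
    den_i <- den_i + colSums(use)
  }
  # every pair was counted twice (once from each side) in the totals
  list(concordant = concordant / 1, tied = tied / 1, usable = usable / 1,
       per_subject_num = num_i / 2, per_subject_den = den_i / 2)
}

#' Stratified validation of a HAT score
#'
#' Computes every requested metric overall and within the four strata
#' (male, female, age < 78, age >= 78).  Degenerate strata (single
#' outcome class or no events) are skipped and recorded in the `skipped`
#' attribute.
#'
#' @param table cohort data.frame with outcomes.
#' @param score numeric HAT score aligned with `table` rows.
#' @param outcomes subset of
#'   `c("mort_1y","mort_3y","mort_5y","time_to_death","admit_1y","admit_3y")`.
#' @param cohort label for the result rows.
#' @param age_break stratification boundary (default 78).
#' @return data.frame of `ValidationResult` rows; skipped strata in
#'   `attr(, "skipped")`.
#' @export
stratified_validation <- function(table, score,
                                  outcomes = c("mort_1y", "mort_3y", "mort_5y",
                                               "time_to_death", "admit_1y", "admit_3y"),
                                  cohort = "all", age_break = 78) {
  strata <- list(
    overall = rep(TRUE, nrow(table)),
    male = table$sex == "male",
    female = table$sex == "female",
    age_lt = table$age < age_break,
    age_ge = table$age >= age_break
  )
  names(strata)[4:5] <- c(sprintf("age<%g", age_break), sprintf("age>=%g", age_break))
  flag <- function(k) as.integer(!is.na(table$death_event) & table$death_event == 1 &
                                   table$death_time <= k)
  out <- list(); skipped <- character(0)
  for (oc in outcomes) {
    for (sn in names(strata)) {
      sel <- strata[[sn]]
      res <- tryCatch({
        if (oc == "time_to_death") {
          harrell_c(score[sel], table$death_time[sel], table$death_event[sel],
                    cohort = cohort, outcome = oc, stratum = sn)
        } else {
          y <- switch(oc,
                      mort_1y = flag(1), mort_3y = flag(3), mort_5y = flag(5),
                      admit_1y = table$admit_1y, admit_3y = table$admit_3y)
          auc_logistic(score[sel], y[sel], cohort = cohort, outcome = oc, stratum = sn)
        }
      }, error = function(e) e)
      if (inherits(res, "error")) {
        skipped <- c(skipped, sprintf("%s/%s: %s", oc, sn, conditionMessage(res)))
      } else {
        attr(res, "glm") <- NULL; attr(res, "cox") <- NULL
        attr(res, "fitted_prob") <- NULL
        out[[length(out) + 1L]] <- res
      }
    }
  }
  res <- do.call(rbind, out)
  if (!is.null(table$admissions_unplanned)) {
    mixed <- any(table$admissions_unplanned == 0, na.rm = TRUE)
    res$note[res$outcome %in% c("admit_1y", "admit_3y") & mixed] <-
      "includes cohort(s) where planned admissions are not distinguishable"
  }
  attr(res, "skipped") <- skipped
  res
}

#' Calibration (reliability) table
#'
#' Bins records by predicted probability (deciles of the predictions by
#' default) and reports mean predicted versus observed event rate per bin.
#'
#' @param predicted_prob probabilities in \[0, 1\].
#' @param outcome_flag binary outcome.
#' @param n_bins number of quantile bins (default 10).
#' @return data.frame with `bin`, `n`, `mean_predicted`, `observed_rate`.
#' @export
reliability_table <- function(predicted_prob, outcome_flag, n_bins = 10L) {
  stopifnot(all(predicted_prob >= 0 & predicted_prob <= 1, na.rm = TRUE))
  keep <- !is.na(predicted_prob) & !is.na(outcome_flag)
  p <- predicted_prob[keep]; y <- as.integer(outcome_flag[keep])
  br <- unique(stats::quantile(p, probs = seq(0, 1, length.out = n_bins + 1L)))
  if (length(br) < 2L) {
    return(data.frame(bin = 1L, n = length(p), mean_predicted = mean(p),
                      observed_rate = mean(y)))
  }
  bin <- cut(p, breaks = br, include.lowest = TRUE, labels = FALSE)
  agg <- lapply(sort(unique(bin)), function(b) {
    sel <- bin == b
    data.frame(bin = b, n = sum(sel), mean_predicted = mean(p[sel]),
               observed_rate = mean(y[sel]))
  })
  do.call(rbind, agg)
}
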