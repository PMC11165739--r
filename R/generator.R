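# Synthetic multi-cohort generator.
#
# Emulates four Swedish aging (SNAC-like) cohorts: a single latent health
# factor theta (higher = healthier) declines linearly with age and drives
# five observed indicators, mortality, and hospital admissions.  Marginal
# targets (per-cohort age, sex, education, indicator means) are calibrated
# to the published baseline table; link intercepts are derived from those
# targets in closed form or by quadrature at generation time.

# ---- configuration -------------------------------------------------------

#' Default calibrated generator configuration
#'
#' Returns a [GeneratorConfig]-style list describing four cohorts
#' (`snac_k`, `snac_b`, `snac_gas`, `snac_n`) whose marginals are
#' calibrated to the published baseline characteristics of the source
#' cohorts.  `snac_b` has systematically missing gait speed and cannot
#' distinguish unplanned from planned admissions.
#'
#' @param scale `"included"` generates the post-exclusion sample sizes
#'   (3096/1228/2390/588) with no item-level missingness, so the
#'   harmonized dataset has exactly 7302 rows.  `"baseline"` generates the
#'   pre-exclusion sizes (3363/1402/2931/766) with per-cohort item-level
#'   missing rates calibrated so that complete-case exclusion reproduces
#'   the included counts in expectation.
#' @param seed integer master seed; per-cohort substreams are derived
#'   deterministically from it.
#' @return nested list with `cohorts`, `latent`, `links`, `outcome`,
#'   `seed` blocks.
#' @export
default_generator_config <- function(scale = c("included", "baseline"), seed = 20240610L) {
  scale <- match.arg(scale)
  base <- function(name, n_incl, n_base, miss, age_mean, age_sd, young, female, edu,
                   gait, gait_sd, mmse, mmse_sd, chronic, iadl, padl,
                   gait_miss = FALSE, unplanned_ok = TRUE) {
    list(name = name,
         n_baseline = if (scale == "included") n_incl else n_base,
         indicator_missing_rate = if (scale == "included") 0 else miss,
         age_mean = age_mean, age_sd = age_sd, age_min = 60,
         age_young_frac = young,  # published share aged < 78
         female_frac = female, education_probs = edu / sum(edu),
         gait_mean = gait, gait_sd = gait_sd,
         mmse_mean = mmse, mmse_sd = mmse_sd,
         chronic_mean = chronic,
         iadl_mean = iadl, padl_mean = padl,
         gait_systematically_missing = gait_miss,
         admissions_unplanned_distinguishable = unplanned_ok)
  }
  # item-level missing rates solve (1 - r)^n_items = included/baseline,
  # with 4 exclusion-relevant items for the gait-missing cohort (its gait
  # is imputed before harmonization and never triggers exclusion)
  cohorts <- list(
    snac_k   = base("snac_k",   3096L, 3363L, 1 - (3096 / 3363)^(1 / 5),
                    74.0, 10.9, 0.549, 0.641, c(0.170, 0.494, 0.336),
                    1.0, 0.5, 27.8, 4.3, 4.0, 0.7, 0.2),
    snac_b   = base("snac_b",   1228L, 1402L, 1 - (1228 / 1402)^(1 / 4),
                    75.9, 10.0, 0.442, 0.576, c(0.568, 0.322, 0.110),
                    1.0, 0.4, 26.3, 4.6, 2.8, 1.0, 0.2,
                    gait_miss = TRUE, unplanned_ok = FALSE),
    snac_gas = base("snac_gas", 2390L, 2931L, 1 - (2390 / 2931)^(1 / 5),
                    71.1, 9.7, 0.674, 0.541, c(0.383, 0.428, 0.190),
                    1.3, 0.3, 26.9, 2.8, 4.7, 0.5, 0.1),
    snac_n   = base("snac_n",   588L,  766L,  1 - (588 / 766)^(1 / 5),
                    74.4, 9.7, 0.517, 0.529, c(0.760, 0.190, 0.050),
                    0.9, 0.3, 28.3, 3.0, 2.1, 0.9, 0.1)
  )
  list(
    cohorts = cohorts,
    latent = list(age_ref = 73.4, theta_age_slope = -0.05, theta_sd = 0.8),
    links = list(
      gait_loading = 0.30, gait_noise_floor = 0.10,
      nonwalker_intercept = -5.5, nonwalker_slope = 2.0,
      mmse_loading = 0.70, mmse_noise_floor = 0.30,
      chronic_loading = 0.35, chronic_size = 20,
      iadl_slope = 2.0, padl_slope = 2.5,
      adl_person_sd = 0.6  # shared frailty heterogeneity beyond theta
    ),
    outcome = list(
      # Gompertz log-hazard: intercept + age + frailty terms + gamma * t;
      # intercept and gamma calibrated to pooled 1-year and 16-year
      # mortality (2.5% / 51.2%), see calibrate_outcome_params()
      gompertz_intercept = -4.7411, gompertz_age_coef = 0.085,
      theta_hazard_coef = 0.8, gompertz_shape = 0.1624,
      followup_censor_years = 16,
      # annual admission probability on the logit scale, calibrated so the
      # pooled 1-year unplanned rate is ~15.5% (the printed pooled 18.7%
      # includes one cohort's undistinguishable planned admissions)
      admission_logit_intercept = -1.8369, admission_age_coef = 0.02,
      admission_theta_coef = -0.6,
      planned_admission_annual_rate = 0.18
    ),
    seed = as.integer(seed)
  )
}

# validate config, naming the offending field
.validate_generator_config <- function(config) {
  if (is.null(config$cohorts) || !length(config$cohorts)) {
    stop("generator config: 'cohorts' must be a non-empty list", call. = FALSE)
  }
  for (cb in config$cohorts) {
    nm <- cb$name %||% "<unnamed>"
    if (is.null(cb$n_baseline) || cb$n_baseline <= 0) {
      stop(sprintf("cohort '%s': field 'n_baseline' must be > 0", nm), call. = FALSE)
    }
    .assert_prob(cb$female_frac, paste0(nm, ":female_frac"))
    .assert_prob(cb$indicator_missing_rate, paste0(nm, ":indicator_missing_rate"))
    if (abs(sum(cb$education_probs) - 1) > 1e-8 || any(cb$education_probs < 0)) {
      stop(sprintf("cohort '%s': field 'education_probs' must be a probability 3-vector summing to 1", nm),
           call. = FALSE)
    }
    .assert_pos(cb$age_sd, paste0(nm, ":age_sd"))
  }
  if ((config$outcome$followup_censor_years %||% 16) <= 0) {
    stop("outcome config: field 'followup_censor_years' must be > 0", call. = FALSE)
  }
  invisible(config)
}

# per-cohort latent moments implied by the age calibration targets
.theta_moments <- function(cohort, latent) {
  mu <- latent$theta_age_slope * (cohort$age_mean - latent$age_ref)
  sd <- sqrt(latent$theta_age_slope^2 * cohort$age_sd^2 + latent$theta_sd^2)
  list(mu = mu, sd = sd)
}

# solve a in  size * E[plogis(a - b*theta)] = target  over theta ~ N(mu, sd)
.solve_binom_intercept <- function(target, size, slope, mu, sd, qd = gauss_hermite(41L)) {
  th <- mu + sd * qd$nodes
  f <- function(a) size * sum(qd$weights * stats::plogis(a - slope * th)) - target
  stats::uniroot(f, c(-30, 30), tol = 1e-10)$root
}

# ---- cohort generation ---------------------------------------------------

#' Generate baseline records for one synthetic cohort
#'
#' Draws age (lower-truncated normal moment-matched to the cohort's target
#' mean/SD), sex, education, a latent health factor theta declining with
#' age, and the five health indicators from theta-linked models: log-normal
#' gait speed (with a small exact-zero non-walker fraction), a log-normal
#' MMSE deficit, a negative-binomial chronic disease count, and binomial
#' I-ADL/P-ADL counts with the P-ADL link steeper and more extreme than the
#' I-ADL one.  Link intercepts are solved from the cohort's calibration
#' targets, so marginal means track the configured values.
#'
#' The returned table carries theta in a `.theta` column consumed by
#' [generate_outcomes()]; it is dropped by [write_cohort_csv()].
#'
#' @param config generator configuration, see [default_generator_config()].
#' @param cohort_name name of a cohort block in `config$cohorts`.
#' @return data.frame with one row per participant.
#' @export
generate_cohort <- function(config, cohort_name) {
  .validate_generator_config(config)
  cb <- config$cohorts[[cohort_name]]
  if (is.null(cb)) stop(sprintf("unknown cohort name '%s'", cohort_name), call. = FALSE)
  set.seed(.sub_seed(config$seed, paste0("cohort:", cohort_name)))
  n <- as.integer(cb$n_baseline)
  lat <- config$latent; lk <- config$links

  # age: two-component truncated-normal mixture whose weight reproduces
  # the published < 78 share and whose moments match the published mean/SD
  mix <- .age_mixture_solve(cb$age_mean, cb$age_sd, cb$age_young_frac)
  young <- stats::runif(n) < cb$age_young_frac
  age <- numeric(n)
  age[young] <- .rtnorm_ab(sum(young), mix$mu_young, mix$s, mix$lower, mix$brk)
  age[!young] <- .rtnorm_ab(sum(!young), mix$mu_old, mix$s, mix$brk, mix$upper)
  sex <- ifelse(stats::runif(n) < cb$female_frac, "female", "male")
  education <- sample(c("primary", "high_school", "university"), n,
                      replace = TRUE, prob = cb$education_probs)
  theta <- lat$theta_age_slope * (age - lat$age_ref) + stats::rnorm(n, 0, lat$theta_sd)
  tm <- .theta_moments(cb, lat)

  # gait speed: log-normal in theta, exact zeros for non-walkers; the
  # residual log-noise is solved per cohort from the published gait SD
  # (log-normal CV identity), floored for degenerate targets
  sig2_g <- log(1 + (cb$gait_sd / cb$gait_mean)^2)
  noise_g <- sqrt(max(sig2_g - (lk$gait_loading * tm$sd)^2, lk$gait_noise_floor^2))
  sig2_g <- (lk$gait_loading * tm$sd)^2 + noise_g^2
  p_nw <- stats::plogis(lk$nonwalker_intercept - lk$nonwalker_slope * theta)
  mu_g <- log(cb$gait_mean / (1 - mean(p_nw))) - lk$gait_loading * tm$mu - sig2_g / 2
  gait <- exp(mu_g + lk$gait_loading * theta + stats::rnorm(n, 0, noise_g))
  gait[stats::runif(n) < p_nw] <- 0
  gait <- round(gait, 2)

  # MMSE: 30 minus a log-normal deficit, clipped to [0, 30]; residual
  # noise solved per cohort from the published MMSE SD
  def_mean <- 30 - cb$mmse_mean
  sig2_m_target <- log(1 + (cb$mmse_sd / def_mean)^2)
  noise_m <- sqrt(max(sig2_m_target - (lk$mmse_loading * tm$sd)^2,
                      lk$mmse_noise_floor^2))
  sig2_m <- (lk$mmse_loading * tm$sd)^2 + noise_m^2
  mu_m <- log(def_mean) + lk$mmse_loading * tm$mu - sig2_m / 2
  deficit <- exp(mu_m - lk$mmse_loading * theta + stats::rnorm(n, 0, noise_m))
  mmse <- as.integer(pmax(0, pmin(30, 30 - round(deficit))))

  # chronic disease count: negative binomial, log-mean linear in theta
  mu_c <- log(cb$chronic_mean) + lk$chronic_loading * tm$mu -
    (lk$chronic_loading * tm$sd)^2 / 2
  lam <- exp(mu_c - lk$chronic_loading * theta)
  n_chronic <- as.integer(pmin(60, stats::rnbinom(n, size = lk$chronic_size, mu = lam)))

  # disability counts: binomial with a logistic link in a frailty index
  # (theta minus a shared person-level disability term, which fattens the
  # count tails and correlates I-ADL with P-ADL beyond theta); the P-ADL
  # link is steeper and its intercept more extreme, so severe disability
  # implies mild disability on average
  u <- stats::rnorm(n, 0, lk$adl_person_sd)
  sd_idx <- sqrt(tm$sd^2 + lk$adl_person_sd^2)
  a_i <- .solve_binom_intercept(cb$iadl_mean, 8, lk$iadl_slope, tm$mu, sd_idx)
  a_p <- .solve_binom_intercept(cb$padl_mean, 6, lk$padl_slope, tm$mu, sd_idx)
  iadl <- stats::rbinom(n, 8, stats::plogis(a_i - lk$iadl_slope * (theta - u)))
  padl <- stats::rbinom(n, 6, stats::plogis(a_p - lk$padl_slope * (theta - u)))

  data.frame(
    participant_id = sprintf("%s_%05d", cohort_name, seq_len(n)),
    cohort = cohort_name,
    age = round(age, 1),
    sex = sex,
    education = education,
    gait_speed = gait,
    mmse = mmse,
    n_chronic = n_chronic,
    iadl = as.integer(iadl),
    padl = as.integer(padl),
    death_time = NA_real_,
    death_event = NA_integer_,
    admit_1y = NA_integer_,
    admit_3y = NA_integer_,
    admissions_unplanned = 1L,
    gait_imputed = 0L,
    .theta = theta,
    stringsAsFactors = FALSE
  )
}

#' Attach simulated outcomes to a generated cohort
#'
#' Death times are drawn from a Gompertz hazard whose log is linear in age
#' and (negative) theta, administratively censored at the follow-up
#' horizon.  Hospital admissions are annual Bernoulli draws within the
#' first three follow-up years on a logistic scale in age and theta, with
#' exposure truncated at death, so `admit_1y == 1` implies `admit_3y == 1`.
#'
#' @param table cohort table produced by [generate_cohort()] (must retain
#'   the `.theta` column).
#' @param config generator configuration.
#' @return the table with `death_time`, `death_event`, `admit_1y`,
#'   `admit_3y` filled in.
#' @export
generate_outcomes <- function(table, config) {
  if (is.null(table$.theta)) {
    stop("table lacks the internal '.theta' column; outcomes can only be generated for tables from generate_cohort()",
         call. = FALSE)
  }
  oc <- config$outcome
  for (f in c("gompertz_intercept", "gompertz_age_coef", "theta_hazard_coef", "gompertz_shape")) {
    if (!is.finite(oc[[f]])) stop(sprintf("outcome config: field '%s' must be finite", f), call. = FALSE)
  }
  if (oc$gompertz_shape <= 0) {
    stop("outcome config: field 'gompertz_shape' must be > 0 (non-finite survival times otherwise)",
         call. = FALSE)
  }
  set.seed(.sub_seed(config$seed, paste0("outcomes:", table$cohort[1])))
  n <- nrow(table)
  lat <- config$latent
  horizon <- oc$followup_censor_years

  lam <- exp(oc$gompertz_intercept + oc$gompertz_age_coef * (table$age - lat$age_ref) -
               oc$theta_hazard_coef * table$.theta)
  g <- oc$gompertz_shape
  u <- stats::runif(n)
  t_death <- log(pmax(1 - g * log(u) / lam, 1)) / g  # inverse Gompertz CDF
  event <- as.integer(t_death <= horizon)
  table$death_time <- round(pmin(t_death, horizon), 3)
  # avoid zero survival times after rounding
  table$death_time[table$death_time <= 0] <- 0.001
  table$death_event <- event

  p_year <- stats::plogis(oc$admission_logit_intercept +
                            oc$admission_age_coef * (table$age - lat$age_ref) +
                            oc$admission_theta_coef * table$.theta)
  admit_y <- matrix(0L, n, 3)
  for (y in 1:3) {
    exposure <- pmin(1, pmax(0, table$death_time - (y - 1)))
    p_y <- 1 - (1 - p_year)^exposure
    admit_y[, y] <- as.integer(stats::runif(n) < p_y)
  }
  table$admit_1y <- admit_y[, 1]
  table$admit_3y <- as.integer(rowSums(admit_y) > 0)
  table
}

#' Inject the configured data defects into a cohort table
#'
#' Applies the two structural defects the analysis must cope with, plus
#' random item-level missingness: (1) in cohorts flagged
#' `gait_systematically_missing`, every gait value is set missing; (2) in
#' cohorts where unplanned admissions are not distinguishable, extra
#' planned-admission events are mixed into the admission indicators at the
#' configured annual rate and `admissions_unplanned` is set to 0;
#' (3) elsewhere, each of the five indicators is independently set missing
#' at `indicator_missing_rate`.
#'
#' @param table cohort table with outcomes.
#' @param config generator configuration.
#' @return the defected table.
#' @export
inject_defects <- function(table, config) {
  cb <- config$cohorts[[table$cohort[1]]]
  if (is.null(cb)) stop(sprintf("unknown cohort name '%s'", table$cohort[1]), call. = FALSE)
  set.seed(.sub_seed(config$seed, paste0("defects:", cb$name)))
  n <- nrow(table)

  if (isTRUE(cb$gait_systematically_missing)) {
    table$gait_speed <- NA_real_
  }

  if (!isTRUE(cb$admissions_unplanned_distinguishable)) {
    table$admissions_unplanned <- 0L
    rate <- config$outcome$planned_admission_annual_rate %||% 0
    for (y in 1:3) {
      exposure <- pmin(1, pmax(0, table$death_time - (y - 1)))
      extra <- as.integer(stats::runif(n) < (1 - (1 - rate)^exposure))
      if (y == 1) table$admit_1y <- pmax(table$admit_1y, extra)
      if (y <= 3) table$admit_3y <- pmax(table$admit_3y, extra)
    }
    table$admit_3y <- pmax(table$admit_3y, table$admit_1y)
  }

  r <- cb$indicator_missing_rate
  if (r > 0) {
    items <- c("gait_speed", "mmse", "n_chronic", "iadl", "padl")
    if (isTRUE(cb$gait_systematically_missing)) items <- setdiff(items, "gait_speed")
    for (it in items) {
      table[[it]][stats::runif(n) < r] <- NA
    }
  }
  table
}

#' Simulate all configured cohorts end to end
#'
#' Runs [generate_cohort()], [generate_outcomes()] and [inject_defects()]
#' for every cohort in the configuration, each on its own deterministic
#' seed substream, and returns the stacked table.
#'
#' @param config generator configuration.
#' @param keep_theta keep the internal `.theta` column (default `FALSE`).
#' @return combined cohort data.frame.
#' @export
simulate_cohorts <- function(config = default_generator_config(), keep_theta = FALSE) {
  .validate_generator_config(config)
  out <- lapply(names(config$cohorts), function(nm) {
    tb <- generate_cohort(config, nm)
    tb <- generate_outcomes(tb, config)
    inject_defects(tb, config)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  if (!keep_theta) res$.theta <- NULL
  res
}
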