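# Shared fixture builders; everything generated in code at test time.

# legal cohort table with no missing values
make_table <- function(n = 50, seed = 1, cohort = "test") {
  set.seed(seed)
  data.frame(
    participant_id = sprintf("%s_%04d", cohort, seq_len(n)),
    cohort = cohort,
    age = round(runif(n, 60, 95), 1),
    sex = sample(c("female", "male"), n, replace = TRUE),
    education = sample(c("primary", "high_school", "university"), n, replace = TRUE),
    gait_speed = round(pmax(0, rnorm(n, 1.0, 0.3)), 2),
    mmse = as.integer(pmin(30, pmax(0, round(rnorm(n, 27, 3))))),
    n_chronic = as.integer(pmin(60, rpois(n, 3))),
    iadl = as.integer(rbinom(n, 8, 0.1)),
    padl = as.integer(rbinom(n, 6, 0.03)),
    death_time = round(runif(n, 0.1, 16), 3),
    death_event = rbinom(n, 1, 0.4),
    admit_1y = rbinom(n, 1, 0.2),
    admit_3y = NA_integer_,
    admissions_unplanned = 1L,
    gait_imputed = 0L,
    stringsAsFactors = FALSE
  ) |> (\(tb) { tb$admit_3y <- as.integer(pmax(tb$admit_1y, rbinom(n, 1, 0.2))); tb })()
}

# simulate NRM responses from known item parameters
gen_nrm_data <- function(n, items, seed) {
  set.seed(seed)
  theta <- rnorm(n)
  resp <- sapply(items, function(p) {
    P <- category_prob(p$a, p$c, theta)
    cums <- t(apply(P, 1, cumsum))
    rowSums(runif(n) > cums)  # inverse-CDF draw, category codes 0..K-1
  })
  storage.mode(resp) <- "integer"
  attr(resp, "theta") <- theta
  resp
}

# canonical 5-item parameter set used across NRM tests
nrm_items_5 <- function() {
  list(
    list(a = c(-1.0, 0.2, 0.8), c = c(-0.3, 0.5, -0.2)),
    list(a = c(-0.7, 0.7), c = c(0.2, -0.2)),
    list(a = c(-1.2, -0.1, 1.3), c = c(-0.5, 0.6, -0.1)),
    list(a = c(-0.5, 0.0, 0.5), c = c(0.1, 0.2, -0.3)),
    list(a = c(-0.9, 0.9), c = c(-0.4, 0.4))
  )
}

# down-scaled generator config for fast end-to-end tests
scaled_config <- function(frac = 0.1, seed = 20240610L, scale = "included") {
  cfg <- default_generator_config(scale, seed = seed)
  for (nm in names(cfg$cohorts)) {
    cfg$cohorts[[nm]]$n_baseline <-
      max(60L, as.integer(round(cfg$cohorts[[nm]]$n_baseline * frac)))
  }
  cfg
}

# exhaustive enumeration of category profiles for a hat model
enumerate_profiles <- function(model) {
  Ks <- vapply(model$weights, length, 0L)
  expand.grid(lapply(Ks, function(K) 0:(K - 1L)), KEEP.OUT.ATTRS = FALSE)
}

# raw score + hat for a category profile (independent of score_hat's path)
profile_hat <- function(model, profile) {
  raw <- sum(vapply(seq_along(model$weights),
                    function(i) model$weights[[i]][profile[[i]] + 1L], 0))
  10 * (raw - model$min_raw) / (model$max_raw - model$min_raw)
}
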