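test_that("AUC equals the exhaustive pairwise concordance oracle", {
  set.seed(50)
  n <- 200
  score <- rnorm(n)
  score[sample(n, 20)] <- score[sample(n, 20)]  # inject ties
  y <- rbinom(n, 1, plogis(-0.5 + score))
  r <- auc_logistic(score, y, higher_risk = TRUE)
  cases <- score[y == 1]; ctrl <- score[y == 0]
  oracle <- (sum(outer(cases, ctrl, ">")) + 0.5 * sum(outer(cases, ctrl, "=="))) /
    (length(cases) * length(ctrl))
  expect_equal(r$estimate, oracle, tolerance = 1e-12)
  expect_true(r$ci_lo <= r$estimate && r$estimate <= r$ci_hi)
  expect_equal(r$metric, "AUC")
})

test_that("AUC is invariant to monotone transforms and handles separation", {
  set.seed(51)
  score <- rnorm(150); y <- rbinom(150, 1, plogis(score))
  a1 <- auc_logistic(score, y, higher_risk = TRUE)$estimate
  a2 <- auc_logistic(exp(3 * score), y, higher_risk = TRUE)$estimate
  expect_equal(a1, a2, tolerance = 1e-12)
  # perfectly separating score
  ysep <- as.integer(score > 0)
  r <- suppressWarnings(auc_logistic(score, ysep, higher_risk = TRUE))
  expect_equal(r$estimate, 1.0, tolerance = 1e-12)
  expect_error(auc_logistic(score, rep(1, 150)), "single class")
})

test_that("Harrell's C matches the brute-force usable-pair oracle", {
  set.seed(52)
  n <- 300
  score <- rnorm(n)
  score[1:30] <- score[31:60]  # score ties
  tt <- rexp(n, exp(0.7 * score))
  cens <- quantile(tt, 0.7)
  time <- round(pmin(tt, cens), 3)  # induces some tied times
  ev <- as.integer(tt <= cens)
  r <- harrell_c(score, time, ev, higher_risk = TRUE)
  conc <- ties <- usable <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    use <- (time[i] < time[j] && ev[i] == 1) || (time[j] < time[i] && ev[j] == 1) ||
      (time[i] == time[j] && ev[i] + ev[j] == 1)
    if (!use) next
    usable <- usable + 1
    hi <- if (time[i] < time[j] || (time[i] == time[j] && ev[i] == 1)) i else j
    lo <- if (hi == i) j else i
    if (score[hi] > score[lo]) conc <- conc + 1
    else if (score[hi] == score[lo]) ties <- ties + 1
  }
  expect_equal(r$estimate, (conc + 0.5 * ties) / usable, tolerance = 1e-12)
  expect_true(r$ci_lo <= r$estimate && r$estimate <= r$ci_hi)
})

test_that("Harrell's C hits the stated limits", {
  # no censoring, perfectly anti-concordant score vs time -> risk C = 1
  time <- 1:50 + 0
  score <- -time  # higher risk-score = shorter survival
  # the Cox fit itself cannot converge under perfect separation; only the
  # concordance value is under test here
  r <- suppressWarnings(harrell_c(score, time, rep(1L, 50), higher_risk = TRUE))
  expect_equal(r$estimate, 1.0, tolerance = 1e-12)
  # independent score -> C ~ 0.5
  set.seed(53)
  r0 <- harrell_c(rnorm(600), rexp(600), rbinom(600, 1, 0.8), higher_risk = TRUE)
  expect_lt(abs(r0$estimate - 0.5), 0.05)
  # C invariant to monotone transform
  set.seed(54)
  sc <- rnorm(200); tm <- rexp(200, exp(sc)); ev <- rbinom(200, 1, 0.9)
  expect_equal(harrell_c(sc, tm, ev, higher_risk = TRUE)$estimate,
               harrell_c(qlogis(plogis(sc)), tm, ev, higher_risk = TRUE)$estimate,
               tolerance = 1e-9)
  expect_error(harrell_c(sc, tm, rep(0L, 200)), "no events")
})

test_that("stratified validation partitions, skips and annotates correctly", {
  cfg <- scaled_config(0.3)
  tab <- simulate_cohorts(cfg)
  tab <- tab[complete.cases(tab[, c("mmse", "n_chronic", "iadl", "padl")]), ]
  score <- tab$mmse / 3 - tab$iadl + rnorm(nrow(tab), 0, 0.5)  # crude health score
  res <- stratified_validation(tab, score, outcomes = c("mort_1y", "mort_5y",
                                                        "time_to_death", "admit_1y"))
  expect_true(all(res$ci_lo <= res$estimate & res$estimate <= res$ci_hi))
  expect_true(all(res$estimate >= 0 & res$estimate <= 1))
  # age strata partition the overall sample
  ov <- res[res$outcome == "mort_5y" & res$stratum == "overall", ]
  ages <- res[res$outcome == "mort_5y" & grepl("^age", res$stratum), ]
  expect_equal(sum(ages$n), ov$n)
  # admissions rows carry the provenance note (snac_b mixes planned ones)
  adm <- res[res$outcome == "admit_1y", ]
  expect_true(all(grepl("planned", adm$note)))
  # a stratum with a single class is skipped and recorded
  tab2 <- tab[tab$sex == "female" | tab$death_event == 0, ]
  tab2$death_event[tab2$sex == "male"] <- 0L
  res2 <- stratified_validation(tab2, score[seq_len(nrow(tab2))],
                                outcomes = "mort_5y")
  expect_true(any(grepl("mort_5y/male", attr(res2, "skipped"))))
})

test_that("stratified AUC is lower where the association is weaker", {
  set.seed(55)
  n <- 4000
  tab <- make_table(n, seed = 55)
  tab$age <- runif(n, 60, 95)
  young <- tab$age < 78
  score <- rnorm(n)  # health-directed: higher = healthier (HAT convention)
  # association much stronger among the old
  lp <- -ifelse(young, 0.4, 1.4) * score - 2
  y5 <- rbinom(n, 1, plogis(lp))
  tab$death_event <- y5
  tab$death_time <- ifelse(y5 == 1, runif(n, 0.1, 5), 16)
  res <- stratified_validation(tab, score, outcomes = "mort_5y",
                               cohort = "sim")
  auc <- function(st) res$estimate[res$stratum == st]
  expect_lt(auc("age<78"), auc("overall"))
  expect_lt(auc("age<78"), auc("age>=78"))
})

test_that("reliability table is calibrated on self-generated outcomes", {
  set.seed(56)
  p <- runif(5000, 0.02, 0.6)
  y <- rbinom(5000, 1, p)  # outcomes drawn from the predictions themselves
  tab <- reliability_table(p, y)
  expect_equal(sum(tab$n), 5000)        # bins partition all records
  expect_true(all(abs(tab$mean_predicted - tab$observed_rate) <
                    3 * sqrt(tab$mean_predicted * (1 - tab$mean_predicted) / tab$n) + 0.02))
  # constant predictions collapse to a single occupied bin
  tc <- reliability_table(rep(0.3, 400), rbinom(400, 1, 0.3))
  expect_equal(nrow(tc), 1)
  expect_equal(tc$n, 400)
})
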