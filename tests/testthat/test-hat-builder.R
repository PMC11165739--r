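test_that("cutoff grid enumeration counts and deduplicates", {
  expect_equal(length(cutoff_grid()), 48)  # 3 x 2 x 2 x 2 x 2
  single <- lapply(default_cutoff_candidates(), function(l) l[1])
  expect_equal(length(cutoff_grid(single)), 1)
  dup <- default_cutoff_candidates()
  dup$mmse <- list(c(24, 28), c(24, 28))  # duplicate set collapses
  expect_equal(length(cutoff_grid(dup)), 24)
  bad <- default_cutoff_candidates(); bad$padl <- list()
  expect_error(cutoff_grid(bad), "empty candidate list")
  expect_error(indicator_cutoffs(gait = c(1.0, 0.6)), "strictly increasing")
})

test_that("a singleton grid selects itself with stability 1", {
  tb <- make_table(400, seed = 40)
  g <- cutoff_grid(lapply(default_cutoff_candidates(), function(l) l[1]))
  sel <- suppressWarnings(select_hat_model(g, tb, n_splits = 0, seed = 1))
  expect_s3_class(sel$model, "hat_model")
  expect_equal(sel$report$stability_fraction, 1.0)
  expect_equal(sel$report$winner, 1L)
})

test_that("the generating categorization outranks perturbed cut-offs", {
  # data whose raw indicators are drawn inside the bands of known cut-offs;
  # oracle = the generating thresholds themselves
  true_cand <- lapply(default_cutoff_candidates(), function(l) l[[1]])
  perturbed <- list(
    gait_speed = list(true_cand$gait_speed, c(0.2, 1.8)),
    mmse = list(true_cand$mmse, c(10, 15)),
    n_chronic = list(true_cand$n_chronic),
    iadl = list(true_cand$iadl),
    padl = list(true_cand$padl)
  )
  g <- cutoff_grid(perturbed)
  wins <- 0L
  n_seeds <- 11L
  for (s in seq_len(n_seeds)) {
    resp <- gen_nrm_data(1200, nrm_items_5()[c(1, 3, 4)], seed = 400 + s)
    tb <- make_table(1200, seed = 400 + s)
    # embed the generated categories into the raw scales at band midpoints
    tb$gait_speed <- c(0.3, 0.8, 1.2)[resp[, 1] + 1L]
    tb$mmse <- as.integer(c(20, 26, 29)[resp[, 2] + 1L])
    tb$n_chronic <- as.integer(c(6, 3, 1)[resp[, 3] + 1L])
    sel <- suppressWarnings(select_hat_model(g, tb, n_splits = 0, seed = s))
    wins <- wins + (sel$report$winner_label ==
                      hatkit:::.cutoff_label(cutoff_grid(lapply(true_cand, list))[[1]]))
  }
  expect_gt(wins, n_seeds / 2)
})

test_that("derive_weights gives near-equal weights to an uninformative item", {
  items <- nrm_items_5()
  items[[4]] <- list(a = c(-0.02, 0, 0.02), c = c(0, 0, 0))  # null item
  resp <- gen_nrm_data(4000, items, seed = 41)
  fit <- fit_nrm(resp)
  model <- derive_weights(fit, resp, cutoffs = indicator_cutoffs())
  spread_null <- diff(range(model$weights[[4]]))
  spread_strong <- diff(range(model$weights[[3]]))
  expect_lt(spread_null, 0.12)
  expect_gt(spread_strong, 5 * spread_null)
})

test_that("weights are monotone when fitted slopes are ordered", {
  resp <- gen_nrm_data(4000, nrm_items_5(), seed = 42)
  fit <- fit_nrm(resp)
  model <- derive_weights(fit, resp, cutoffs = indicator_cutoffs())
  for (i in seq_along(model$weights)) {
    if (!is.unsorted(fit$items[[i]]$a, strictly = TRUE)) {
      expect_true(!is.unsorted(model$weights[[i]]),
                  label = sprintf("item %d weights monotone", i))
    }
  }
})

test_that("adding a constant to one item's weights leaves HAT unchanged", {
  tb <- make_table(600, seed = 44)
  cuts <- indicator_cutoffs()
  resp <- categorize(tb, cuts)
  fit <- suppressWarnings(fit_nrm(resp))
  model <- derive_weights(fit, resp, cutoffs = cuts)
  shifted <- model
  shifted$weights[[2]] <- shifted$weights[[2]] + 3.7
  shifted$min_raw <- shifted$min_raw + 3.7
  shifted$max_raw <- shifted$max_raw + 3.7
  expect_equal(score_hat(shifted, tb), score_hat(model, tb), tolerance = 1e-12)
})

test_that("scoring endpoints, monotone degradation and serialization are exact", {
  cfg <- scaled_config(0.15)
  tab <- simulate_cohorts(cfg)
  tab <- tab[complete.cases(tab[, c("gait_speed", "mmse", "n_chronic", "iadl", "padl")]), ]
  cuts <- indicator_cutoffs()
  resp <- categorize(tab, cuts)
  fit <- fit_nrm(resp)
  model <- derive_weights(fit, resp, cutoffs = cuts)

  profiles <- enumerate_profiles(model)
  hats <- apply(profiles, 1, function(pr) profile_hat(model, as.list(pr)))
  expect_equal(max(hats), 10, tolerance = 1e-12)
  expect_equal(min(hats), 0, tolerance = 1e-12)

  # worsening one indicator by one category never raises the score when
  # the model's weights are monotone (exhaustive over adjacent profiles)
  monotone <- all(vapply(model$weights, function(w) !is.unsorted(w), TRUE))
  if (monotone) {
    for (r in seq_len(nrow(profiles))) {
      base <- as.list(profiles[r, ])
      h0 <- profile_hat(model, base)
      for (i in seq_along(base)) {
        if (base[[i]] > 0) {
          worse <- base; worse[[i]] <- worse[[i]] - 1L
          expect_lte(profile_hat(model, worse), h0 + 1e-12)
        }
      }
    }
  }

  # JSON round trip scores identically
  f <- withr::local_tempfile(fileext = ".json")
  write_hat_model(model, f)
  back <- read_hat_model(f)
  expect_equal(score_hat(back, tab), score_hat(model, tab), tolerance = 1e-12)

  # pure function: repeated calls identical
  expect_identical(score_hat(model, tab), score_hat(model, tab))
})

test_that("hierarchy report bands partition the scored sample", {
  cfg <- scaled_config(0.15)
  tab <- simulate_cohorts(cfg)
  tab <- tab[complete.cases(tab[, c("gait_speed", "mmse", "n_chronic", "iadl", "padl")]), ]
  cuts <- indicator_cutoffs()
  resp <- categorize(tab, cuts)
  model <- derive_weights(fit_nrm(resp), resp, cutoffs = cuts)
  rep <- check_hat_hierarchy(model, tab)
  expect_equal(sum(rep$bands$n), nrow(tab))
  expect_true(all(rep$bands$band == 0:9))
  # empty bands are reported, not errors
  expect_true(any(rep$bands$n >= 0))
})
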