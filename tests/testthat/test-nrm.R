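test_that("categorize maps boundaries and directions correctly", {
  tb <- make_table(6, seed = 30)
  tb$mmse <- c(30L, 23L, 24L, 28L, 0L, 29L)
  tb$gait_speed <- c(0, 0.6, 0.59, 1.0, 1.5, 0.3)
  tb$n_chronic <- c(0L, 2L, 5L, 1L, 7L, 3L)
  tb$iadl <- c(0L, 1L, 3L, 8L, 2L, 0L)
  tb$padl <- c(0L, 1L, 6L, 0L, 0L, 2L)
  cuts <- indicator_cutoffs()  # gait .6/1.0, mmse 24/28, chronic 2/5, iadl 1/3, padl 1
  r <- categorize(tb, cuts)
  expect_equal(r[, "mmse"], c(2L, 0L, 1L, 2L, 0L, 2L))       # >= threshold goes up
  expect_equal(r[, "gait_speed"], c(0L, 1L, 0L, 2L, 2L, 0L)) # non-walker in lowest
  expect_equal(r[, "n_chronic"], c(2L, 1L, 0L, 2L, 0L, 1L))  # reversed direction
  expect_equal(r[, "iadl"], c(2L, 1L, 0L, 0L, 1L, 2L))
  expect_equal(r[, "padl"], c(1L, 0L, 0L, 1L, 1L, 0L))
  tb$mmse[1] <- 31L
  expect_error(categorize(tb, cuts), "legal range")
})

test_that("category_prob is a proper, overflow-safe softmax", {
  p <- category_prob(c(0, 0, 0), c(0, 0, 0), c(-2, 0, 2))
  expect_equal(p, matrix(1 / 3, 3, 3), ignore_attr = TRUE)
  a <- c(-1.3, 0.4, 0.9); cc <- c(0.2, -0.1, -0.1)
  th <- seq(-6, 6, by = 0.5)
  P <- category_prob(a, cc, th)
  expect_equal(rowSums(P), rep(1, length(th)))
  expect_true(all(P > 0))
  # softmax limit: mass concentrates on argmax slope
  expect_gt(category_prob(a, cc, 50)[, 3], 1 - 1e-10)
  # overflow safety at |theta * a| ~ 700
  big <- category_prob(c(-7, 7), c(0, 0), 100)
  expect_equal(rowSums(big), 1)
  expect_false(anyNA(big))
})

test_that("NRM slopes recover 2PL discriminations on binary items", {
  # 2PL P(y=1) = plogis(s(theta - b)) equals an NRM with a2 - a1 = s
  set.seed(31)
  n <- 5000
  theta <- rnorm(n)
  slopes <- c(0.8, 1.4, 2.0, 1.0, 0.6)
  diffs <- c(-0.5, 0, 0.6, 0.3, -0.2)
  resp <- sapply(seq_along(slopes), function(i) {
    as.integer(runif(n) < plogis(slopes[i] * (theta - diffs[i])))
  })
  fit <- fit_nrm(resp)
  for (i in seq_along(slopes)) {
    est <- diff(fit$items[[i]]$a)
    expect_lt(abs(est - slopes[i]), 0.2)
  }
})

test_that("EM log-likelihood trace is monotone and identification holds", {
  resp <- gen_nrm_data(800, nrm_items_5(), seed = 32)
  fit <- fit_nrm(resp)
  expect_true(fit$converged)
  expect_false(is.unsorted(fit$trace))
  for (p in fit$items) {
    expect_lt(abs(sum(p$a)), 1e-8)
    expect_lt(abs(sum(p$c)), 1e-8)
  }
  expect_equal(sum(fit$quadrature$weights), 1, tolerance = 1e-12)
})

test_that("a constant item is collapsed without disturbing the others", {
  resp <- gen_nrm_data(700, nrm_items_5()[1:3], seed = 33)
  resp_plus <- cbind(resp, rep(2L, nrow(resp)))  # constant extra item
  # warns twice: category collapse, then the now-constant item
  expect_warning(expect_warning(fit_all <- fit_nrm(resp_plus), "collaps"),
                 "constant")
  fit_ref <- fit_nrm(resp)
  for (i in 1:3) {
    expect_equal(fit_all$items[[i]]$a, fit_ref$items[[i]]$a, tolerance = 1e-4)
  }
})

test_that("TCC and TIF have the stated forms and degeneracies", {
  resp <- gen_nrm_data(600, nrm_items_5(), seed = 34)
  fit <- fit_nrm(resp)
  th <- seq(-3, 3, by = 0.2)
  tcc <- nrm_tcc(fit, th); tif <- nrm_tif(fit, th)
  expect_equal(tcc$total, rowSums(tcc[, grep("^item", names(tcc))]))
  expect_equal(tif$total, rowSums(tif[, grep("^item", names(tif))]))
  expect_true(all(tif[, -1] >= -1e-12))
  # zero-slope item: flat TCC, zero TIF
  flat <- list(list(a = c(0, 0, 0), c = c(0.3, -0.1, -0.2)))
  fake <- fit; fake$items <- flat; fake$category_map <- list(0:2)
  expect_equal(diff(range(nrm_tcc(fake, th)$item1)), 0, tolerance = 1e-12)
  expect_equal(max(abs(nrm_tif(fake, th)$item1)), 0, tolerance = 1e-12)
})

test_that("TIF equals the numerical variance of the score function", {
  resp <- gen_nrm_data(500, nrm_items_5(), seed = 35)
  fit <- fit_nrm(resp)
  th <- seq(-3, 3, by = 0.25)
  tif <- nrm_tif(fit, th)
  p1 <- fit$items[[1]]
  oracle <- sapply(th, function(t) {
    eps <- 1e-5
    P0 <- category_prob(p1$a, p1$c, t)
    dl <- (log(category_prob(p1$a, p1$c, t + eps)) -
             log(category_prob(p1$a, p1$c, t - eps))) / (2 * eps)
    sum(P0 * dl^2)
  })
  expect_equal(tif$item1, oracle, tolerance = 1e-6)
})

test_that("EAP scoring behaves as posterior mean under the normal prior", {
  # all-uninformative items -> EAP equals the prior mean 0
  resp <- gen_nrm_data(200, nrm_items_5()[1:2], seed = 36)
  fit0 <- fit_nrm(resp)
  fit0$items <- lapply(fit0$items, function(p) list(a = p$a * 0, c = p$c * 0))
  e0 <- eap_score(fit0, resp)
  expect_equal(e0$theta, rep(0, nrow(resp)), tolerance = 1e-12)
  expect_equal(e0$sd, rep(1, nrow(resp)), tolerance = 1e-3)

  # EAP is monotone in an informative ordered item's category
  fit <- fit_nrm(gen_nrm_data(2000, nrm_items_5(), seed = 37))
  pats <- matrix(1L, 3, 5)
  pats[, 3] <- 0:2  # item 3 has ordered slopes
  e <- eap_score(fit, pats)$theta
  expect_true(all(diff(e) > 0))

  # quadrature EAP matches dense-grid numerical integration
  dense <- seq(-8, 8, length.out = 4001)
  w <- dnorm(dense); w <- w / sum(w)
  pat <- matrix(c(2L, 1L, 2L, 0L, 1L), 1)
  lik <- rep(1, length(dense))
  for (i in 1:5) {
    p <- fit$items[[i]]
    lik <- lik * category_prob(p$a, p$c, dense)[, pat[1, i] + 1L]
  }
  post <- lik * w / sum(lik * w)
  expect_equal(eap_score(fit, pat)$theta, sum(post * dense), tolerance = 1e-4)

  expect_error(eap_score(fit, matrix(c(9L, 1L, 1L, 1L, 1L), 1)), "unseen category")
})

test_that("fit_nrm warns on tiny samples and rejects missing responses", {
  resp <- gen_nrm_data(30, nrm_items_5()[1:2], seed = 38)
  expect_warning(fit_nrm(resp, max_iter = 50), "unstable")
  resp[1, 1] <- NA
  expect_error(fit_nrm(resp), "complete")
})
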