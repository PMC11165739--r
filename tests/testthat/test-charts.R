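test_that("bounded logit is a monotone bijection on the score scale", {
  y <- seq(0, 10, by = 0.25)
  h <- bounded_logit(y)
  expect_true(all(diff(h) > 0))
  expect_equal(bounded_logit_inv(h), y, tolerance = 1e-12)
  expect_equal(bounded_logit(5), 0, tolerance = 1e-12)  # midpoint symmetry
  expect_error(bounded_logit(10.5), "outside")
  expect_error(bounded_logit(-0.1), "outside")
})

test_that("the restricted cubic spline basis is natural and smooth", {
  knots <- c(65, 72, 80, 92)
  x <- seq(55, 105, by = 0.1)
  B <- rcs_basis(x, knots)
  expect_equal(ncol(B), 3)
  # second differences vanish outside the boundary knots (linearity)
  for (j in 1:3) {
    seg <- B[x < 64, j]
    expect_lt(max(abs(diff(diff(seg)))), 1e-8)
    seg2 <- B[x > 93, j]
    expect_lt(max(abs(diff(diff(seg2)))), 1e-8)
  }
  # continuity of value and first/second difference across each knot
  for (kn in knots) {
    i <- which.min(abs(x - kn))
    window <- B[(i - 3):(i + 3), , drop = FALSE]
    expect_true(all(is.finite(window)))
    expect_lt(max(abs(diff(diff(window[, 1])))), 1e-6)
  }
  expect_error(rcs_basis(x, c(70, 70, 70)), "3 distinct knots")
})

test_that("quantile curves recover empirical quantiles in a homogeneous stratum", {
  set.seed(80)
  n <- 6000
  tab <- data.frame(age = runif(n, 60, 100), sex = "all",
                    hat = pmin(10, pmax(0, rnorm(n, 7, 1.5))))
  cm <- fit_quantile_curves(tab, sex = "all", percentiles = c(5, 50, 95))
  pq <- predict_quantiles(cm, c(65, 75, 85, 95))
  emp <- quantile(tab$hat, c(0.05, 0.5, 0.95))
  expect_lt(max(abs(sweep(as.matrix(pq[, -1]), 2, emp))), 0.15)
  # coverage
  pa <- predict_quantiles(cm, tab$age)
  for (j in 1:3) {
    expect_lt(abs(mean(tab$hat < pa[, j + 1]) - c(.05, .5, .95)[j]), 0.02)
  }
  # non-crossing and strict interior
  grid <- predict_quantiles(cm, 60:100)
  expect_true(all(grid$p5 <= grid$p50 & grid$p50 <= grid$p95))
  expect_true(all(grid[, -1] > 0 & grid[, -1] < 10))
  expect_error(fit_quantile_curves(data.frame(age = 60:400, sex = "all",
                                              hat = rep(5, 341)), sex = "all"),
               "degenerate")
})

test_that("IRLS check-loss fit matches the LP-vertex oracle on small instances", {
  set.seed(81)
  ns <- 40
  x <- runif(ns); z <- rnorm(ns, 2 * x, 0.5)
  X <- cbind(1, x)
  for (p in c(0.25, 0.5, 0.9)) {
    beta <- hatkit:::.quantile_irls(X, z, p)
    obj <- function(b) sum(ifelse(z - X %*% b > 0, p, p - 1) * (z - X %*% b))
    best <- Inf  # enumerate lines through pairs of points = LP vertices
    for (i in 1:(ns - 1)) for (j in (i + 1):ns) {
      if (x[i] == x[j]) next
      sl <- (z[j] - z[i]) / (x[j] - x[i])
      o <- obj(c(z[i] - sl * x[i], sl))
      if (o < best) best <- o
    }
    expect_lt((obj(beta) - best) / best, 1e-3)
  }
  # intercept-only model recovers the sample quantile
  Xi <- matrix(1, ns, 1)
  b50 <- hatkit:::.quantile_irls(Xi, z, 0.5)
  expect_equal(as.numeric(b50), median(z), tolerance = 0.02)
})

test_that("risk surface respects bounds, consistency and generating signs", {
  cfg <- scaled_config(0.4)
  tab <- generate_outcomes(generate_cohort(cfg, "snac_k"), cfg)
  hat <- pmin(10, pmax(0, 5 + 2.5 * tab$.theta))  # monotone proxy score
  y5 <- as.integer(tab$death_event == 1 & tab$death_time <= 5)
  rs <- fit_risk_surface(tab, y5, hat)
  expect_true(all(rs$grid$risk >= 0 & rs$grid$risk <= 1))
  # direct prediction at a grid node equals the grid value
  node <- rs$grid[1000, ]
  Xn <- cbind(1, rcs_basis(node$age, rs$knots), node$hat)
  expect_equal(drop(plogis(Xn %*% rs$coefficients)), node$risk, tolerance = 1e-12)
  # risk rises with age at fixed HAT, falls with HAT at fixed age
  sub <- rs$grid[rs$grid$hat == 5, ]
  sub <- sub[order(sub$age), ]
  expect_gt(sub$risk[nrow(sub) - 5], sub$risk[5])
  sub2 <- rs$grid[rs$grid$age == 80, ]
  sub2 <- sub2[order(sub2$hat), ]
  expect_lt(sub2$risk[nrow(sub2)], sub2$risk[1])
  expect_error(fit_risk_surface(tab, rep(0L, nrow(tab)), hat), "both classes")
})

test_that("render_chart exports deterministic CSVs that equal predictions", {
  set.seed(82)
  n <- 1500
  tab <- data.frame(age = runif(n, 60, 95), sex = "all",
                    hat = pmin(10, pmax(0, rnorm(n, 7 - 0.03 * (runif(n, 60, 95) - 60), 1.2))))
  cm <- fit_quantile_curves(tab, sex = "all")
  d1 <- withr::local_tempdir()
  f1 <- render_chart(cm, NULL, file.path(d1, "a"), png_plot = FALSE)
  f2 <- render_chart(cm, NULL, file.path(d1, "b"), png_plot = FALSE)
  expect_identical(readLines(f1[1]), readLines(f2[1]))
  exported <- utils::read.csv(f1[1])
  direct <- predict_quantiles(cm, exported$age)
  expect_equal(as.matrix(exported[, -1]), as.matrix(direct[, -1]),
               tolerance = 1e-10, ignore_attr = TRUE)
  # PNG render path also works
  f3 <- render_chart(cm, NULL, file.path(d1, "c"), png_plot = TRUE)
  expect_true(file.exists(f3[length(f3)]))
})
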