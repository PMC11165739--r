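# HAT-based geriatric charts: percentile curves of HAT versus age by sex
# via logistic quantile regression on a restricted cubic spline basis,
# plus an outcome-risk surface for contour overlays.

#' Bounded logit transform and its inverse
#'
#' `h(y) = log((y - L + eps) / (U - y + eps))`, strictly increasing on
#' \[L, U\]; the epsilon keeps the boundaries finite.
#'
#' @param y values in \[L, U\] (`bounded_logit`) or any reals
#'   (`bounded_logit_inv`).
#' @param L,U scale bounds (defaults 0 and 10, the HAT scale).
#' @param eps boundary epsilon (default 0.01).
#' @return transformed values; the inverse is exact up to the epsilon
#'   mapping.
#' @export
bounded_logit <- function(y, L = 0, U = 10, eps = 0.01) {
  if (any(y < L | y > U, na.rm = TRUE)) {
    stop(sprintf("values outside [%g, %g]", L, U), call. = FALSE)
  }
  log((y - L + eps) / (U - y + eps))
}

#' @rdname bounded_logit
#' @export
bounded_logit_inv <- function(y, L = 0, U = 10, eps = 0.01) {
  e <- exp(y)
  (e * (U + eps) + L - eps) / (1 + e)
}

#' Restricted (natural) cubic spline basis
#'
#' Harrell's truncated-power parameterization: for `k` knots the basis has
#' `k - 1` columns (the linear term plus `k - 2` nonlinear terms) and is
#' linear beyond the boundary knots.
#'
#' @param x numeric vector.
#' @param knots strictly increasing knot positions (>= 3 distinct).
#' @return matrix with `length(knots) - 1` columns.
#' @export
rcs_basis <- function(x, knots) {
  knots <- sort(unique(knots))
  k <- length(knots)
  if (k < 3L) stop("need at least 3 distinct knots", call. = FALSE)
  t1 <- knots[1]; tk <- knots[k]; tk1 <- knots[k - 1]
  scale2 <- (tk - t1)^2
  cub <- function(u) pmax(u, 0)^3
  B <- matrix(0, length(x), k - 1L)
  B[, 1] <- x
  for (j in seq_len(k - 2L)) {
    tj <- knots[j]
    B[, j + 1L] <- (cub(x - tj) -
                      cub(x - tk1) * (tk - tj) / (tk - tk1) +
                      cub(x - tk) * (tk1 - tj) / (tk - tk1)) / scale2
  }
  colnames(B) <- c("lin", paste0("rcs", seq_len(k - 2L)))
  B
}

# smoothed check-loss (pinball) minimization by IRLS with a decreasing
# smoothing floor; returns coefficients for design X (with intercept)
.quantile_irls <- function(X, z, p, eps_seq = c(1, 0.1, 0.01, 0.001),
                           max_iter = 100L, tol = 1e-10) {
  beta <- qr.coef(qr(X), z)  # LS start
  beta[is.na(beta)] <- 0
  for (eps in eps_seq) {
    for (it in seq_len(max_iter)) {
      r <- z - drop(X %*% beta)
      w <- ifelse(r > 0, p, 1 - p) / pmax(abs(r), eps)
      fit <- stats::lm.wfit(X, z, w)
      new_beta <- fit$coefficients
      new_beta[is.na(new_beta)] <- 0
      if (max(abs(new_beta - beta)) < tol) { beta <- new_beta; break }
      beta <- new_beta
    }
  }
  beta
}

.check_loss <- function(r, p) sum(ifelse(r > 0, p * r, (p - 1) * r))

#' Fit HAT percentile curves for one sex stratum
#'
#' HAT scores are mapped through the bounded logit, each requested
#' percentile is fitted by check-loss (pinball) minimization on a
#' restricted cubic spline basis in age (IRLS with smoothing parameter
#' driven to zero), and predictions are back-transformed.  Percentile
#' curves are monotonized across percentiles at each age by rearrangement,
#' so they never cross; all predictions lie strictly inside (0, 10).
#'
#' @param table cohort data.frame with a `hat` column (or supply `hat`).
#' @param sex `"female"`, `"male"`, or `"all"`.
#' @param percentiles percentile levels in (0, 100).
#' @param knots age knot positions; default at the 5th/35th/65th/95th age
#'   quantiles of the stratum.
#' @param hat optional numeric HAT vector overriding `table$hat`.
#' @param eps bounded-logit boundary epsilon.
#' @return object of class `chart_model`.
#' @export
fit_quantile_curves <- function(table, sex = "all",
                                percentiles = c(5, 10, 25, 50, 75, 90, 95),
                                knots = NULL, hat = NULL, eps = 0.01) {
  sel <- if (sex == "all") rep(TRUE, nrow(table)) else table$sex == sex
  age <- table$age[sel]
  y <- (hat %||% table$hat)[sel]
  if (length(y) < 200L) warning(sprintf("only %d records in stratum '%s'", length(y), sex))
  if (stats::sd(y) == 0) stop("degenerate HAT distribution (all values equal)", call. = FALSE)
  stopifnot(all(y >= 0 & y <= 10))
  knots <- knots %||% unname(stats::quantile(age, c(0.05, 0.35, 0.65, 0.95)))
  if (length(unique(knots)) < 3L) stop("need at least 3 distinct knots", call. = FALSE)
  z <- bounded_logit(y, eps = eps)
  X <- cbind(1, rcs_basis(age, knots))
  coefs <- vapply(percentiles / 100, function(p) .quantile_irls(X, z, p),
                  numeric(ncol(X)))
  loss <- vapply(seq_along(percentiles), function(j) {
    .check_loss(z - drop(X %*% coefs[, j]), percentiles[j] / 100)
  }, 0)
  structure(list(
    sex = sex, percentiles = percentiles, knots = knots, eps = eps,
    coefficients = coefs, check_loss = loss,
    age_range = range(age), n = length(y)
  ), class = "chart_model")
}

#' Predict percentile curves from a chart model
#'
#' Applies the fitted quantile coefficients on the spline basis,
#' back-transforms, and monotonizes across percentiles at each age
#' (rearrangement), guaranteeing non-crossing curves inside (0, 10).
#'
#' @param model `chart_model`.
#' @param ages numeric age grid.
#' @return data.frame with `age` and one `p<q>` column per percentile.
#' @export
predict_quantiles <- function(model, ages) {
  X <- cbind(1, rcs_basis(ages, model$knots))
  Z <- X %*% model$coefficients
  H <- bounded_logit_inv(Z, eps = model$eps)
  # monotone rearrangement across percentiles (columns already ordered)
  H <- t(apply(H, 1L, sort))
  H <- matrix(H, nrow = length(ages))
  out <- data.frame(age = ages, H)
  names(out) <- c("age", paste0("p", model$percentiles))
  out
}

#' Fit an outcome-risk surface over (age, HAT)
#'
#' Logistic regression of a binary outcome on a restricted cubic age
#' spline plus the HAT score, evaluated on a rectangular grid.  If the
#' fit separates (fitted probabilities numerically 0/1), it is refitted
#' with a small L2 penalty and a warning.
#'
#' @param table cohort data.frame.
#' @param outcome_flag binary outcome vector aligned with `table`.
#' @param hat HAT scores aligned with `table`.
#' @param age_grid,hat_grid grid axes (defaults span the data).
#' @param knots age spline knots (default as in [fit_quantile_curves()]).
#' @return object of class `risk_surface` with `grid` (long data.frame:
#'   `age`, `hat`, `risk`) and the model coefficients.
#' @export
fit_risk_surface <- function(table, outcome_flag, hat,
                             age_grid = NULL, hat_grid = seq(0, 10, by = 0.25),
                             knots = NULL) {
  keep <- !is.na(outcome_flag) & !is.na(hat)
  age <- table$age[keep]; y <- as.integer(outcome_flag[keep]); h <- hat[keep]
  if (length(unique(y)) < 2L) stop("outcome must have both classes", call. = FALSE)
  knots <- knots %||% unname(stats::quantile(age, c(0.05, 0.35, 0.65, 0.95)))
  X <- cbind(rcs_basis(age, knots), hat = h)
  dat <- data.frame(y = y, X)
  fit <- stats::glm(y ~ ., data = dat, family = stats::binomial())
  pr <- stats::fitted(fit)
  if (any(pr < 1e-10 | pr > 1 - 1e-10) || !fit$converged) {
    warning("possible separation; refitting with a small L2 penalty")
    Xi <- cbind(1, X)
    beta <- .ridge_logistic(Xi, y, lambda = 1e-3)
  } else {
    beta <- stats::coef(fit)
  }
  grid <- expand.grid(age = age_grid %||% seq(floor(min(age)), ceiling(max(age)), by = 1),
                      hat = hat_grid)
  Xg <- cbind(1, rcs_basis(grid$age, knots), grid$hat)
  grid$risk <- stats::plogis(drop(Xg %*% beta))
  structure(list(grid = grid, coefficients = beta, knots = knots),
            class = "risk_surface")
}

# Newton logistic regression with L2 penalty on non-intercept terms
.ridge_logistic <- function(X, y, lambda = 1e-3, max_iter = 100L) {
  beta <- rep(0, ncol(X))
  pen <- diag(c(0, rep(lambda, ncol(X) - 1L)))
  for (it in seq_len(max_iter)) {
    p <- stats::plogis(drop(X %*% beta))
    g <- crossprod(X, y - p) - pen %*% beta
    W <- p * (1 - p)
    H <- crossprod(X * W, X) + pen
    step <- solve(H, g)
    beta <- beta + drop(step)
    if (max(abs(step)) < 1e-10) break
  }
  beta
}

#' Render a geriatric chart and export its data
#'
#' Writes `<out_prefix>_percentiles.csv` (age grid x percentile
#' predictions), `<out_prefix>_risk.csv` (the risk surface grid, if
#' given), and `<out_prefix>.png` with percentile curves over filled risk
#' contours.  The CSVs are the single source of truth: the plot is drawn
#' from exactly those values.
#'
#' @param chart `chart_model`.
#' @param surface optional `risk_surface`.
#' @param out_prefix output path prefix.
#' @param ages age grid (default: integer ages spanning the fitted range).
#' @param png_plot write the PNG (set `FALSE` for data-only export).
#' @return invisible character vector of files written.
#' @export
render_chart <- function(chart, surface = NULL, out_prefix, ages = NULL,
                         png_plot = TRUE) {
  ages <- ages %||% seq(floor(chart$age_range[1]), ceiling(chart$age_range[2]), by = 1)
  pc <- predict_quantiles(chart, ages)
  files <- paste0(out_prefix, "_percentiles.csv")
  utils::write.csv(pc, files[1], row.names = FALSE)
  if (!is.null(surface)) {
    rf <- paste0(out_prefix, "_risk.csv")
    utils::write.csv(surface$grid, rf, row.names = FALSE)
    files <- c(files, rf)
  }
  if (png_plot) {
    pf <- paste0(out_prefix, ".png")
    grDevices::png(pf, width = 900, height = 700, res = 110)
    on.exit(grDevices::dev.off(), add = TRUE)
    plot(NA, xlim = range(pc$age), ylim = c(0, 10), xlab = "Age (years)",
         ylab = "HAT score",
         main = sprintf("HAT-based geriatric chart (%s)", chart$sex))
    if (!is.null(surface)) {
      zm <- with(surface$grid, tapply(risk, list(age, hat), mean))
      graphics::.filled.contour(as.numeric(rownames(zm)), as.numeric(colnames(zm)), zm,
                                levels = seq(0, 1, by = 0.1),
                                col = grDevices::hcl.colors(10, "YlOrRd", rev = TRUE, alpha = 0.5))
    }
    for (j in seq_along(chart$percentiles)) {
      graphics::lines(pc$age, pc[[j + 1L]], lwd = if (chart$percentiles[j] == 50) 2.5 else 1.2)
      graphics::text(max(pc$age), pc[[j + 1L]][nrow(pc)],
                     labels = paste0("P", chart$percentiles[j]), pos = 4, cex = 0.7, xpd = NA)
    }
    files <- c(files, pf)
  }
  invisible(files)
}
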