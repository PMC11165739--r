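# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Gauss-Hermite quadrature rescaled to the standard normal distribution
#'
#' Nodes and weights such that `sum(w * f(x))` approximates `E[f(Z)]` for
#' `Z ~ N(0, 1)`.  Computed by the Golub-Welsch eigenvalue method, so no
#' tables are embedded and any order is available.
#'
#' @param n number of quadrature nodes (default 41).
#' @return list with `nodes` and `weights`; weights sum to 1.
#' @export
gauss_hermite <- function(n = 41L) {
  stopifnot(n >= 1L)
  if (n == 1L) return(list(nodes = 0, weights = 1))
  off <- sqrt(seq_len(n - 1L) / 2)
  J <- matrix(0, n, n)
  J[cbind(seq_len(n - 1L), seq_len(n - 1L) + 1L)] <- off
  J[cbind(seq_len(n - 1L) + 1L, seq_len(n - 1L))] <- off
  e <- eigen(J, symmetric = TRUE)
  ord <- order(e$values)
  w <- e$vectors[1L, ord]^2
  # physicists' Hermite nodes x relate to N(0,1) nodes by sqrt(2) * x
  list(nodes = e$values[ord] * sqrt(2), weights = w / sum(w))
}

# deterministic 32-bit string hash (FNV-1a variant, kept < 2^31)
.str_hash <- function(s) {
  h <- 2166136261
  for (b in utf8ToInt(s)) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^31
  }
  as.integer(h %% 2^31)
}

# derive a reproducible sub-seed below 2^31 from a base seed and a label
.sub_seed <- function(seed, label) {
  as.integer((as.numeric(seed) * 7919 + .str_hash(label)) %% 2147483647)
}

.assert_prob <- function(x, name) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    stop(sprintf("'%s' must be a proportion in [0, 1]", name), call. = FALSE)
  }
  invisible(x)
}

.assert_pos <- function(x, name, strict = TRUE) {
  bad <- if (strict) any(!is.finite(x)) || any(x <= 0) else any(!is.finite(x)) || any(x < 0)
  if (bad) stop(sprintf("'%s' must be %s", name, if (strict) "> 0" else ">= 0"), call. = FALSE)
  invisible(x)
}

# quantile-function sampling from a normal truncated below at `lower`
.rtnorm_lower <- function(n, mean, sd, lower) {
  plo <- stats::pnorm(lower, mean, sd)
  u <- stats::runif(n, plo, 1)
  stats::qnorm(u, mean, sd)
}

# sampling from a normal truncated to [a, b]
.rtnorm_ab <- function(n, mean, sd, a, b) {
  pa <- stats::pnorm(a, mean, sd); pb <- stats::pnorm(b, mean, sd)
  stats::qnorm(stats::runif(n, pa, pb), mean, sd)
}

# mean / sd of a normal truncated to [a, b]
.tnorm_ab_moments <- function(mu, s, a, b) {
  al <- (a - mu) / s; be <- (b - mu) / s
  Z <- stats::pnorm(be) - stats::pnorm(al)
  d <- (stats::dnorm(al) - stats::dnorm(be)) / Z
  m <- mu + s * d
  v <- s^2 * (1 + (al * stats::dnorm(al) - be * stats::dnorm(be)) / Z - d^2)
  c(mean = m, sd = sqrt(max(v, 1e-12)))
}

# two-component truncated-normal age mixture: the young component lives on
# [60, break), the old on [break, upper), with mixture weight `frac_young`
# fixed to the published < 78 share; component locations are solved so the
# overall mean and SD match the published values
.age_mixture_solve <- function(target_mean, target_sd, frac_young,
                               brk = 78, lower = 60, upper = 105, s = 6) {
  obj <- function(p) {
    m1 <- .tnorm_ab_moments(p[1], s, lower, brk)
    m2 <- .tnorm_ab_moments(p[2], s, brk, upper)
    mean_mix <- frac_young * m1["mean"] + (1 - frac_young) * m2["mean"]
    ex2 <- frac_young * (m1["sd"]^2 + m1["mean"]^2) +
      (1 - frac_young) * (m2["sd"]^2 + m2["mean"]^2)
    sd_mix <- sqrt(max(ex2 - mean_mix^2, 1e-12))
    (mean_mix - target_mean)^2 + (sd_mix - target_sd)^2
  }
  fit <- stats::optim(c(target_mean - 5, target_mean + 10), obj,
                      method = "Nelder-Mead",
                      control = list(reltol = 1e-12, maxit = 2000))
  list(mu_young = fit$par[1], mu_old = fit$par[2], s = s,
       brk = brk, lower = lower, upper = upper)
}

# moment-match a lower-truncated normal: find (mu, sigma) such that the
# distribution truncated below at `lower` has the requested mean and sd
.tnorm_solve <- function(target_mean, target_sd, lower) {
  obj <- function(p) {
    mu <- p[1]; sg <- exp(p[2])
    a <- (lower - mu) / sg
    lam <- stats::dnorm(a) / (1 - stats::pnorm(a))
    m <- mu + sg * lam
    v <- sg^2 * (1 + a * lam - lam^2)
    (m - target_mean)^2 + (sqrt(v) - target_sd)^2
  }
  fit <- stats::optim(c(target_mean, log(target_sd)), obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-12, maxit = 2000))
  c(mean = fit$par[1], sd = exp(fit$par[2]))
}
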