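# Bock nominal response model (NRM), fitted from scratch by marginal
# maximum likelihood: EM with Gauss-Hermite quadrature under a standard
# normal latent prior.  Category k of item i has probability
#   P_k(theta) = exp(a_k * theta + c_k) / sum_l exp(a_l * theta + c_l),
# identified by sum-to-zero constraints over categories within each item.

# ---- cut-offs and categorization ----------------------------------------

#' Define per-indicator category cut-offs
#'
#' Thresholds are on the raw indicator scale and must be strictly
#' increasing.  `direction = "up"` means higher raw values are healthier
#' (gait speed, MMSE); `"down"` means lower raw values are healthier
#' (chronic disease count, I-ADL, P-ADL).  Category codes produced by
#' [categorize()] are always health-ordered with 0 = least healthy.
#'
#' @param gait,mmse,chronic,iadl,padl numeric threshold vectors.
#' @return object of class `indicator_cutoffs`.
#' @export
indicator_cutoffs <- function(gait = c(0.6, 1.0), mmse = c(24, 28),
                              chronic = c(2, 5), iadl = c(1, 3), padl = 1) {
  spec <- list(
    gait_speed = list(thresholds = gait, direction = "up"),
    mmse = list(thresholds = mmse, direction = "up"),
    n_chronic = list(thresholds = chronic, direction = "down"),
    iadl = list(thresholds = iadl, direction = "down"),
    padl = list(thresholds = padl, direction = "down")
  )
  for (nm in names(spec)) {
    th <- spec[[nm]]$thresholds
    if (length(th) < 1 || is.unsorted(th, strictly = TRUE)) {
      stop(sprintf("'%s': thresholds must be strictly increasing (K >= 2 categories)", nm),
           call. = FALSE)
    }
    spec[[nm]]$n_categories <- length(th) + 1L
  }
  structure(spec, class = "indicator_cutoffs")
}

#' Categorize the five indicators into health-ordered codes
#'
#' Mapping is deterministic with the half-open convention: a value equal
#' to a threshold falls in the upper raw bin.  Codes are re-oriented so
#' that 0 is always the least healthy category (non-walkers with gait 0
#' always land in gait category 0).
#'
#' @param table cohort data.frame with complete indicators.
#' @param cutoffs [indicator_cutoffs()] object.
#' @return integer matrix (participants x 5), columns named by indicator.
#' @export
categorize <- function(table, cutoffs) {
  stopifnot(inherits(cutoffs, "indicator_cutoffs"))
  out <- matrix(NA_integer_, nrow(table), length(cutoffs),
                dimnames = list(NULL, names(cutoffs)))
  for (nm in names(cutoffs)) {
    x <- table[[nm]]
    if (anyNA(x)) stop(sprintf("'%s' has missing values; categorize requires complete indicators", nm),
                       call. = FALSE)
    rng <- switch(nm, gait_speed = c(0, Inf), mmse = c(0, 30),
                  n_chronic = c(0, 60), iadl = c(0, 8), padl = c(0, 6))
    if (any(x < rng[1] | x > rng[2])) {
      stop(sprintf("'%s' outside legal range [%g, %g]", nm, rng[1], rng[2]), call. = FALSE)
    }
    raw <- findInterval(x, cutoffs[[nm]]$thresholds)  # value >= threshold goes up
    K <- cutoffs[[nm]]$n_categories
    out[, nm] <- if (cutoffs[[nm]]$direction == "up") raw else (K - 1L) - raw
  }
  out
}

# ---- category probabilities ---------------------------------------------

#' Nominal-model category probabilities
#'
#' Overflow-safe softmax `P_k(theta) proportional to exp(a_k theta + c_k)`.
#'
#' @param a,c numeric vectors of category slopes and intercepts (same
#'   length K >= 1).
#' @param theta numeric vector of latent trait values.
#' @return matrix `length(theta) x K`; rows sum to 1.
#' @export
category_prob <- function(a, c, theta) {
  stopifnot(length(a) == length(c), all(is.finite(theta)))
  eta <- outer(theta, a) + matrix(c, length(theta), length(a), byrow = TRUE)
  eta <- eta - apply(eta, 1L, max)
  e <- exp(eta)
  e / rowSums(e)
}

# ---- EM fitting ----------------------------------------------------------

# per-item M-step: weighted multinomial logit by Newton iterations.
# N is a Q x K matrix of expected counts at the quadrature nodes.
.nrm_mstep <- function(N, theta_q, a, c, ridge = 1e-8, max_newton = 50L) {
  K <- ncol(N); rq <- rowSums(N)
  if (K < 2L) return(list(a = 0, c = 0))
  for (nw in seq_len(max_newton)) {
    P <- category_prob(a, c, theta_q)
    G <- N - rq * P
    grad <- c(colSums(theta_q * G)[-1L], colSums(G)[-1L])
    Kf <- K - 1L
    H <- matrix(0, 2L * Kf, 2L * Kf)
    for (k in 2L:K) for (l in 2L:K) {
      wkl <- rq * P[, k] * ((k == l) - P[, l])
      H[k - 1L, l - 1L] <- sum(wkl * theta_q^2)
      H[Kf + k - 1L, Kf + l - 1L] <- sum(wkl)
      H[k - 1L, Kf + l - 1L] <- H[Kf + k - 1L, l - 1L] <- sum(wkl * theta_q)
    }
    step <- tryCatch(solve(H + diag(ridge, 2L * Kf), grad),
                     error = function(e) rep(0, 2L * Kf))
    # dampen huge steps (can occur with near-empty categories)
    if (max(abs(step)) > 5) step <- step * 5 / max(abs(step))
    a[-1L] <- a[-1L] + step[seq_len(Kf)]
    c[-1L] <- c[-1L] + step[Kf + seq_len(Kf)]
    if (max(abs(step)) < 1e-10) break
  }
  list(a = a, c = c)
}

#' Fit a nominal response model by EM marginal maximum likelihood
#'
#' E-step computes each respondent's posterior over Gauss-Hermite nodes of
#' a standard normal prior; M-step refits each item's multinomial logit on
#' expected node counts by ridge-stabilized Newton iterations.  Categories
#' never observed in the data are collapsed out with a warning (the fit
#' records the mapping); convergence is declared when the relative change
#' in marginal log-likelihood drops below `tol`.
#'
#' @param responses integer matrix (respondents x items) of category codes
#'   starting at 0.
#' @param n_quadrature number of quadrature nodes (default 41).
#' @param tol relative log-likelihood convergence tolerance.
#' @param max_iter maximum EM iterations.
#' @param start optional list of per-item starting values (`a`, `c`).
#' @return object of class `nrm_fit`: `items` (centered slopes/intercepts),
#'   `loglik`, `trace`, `converged`, `quadrature`, `category_map`, `n`,
#'   `n_parameters`.
#' @export
fit_nrm <- function(responses, n_quadrature = 41L, tol = 1e-6,
                    max_iter = 500L, start = NULL) {
  responses <- as.matrix(responses)
  storage.mode(responses) <- "integer"
  if (anyNA(responses)) stop("responses must be complete", call. = FALSE)
  n <- nrow(responses); m <- ncol(responses)
  if (n < 50L) warning(sprintf("only %d respondents; NRM estimates will be unstable", n))

  # collapse unobserved categories, remember the mapping old -> new
  category_map <- vector("list", m)
  for (i in seq_len(m)) {
    obs <- sort(unique(responses[, i]))
    full <- 0L:max(obs)
    if (!identical(obs, full)) {
      warning(sprintf("item %d: collapsing unobserved categories (%s observed of 0..%d)",
                      i, paste(obs, collapse = ","), max(obs)))
    }
    category_map[[i]] <- obs
    responses[, i] <- match(responses[, i], obs) - 1L
  }
  K <- apply(responses, 2L, max) + 1L
  if (any(K < 2L)) {
    warning(sprintf("item(s) %s constant after collapsing; they carry no information",
                    paste(which(K < 2L), collapse = ",")))
  }

  qd <- gauss_hermite(n_quadrature)
  th <- qd$nodes; wq <- qd$weights; Q <- length(th)

  items <- vector("list", m)
  for (i in seq_len(m)) {
    if (!is.null(start) && length(start[[i]]$a) == K[i]) {
      items[[i]] <- start[[i]]; next
    }
    Ki <- K[i]
    freq <- tabulate(responses[, i] + 1L, Ki) / n
    items[[i]] <- list(a = if (Ki > 1) seq(-0.5, 0.5, length.out = Ki) else 0,
                       c = if (Ki > 1) log(pmax(freq, 1e-6)) - mean(log(pmax(freq, 1e-6))) else 0)
  }

  ll_old <- -Inf; trace <- numeric(0); converged <- FALSE
  Lw <- matrix(0, n, Q)
  for (it in seq_len(max_iter)) {
    Plist <- lapply(items, function(p) category_prob(p$a, p$c, th))
    Lw[] <- matrix(wq, n, Q, byrow = TRUE)
    for (i in seq_len(m)) {
      Lw <- Lw * t(Plist[[i]])[responses[, i] + 1L, , drop = FALSE]
    }
    rs <- rowSums(Lw)
    ll <- sum(log(rs))
    trace <- c(trace, ll)
    if (is.finite(ll_old) && abs(ll - ll_old) < tol * abs(ll)) { converged <- TRUE; break }
    ll_old <- ll
    R <- Lw / rs
    for (i in seq_len(m)) {
      if (K[i] < 2L) next
      Yoh <- matrix(0, n, K[i])
      Yoh[cbind(seq_len(n), responses[, i] + 1L)] <- 1
      N <- crossprod(R, Yoh)
      items[[i]] <- .nrm_mstep(N, th, items[[i]]$a, items[[i]]$c)
    }
  }
  if (!converged) warning(sprintf("EM did not converge in %d iterations", max_iter))

  # center to the sum-to-zero identification (leaves probabilities intact)
  items <- lapply(items, function(p) list(a = p$a - mean(p$a), c = p$c - mean(p$c)))
  structure(list(
    items = items,
    loglik = ll,
    trace = trace,
    converged = converged,
    quadrature = qd,
    category_map = category_map,
    n = n,
    n_parameters = sum(pmax(K - 1L, 0L) * 2L),
    responses_collapsed = responses
  ), class = "nrm_fit")
}

#' @export
print.nrm_fit <- function(x, ...) {
  cat(sprintf("Nominal response model: %d items, n = %d, logLik = %.2f (%s, %d EM iterations)\n",
              length(x$items), x$n, x$loglik,
              if (x$converged) "converged" else "NOT converged", length(x$trace)))
  invisible(x)
}

# ---- curves --------------------------------------------------------------

# map original category codes to collapsed codes used by the fit
.collapse_codes <- function(fit, responses) {
  responses <- as.matrix(responses)
  for (i in seq_along(fit$items)) {
    mapped <- match(responses[, i], fit$category_map[[i]]) - 1L
    if (anyNA(mapped)) {
      stop(sprintf("item %d: unseen category code in responses", i), call. = FALSE)
    }
    responses[, i] <- mapped
  }
  responses
}

#' Test characteristic curves
#'
#' Item TCC is the expected category score `sum_k k * P_k(theta)`; the
#' total curve is the sum over items.
#'
#' @param fit `nrm_fit` object.
#' @param theta_grid numeric grid of latent values.
#' @return data.frame with `theta`, one column per item, and `total`.
#' @export
nrm_tcc <- function(fit, theta_grid = seq(-4, 4, by = 0.1)) {
  vals <- vapply(fit$items, function(p) {
    P <- category_prob(p$a, p$c, theta_grid)
    drop(P %*% (seq_along(p$a) - 1))
  }, numeric(length(theta_grid)))
  vals <- matrix(vals, nrow = length(theta_grid),
                 dimnames = list(NULL, paste0("item", seq_along(fit$items))))
  data.frame(theta = theta_grid, vals, total = rowSums(vals))
}

#' Test information functions
#'
#' Item information under the nominal model is the theta-score variance
#' `sum_k P_k a_k^2 - (sum_k P_k a_k)^2`; always non-negative.
#'
#' @inheritParams nrm_tcc
#' @return data.frame with `theta`, one column per item, and `total`.
#' @export
nrm_tif <- function(fit, theta_grid = seq(-4, 4, by = 0.1)) {
  vals <- vapply(fit$items, function(p) {
    P <- category_prob(p$a, p$c, theta_grid)
    drop(P %*% p$a^2) - drop(P %*% p$a)^2
  }, numeric(length(theta_grid)))
  vals <- matrix(vals, nrow = length(theta_grid),
                 dimnames = list(NULL, paste0("item", seq_along(fit$items))))
  data.frame(theta = theta_grid, vals, total = rowSums(vals))
}

#' Expected a posteriori latent scores
#'
#' Posterior mean and SD of theta for each response pattern under the
#' standard normal prior, evaluated on the fit's quadrature grid.
#'
#' @param fit `nrm_fit` object.
#' @param responses integer category matrix on the original coding (codes
#'   are mapped through the fit's collapse map; unseen codes are an error).
#' @return data.frame with `theta` (EAP) and `sd` (posterior SD).
#' @export
eap_score <- function(fit, responses) {
  responses <- .collapse_codes(fit, responses)
  th <- fit$quadrature$nodes; wq <- fit$quadrature$weights
  n <- nrow(responses); Q <- length(th)
  Lw <- matrix(wq, n, Q, byrow = TRUE)
  for (i in seq_along(fit$items)) {
    p <- fit$items[[i]]
    Lw <- Lw * t(category_prob(p$a, p$c, th))[responses[, i] + 1L, , drop = FALSE]
  }
  R <- Lw / rowSums(Lw)
  eap <- drop(R %*% th)
  psd <- sqrt(pmax(drop(R %*% th^2) - eap^2, 0))
  data.frame(theta = eap, sd = psd)
}
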