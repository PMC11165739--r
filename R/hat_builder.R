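# HAT construction: candidate cut-off grid, NRM-based model selection with
# 10-split internal consistency, weight derivation by regressing EAP
# latent scores on item-category dummies, and the 0-10 rescale.

#' Default candidate cut-off lists (48-candidate grid)
#'
#' Candidates reflect common clinical thresholds: gait speed around the
#' 0.6/0.8/1.0/1.2 m/s frailty bands, MMSE cognitive-impairment cuts,
#' multimorbidity counts, and presence/extent of I-ADL and P-ADL
#' dependence.  3 x 2 x 2 x 2 x 2 = 48 candidates.
#'
#' @return named list of candidate threshold lists per indicator.
#' @export
default_cutoff_candidates <- function() {
  list(
    gait_speed = list(c(0.6, 1.0), c(0.5, 0.8), c(0.8, 1.2)),
    mmse = list(c(24, 28), c(26, 29)),
    n_chronic = list(c(2, 5), c(3, 6)),
    iadl = list(c(1, 3), c(1, 2)),
    padl = list(1, c(1, 3))
  )
}

#' Enumerate the Cartesian cut-off grid
#'
#' Duplicate threshold sets within an indicator are deduplicated; the grid
#' is the Cartesian product over indicators, each candidate an
#' [indicator_cutoffs()] object.
#'
#' @param candidates named list of per-indicator candidate threshold
#'   lists, as from [default_cutoff_candidates()].
#' @return object of class `cutoff_grid`: list of `indicator_cutoffs` with
#'   a `count` attribute.
#' @export
cutoff_grid <- function(candidates = default_cutoff_candidates()) {
  needed <- c("gait_speed", "mmse", "n_chronic", "iadl", "padl")
  if (!all(needed %in% names(candidates))) {
    stop("candidates must name all five indicators", call. = FALSE)
  }
  cand <- lapply(candidates[needed], function(lst) {
    if (!length(lst)) stop("empty candidate list for an indicator", call. = FALSE)
    lst[!duplicated(vapply(lst, paste, "", collapse = "|"))]
  })
  idx <- expand.grid(lapply(cand, seq_along), KEEP.OUT.ATTRS = FALSE)
  grid <- lapply(seq_len(nrow(idx)), function(r) {
    indicator_cutoffs(gait = cand$gait_speed[[idx[r, 1]]],
                      mmse = cand$mmse[[idx[r, 2]]],
                      chronic = cand$n_chronic[[idx[r, 3]]],
                      iadl = cand$iadl[[idx[r, 4]]],
                      padl = cand$padl[[idx[r, 5]]])
  })
  structure(grid, class = "cutoff_grid", count = length(grid))
}

# compact label for a candidate (also the lexicographic tie-break key)
.cutoff_label <- function(cutoffs) {
  paste(vapply(cutoffs, function(s) paste(s$thresholds, collapse = "/"), ""),
        collapse = " | ")
}

# selection criterion for one candidate on one dataset.  Likelihood-based
# criteria are not comparable across different categorizations of the same
# raw data (coarser/unbalanced splits get better BIC through lower marginal
# entropy alone), so the primary criterion is the mean total test
# information over theta in [-2, 2] (higher = the categorization retains
# more information about latent health); BIC and the lexicographic cut-off
# label break ties.
.evaluate_candidate <- function(cutoffs, table, n_quadrature, tol, max_iter,
                                start = NULL) {
  resp <- categorize(table, cutoffs)
  fit <- suppressWarnings(fit_nrm(resp, n_quadrature = n_quadrature,
                                  tol = tol, max_iter = max_iter,
                                  start = start))
  bic <- -2 * fit$loglik + fit$n_parameters * log(fit$n)
  grid_th <- seq(-2, 2, by = 0.1)
  tif_mean <- mean(nrm_tif(fit, grid_th)$total)
  list(fit = fit, bic = bic, tif_mean = tif_mean, converged = fit$converged)
}

# order candidates: TIF desc, BIC asc, label asc
.rank_candidates <- function(bic, tif_mean, labels) {
  order(-tif_mean, bic, labels)
}

#' Select the optimal HAT model over a cut-off grid
#'
#' Every candidate categorization is fitted with a nominal response model
#' on the full data and scored by its mean total test information over
#' theta in \[-2, 2\] (higher is better); ties are broken by lower BIC,
#' then by the candidate's lexicographic cut-off label.  (Likelihood-only
#' criteria are not comparable across categorizations — see the methods
#' vignette.)  The selection is then repeated on 10
#' random equal splits of the data and the stability fraction (share of
#' splits whose winner equals the full-data winner) recorded.  The final
#' model (cut-offs, per-category weights, 0-10 transform) is built from
#' the full-data fit via [derive_weights()].
#'
#' @param grid [cutoff_grid()] object.
#' @param table complete-case cohort data.frame.
#' @param n_splits number of internal-consistency splits (default 10).
#' @param seed integer seed for the split assignment.
#' @param n_quadrature,tol,max_iter NRM fitting controls (EM tolerance is
#'   relaxed on the small split samples only through `max_iter`).
#' @param progress print per-candidate progress.
#' @return list with `model` (a `hat_model`) and `report` (per-candidate
#'   criterion table, per-split winners, stability fraction).
#' @export
select_hat_model <- function(grid, table, n_splits = 10L, seed = 1L,
                             n_quadrature = 41L, tol = 1e-6, max_iter = 500L,
                             progress = FALSE) {
  stopifnot(inherits(grid, "cutoff_grid"), length(grid) >= 1L)
  labels <- vapply(grid, .cutoff_label, "")

  evals <- vector("list", length(grid))
  for (j in seq_along(grid)) {
    evals[[j]] <- .evaluate_candidate(grid[[j]], table, n_quadrature, tol, max_iter)
    if (progress) message(sprintf("[%d/%d] BIC %.1f  %s", j, length(grid),
                                  evals[[j]]$bic, labels[j]))
  }
  if (!any(vapply(evals, `[[`, TRUE, "converged"))) {
    stop("no candidate model converged; see per-candidate traces", call. = FALSE)
  }
  bic <- vapply(evals, `[[`, 0, "bic")
  tifm <- vapply(evals, `[[`, 0, "tif_mean")
  winner <- .rank_candidates(bic, tifm, labels)[1L]

  # split-sample internal consistency: rerun the selection on each split
  split_winners <- integer(0)
  if (n_splits >= 2L && nrow(table) >= 10L * n_splits) {
    set.seed(as.integer(seed))
    fold <- sample(rep_len(seq_len(n_splits), nrow(table)))
    # split refits warm-start from the full-data estimates and run on a
    # looser tolerance/iteration budget: they only need to re-rank
    # candidates, not converge deeply
    split_winners <- vapply(seq_len(n_splits), function(s) {
      sub <- table[fold == s, , drop = FALSE]
      sb <- st <- numeric(length(grid))
      for (j in seq_along(grid)) {
        ev <- tryCatch(
          .evaluate_candidate(grid[[j]], sub, n_quadrature,
                              max(tol, 1e-5), min(max_iter, 150L),
                              start = evals[[j]]$fit$items),
          error = function(e) list(bic = Inf, tif_mean = -Inf))
        sb[j] <- ev$bic; st[j] <- ev$tif_mean
      }
      .rank_candidates(sb, st, labels)[1L]
    }, integer(1))
  }
  stability <- if (length(split_winners)) mean(split_winners == winner) else 1.0

  fit <- evals[[winner]]$fit
  resp <- categorize(table, grid[[winner]])
  model <- derive_weights(fit, resp, cutoffs = grid[[winner]])
  model$provenance <- list(
    grid_size = length(grid), criterion = "mean total TIF on [-2,2] (BIC and lexicographic tie-breaks)",
    criterion_value = tifm[winner], stability_fraction = stability,
    n_splits = length(split_winners), seed = as.integer(seed), n = nrow(table)
  )
  report <- list(
    candidates = data.frame(label = labels, bic = bic, tif_mean = tifm,
                            converged = vapply(evals, `[[`, TRUE, "converged"),
                            stringsAsFactors = FALSE),
    winner = winner, winner_label = labels[winner],
    split_winners = split_winners, stability_fraction = stability
  )
  list(model = model, report = report)
}

#' Derive per-category weights and the 0-10 transform
#'
#' EAP latent health scores from the fitted nominal model are regressed by
#' least squares on the full set of item-category indicator variables
#' (reference category 0 per item absorbed; its weight is 0).  The raw
#' score of a profile is the sum of its category weights; the min/max over
#' the *theoretical* profile space define the affine map to \[0, 10\], so
#' both endpoints are attainable by construction.
#'
#' @param fit converged `nrm_fit`.
#' @param responses category matrix used for the fit (original codes).
#' @param cutoffs the `indicator_cutoffs` behind `responses`.
#' @return object of class `hat_model`.
#' @export
derive_weights <- function(fit, responses, cutoffs) {
  eap <- eap_score(fit, responses)$theta
  resp_c <- .collapse_codes(fit, responses)
  item_names <- colnames(resp_c) %||% paste0("item", seq_len(ncol(resp_c)))

  df <- as.data.frame(lapply(seq_len(ncol(resp_c)), function(i) {
    factor(resp_c[, i], levels = 0:(length(fit$items[[i]]$a) - 1L))
  }))
  names(df) <- item_names
  mm <- stats::model.matrix(~ ., data = df)
  ls_fit <- stats::lm.fit(mm, eap)
  coefs <- ls_fit$coefficients
  if (anyNA(coefs)) {
    warning("rank-deficient weight regression; aliased categories weighted 0")
    coefs[is.na(coefs)] <- 0
  }
  r2 <- 1 - sum(ls_fit$residuals^2) / sum((eap - mean(eap))^2)

  items <- item_names
  weights <- lapply(seq_along(items), function(i) {
    K <- length(fit$items[[i]]$a)
    w <- numeric(K)  # reference category 0
    for (k in 1:(K - 1)) {
      nm <- paste0(items[i], k)
      w[k + 1L] <- if (nm %in% names(coefs)) coefs[[nm]] else 0
    }
    w
  })
  names(weights) <- items

  min_raw <- sum(vapply(weights, min, 0))
  max_raw <- sum(vapply(weights, max, 0))
  structure(list(
    cutoffs = cutoffs,
    weights = weights,
    category_map = fit$category_map,
    min_raw = min_raw, max_raw = max_raw,
    r_squared = r2,
    nrm_items = fit$items,
    provenance = list()
  ), class = "hat_model")
}

#' @export
print.hat_model <- function(x, ...) {
  cat(sprintf("HAT model: raw range [%.3f, %.3f] mapped to [0, 10]; weight regression R^2 = %.3f\n",
              x$min_raw, x$max_raw, x$r_squared))
  for (nm in names(x$weights)) {
    cat(sprintf("  %-10s cuts {%s}  weights %s\n", nm,
                paste(x$cutoffs[[nm]]$thresholds, collapse = ", "),
                paste(sprintf("%.2f", x$weights[[nm]]), collapse = " ")))
  }
  invisible(x)
}

#' Score participants on the 0-10 HAT scale
#'
#' Pure function of (model, indicators): categorizes the five indicators
#' with the model's cut-offs, sums category weights and applies the
#' model's affine 0-10 transform.  The best theoretical profile scores
#' exactly 10, the worst exactly 0.
#'
#' @param model `hat_model`.
#' @param table cohort data.frame with complete indicators.
#' @param digits optional rounding (the published scale is reported to 1
#'   decimal); default `NULL` returns the continuous score.
#' @return numeric vector of HAT scores in \[0, 10\].
#' @export
score_hat <- function(model, table, digits = NULL) {
  resp <- categorize(table, model$cutoffs)
  # map through collapse map; categories unseen at fit time take the
  # nearest retained category's weight
  raw <- numeric(nrow(resp))
  for (i in seq_len(ncol(resp))) {
    map <- model$category_map[[i]]
    idx <- vapply(resp[, i], function(v) which.min(abs(map - v)), 0L)
    raw <- raw + model$weights[[i]][idx]
  }
  hat <- 10 * (raw - model$min_raw) / (model$max_raw - model$min_raw)
  if (!is.null(digits)) hat <- round(hat, digits)
  hat
}

#' Hierarchical-ordering report across HAT bands
#'
#' Splits scored participants into the integer bands \[0,1), ..., \[9,10\]
#' and tabulates the modal category of each indicator per band, flagging
#' whether ADL limitation dominates below HAT 5 and severe (P-ADL)
#' disability below HAT 3.
#'
#' @param model `hat_model`.
#' @param table complete-case cohort data.frame.
#' @return list with `bands` (modal categories and counts) and the two
#'   flags `adl_limited_below_5`, `severe_disability_below_3`.
#' @export
check_hat_hierarchy <- function(model, table) {
  hat <- score_hat(model, table)
  resp <- categorize(table, model$cutoffs)
  band <- pmin(floor(hat), 9)
  modal <- function(x) if (!length(x)) NA_integer_ else as.integer(names(which.max(table(x))))
  bands <- do.call(rbind, lapply(0:9, function(b) {
    sel <- band == b
    data.frame(band = b, n = sum(sel),
               t(vapply(colnames(resp), function(cn) modal(resp[sel, cn]), 0L)))
  }))
  below5 <- hat < 5; below3 <- hat < 3
  iadl_top <- max(resp[, "iadl"]); padl_top <- max(resp[, "padl"])
  list(
    bands = bands,
    adl_limited_below_5 = if (any(below5))
      mean(resp[below5, "iadl"] < iadl_top | resp[below5, "padl"] < padl_top) > 0.5 else NA,
    severe_disability_below_3 = if (any(below3))
      mean(resp[below3, "padl"] < padl_top) > 0.5 else NA
  )
}

# ---- serialization -------------------------------------------------------

#' Write / read a HAT model as JSON
#'
#' The JSON round trip is exact for scoring purposes: cut-offs, weights,
#' category maps and the raw-score range are preserved at full precision.
#'
#' @param model `hat_model`.
#' @param path JSON file path.
#' @export
write_hat_model <- function(model, path) {
  obj <- list(
    cutoffs = lapply(model$cutoffs, function(s) s[c("thresholds", "direction")]),
    weights = model$weights,
    category_map = model$category_map,
    min_raw = model$min_raw, max_raw = model$max_raw,
    r_squared = model$r_squared,
    nrm_items = model$nrm_items,
    provenance = model$provenance
  )
  # digits = I(17): decimal significand long enough for an exact IEEE-754
  # round trip (digits = NA stops at 15 and perturbs scores by ~1e-15)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17), pretty = TRUE)
  invisible(path)
}

#' @rdname write_hat_model
#' @export
read_hat_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cuts <- indicator_cutoffs(gait = unlist(obj$cutoffs$gait_speed$thresholds),
                            mmse = unlist(obj$cutoffs$mmse$thresholds),
                            chronic = unlist(obj$cutoffs$n_chronic$thresholds),
                            iadl = unlist(obj$cutoffs$iadl$thresholds),
                            padl = unlist(obj$cutoffs$padl$thresholds))
  structure(list(
    cutoffs = cuts,
    weights = lapply(obj$weights, as.numeric),
    category_map = lapply(obj$category_map, as.integer),
    min_raw = obj$min_raw, max_raw = obj$max_raw,
    r_squared = obj$r_squared,
    nrm_items = lapply(obj$nrm_items, function(p) list(a = as.numeric(p$a), c = as.numeric(p$c))),
    provenance = obj$provenance
  ), class = "hat_model")
}
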