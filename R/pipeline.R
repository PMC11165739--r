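# End-to-end pipeline: simulate -> impute -> harmonize -> build ->
# validate -> meta-analyze -> charts, with a fixed artifact layout and a
# checksummed manifest.

.default_run_config <- function() {
  list(
    generator = NULL,            # NULL -> default_generator_config(scale)
    generator_scale = "included",
    candidates = NULL,           # NULL -> default_cutoff_candidates()
    n_splits = 10L,
    seed = 20240610L,
    per_cohort_models = TRUE,
    leave_out = c("snac_b", "snac_k"),
    leave_out_roles = c(snac_b = "minus_imputed", snac_k = "minus_development"),
    strata_age_break = 78,
    charts_by_sex = TRUE,
    charts_png = FALSE,          # CSV is the canonical chart artifact
    outcomes = c("mort_1y", "mort_3y", "mort_5y", "time_to_death",
                 "admit_1y", "admit_3y")
  )
}

#' Validate and resolve a pipeline run configuration
#'
#' Accepts a config list or a JSON file path; fills documented defaults,
#' warns on unknown keys (forward compatibility), and collects all errors
#' before failing.
#'
#' @param config list or path to a JSON config file.
#' @return fully resolved config list.
#' @export
validate_run_config <- function(config = list()) {
  if (is.character(config)) {
    if (!file.exists(config)) stop(sprintf("config file not found: %s", config), call. = FALSE)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  def <- .default_run_config()
  unknown <- setdiff(names(config), names(def))
  if (length(unknown)) {
    warning(sprintf("unknown config key(s) ignored: %s", paste(unknown, collapse = ", ")))
  }
  cfg <- utils::modifyList(def, config[intersect(names(config), names(def))])
  errors <- character(0)
  if (is.null(cfg$seed) || !is.finite(cfg$seed)) errors <- c(errors, "field 'seed' must be set")
  if (!is.null(cfg$generator)) {
    ok <- tryCatch({ .validate_generator_config(cfg$generator); TRUE },
                   error = function(e) { errors <<- c(errors, conditionMessage(e)); FALSE })
  }
  gen <- cfg$generator %||% default_generator_config(cfg$generator_scale, seed = cfg$seed)
  bad <- setdiff(cfg$leave_out, names(gen$cohorts))
  if (length(bad)) {
    errors <- c(errors, sprintf("leave_out names cohort(s) not generated: %s",
                                paste(bad, collapse = ", ")))
  }
  if (cfg$n_splits < 0) errors <- c(errors, "field 'n_splits' must be >= 0")
  if (length(errors)) {
    stop(paste(c("invalid run configuration:", errors), collapse = "\n  "), call. = FALSE)
  }
  cfg$generator <- gen
  cfg
}

.stage_log <- function(log_path, stage, status, detail = NULL) {
  rec <- list(stage = stage, status = status, detail = detail)
  cat(jsonlite::toJSON(rec, auto_unbox = TRUE), "\n", file = log_path, append = TRUE)
  message(sprintf("[%s] %s%s", stage, status,
                  if (is.null(detail)) "" else paste0(": ", detail)))
}

#' Run the full HAT analysis pipeline
#'
#' Produces, in order: per-cohort CSVs, gait imputation (PMM over all
#' cohorts), the harmonized dataset and report, HAT models (per cohort
#' and harmonized), stratified validation results, fixed-effect IPD-MA
#' results (full and leave-cohort-out), and chart exports.  Every file is
#' listed in `manifest.json` with an MD5 checksum; identical
#' (config, seed) pairs reproduce the manifest bit for bit.
#'
#' @param config run configuration (list or JSON path), see
#'   [validate_run_config()].
#' @param out_dir output directory (created if needed).
#' @return invisible manifest data.frame (`file`, `md5`).
#' @export
run_pipeline <- function(config = list(), out_dir) {
  cfg <- validate_run_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "pipeline_log.jsonl")
  if (file.exists(log_path)) unlink(log_path)
  artifacts <- character(0)
  add <- function(f) artifacts <<- c(artifacts, f)
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      .stage_log(log_path, stage, "failed", conditionMessage(e))
      # persist a partial manifest before aborting
      .write_manifest(artifacts, out_dir, partial = TRUE)
      stop(sprintf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)),
           call. = FALSE)
    })
  }

  # 1. simulate
  gen <- cfg$generator
  cohorts <- run_stage("simulate", {
    tabs <- lapply(names(gen$cohorts), function(nm) {
      tb <- generate_cohort(gen, nm)
      tb <- generate_outcomes(tb, gen)
      inject_defects(tb, gen)
    })
    names(tabs) <- names(gen$cohorts)
    for (nm in names(tabs)) {
      f <- file.path(out_dir, sprintf("cohort_%s.csv", nm))
      write_cohort_csv(tabs[[nm]], f); add(f)
    }
    .stage_log(log_path, "simulate", "ok", sprintf("%d cohorts", length(tabs)))
    tabs
  })

  # 2. impute systematically missing gait
  cohorts <- run_stage("impute", {
    pooled <- do.call(rbind, lapply(cohorts, function(tb) tb[, names(cohort_schema())]))
    set.seed(.sub_seed(cfg$seed, "impute"))
    pmm <- fit_pmm(pooled)
    for (nm in names(cohorts)) {
      if (anyNA(cohorts[[nm]]$gait_speed) &&
          isTRUE(gen$cohorts[[nm]]$gait_systematically_missing)) {
        cohorts[[nm]] <- impute_pmm(pmm, cohorts[[nm]])
        f <- file.path(out_dir, sprintf("cohort_%s_imputed.csv", nm))
        write_cohort_csv(cohorts[[nm]], f); add(f)
      }
    }
    f <- file.path(out_dir, "pmm_model.json")
    jsonlite::write_json(pmm[c("target", "covariates", "k", "coefficients")],
                         f, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    add(f)
    .stage_log(log_path, "impute", "ok")
    cohorts
  })

  # 3. harmonize
  harm <- run_stage("harmonize", {
    h <- harmonize(unname(cohorts), impute_first = TRUE)
    f <- file.path(out_dir, "harmonized.csv"); write_cohort_csv(h$table, f); add(f)
    fr <- file.path(out_dir, "harmonization_report.json")
    jsonlite::write_json(h$report, fr, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    add(fr)
    .stage_log(log_path, "harmonize", "ok", sprintf("n = %d", nrow(h$table)))
    h
  })

  # 4. build HAT models
  grid <- cutoff_grid(cfg$candidates %||% default_cutoff_candidates())
  models <- run_stage("build", {
    targets <- list(harmonized = harm$table)
    if (isTRUE(cfg$per_cohort_models)) {
      for (nm in names(cohorts)) {
        cc <- harm$table[harm$table$cohort == nm, , drop = FALSE]
        targets[[nm]] <- cc
      }
    }
    mods <- list()
    for (nm in names(targets)) {
      sel <- select_hat_model(grid, targets[[nm]], n_splits = cfg$n_splits,
                              seed = .sub_seed(cfg$seed, paste0("build:", nm)))
      f <- file.path(out_dir, sprintf("hat_model_%s.json", nm))
      write_hat_model(sel$model, f); add(f)
      mods[[nm]] <- sel$model
    }
    .stage_log(log_path, "build", "ok", sprintf("grid of %d candidates", length(grid)))
    mods
  })

  # 5. validation
  valid <- run_stage("validate", {
    rows <- list()
    for (nm in names(models)) {
      tab <- if (nm == "harmonized") harm$table else
        harm$table[harm$table$cohort == nm, , drop = FALSE]
      hat <- score_hat(models[[nm]], tab)
      rows[[nm]] <- stratified_validation(tab, hat, outcomes = cfg$outcomes,
                                          cohort = nm, age_break = cfg$strata_age_break)
    }
    res <- do.call(rbind, rows); rownames(res) <- NULL
    f <- file.path(out_dir, "validation.csv")
    utils::write.csv(res, f, row.names = FALSE); add(f)
    .stage_log(log_path, "validate", "ok", sprintf("%d result rows", nrow(res)))
    res
  })

  # 6. IPD meta-analysis (full + leave-cohort-out)
  run_stage("meta", {
    ccr <- valid[valid$cohort != "harmonized" & valid$stratum == "overall", , drop = FALSE]
    combos <- unique(ccr[, c("outcome", "metric")])
    out <- list()
    for (r in seq_len(nrow(combos))) {
      oc <- combos$outcome[r]; mt <- combos$metric[r]
      full <- tryCatch(meta_from_validation(ccr, oc, mt), error = function(e) NULL)
      if (is.null(full)) next
      out[[length(out) + 1L]] <- data.frame(
        analysis = "full", outcome = oc, metric = mt, pooled = full$pooled,
        ci_lo = full$ci[1], ci_hi = full$ci[2], stringsAsFactors = FALSE)
      for (dr in cfg$leave_out) {
        red <- tryCatch(meta_from_validation(ccr, oc, mt, drop = dr),
                        error = function(e) NULL)
        if (is.null(red)) next
        role <- cfg$leave_out_roles[[dr]] %||% paste0("minus_", dr)
        out[[length(out) + 1L]] <- data.frame(
          analysis = role, outcome = oc, metric = mt, pooled = red$pooled,
          ci_lo = red$ci[1], ci_hi = red$ci[2], stringsAsFactors = FALSE)
      }
    }
    meta <- do.call(rbind, out)
    if (is.null(meta)) {
      meta <- data.frame(analysis = character(0), outcome = character(0),
                         metric = character(0), pooled = numeric(0),
                         ci_lo = numeric(0), ci_hi = numeric(0))
    }
    f <- file.path(out_dir, "meta.csv")
    utils::write.csv(meta, f, row.names = FALSE); add(f)
    .stage_log(log_path, "meta", "ok", sprintf("%d pooled rows", nrow(meta)))
    meta
  })

  # 7. charts
  run_stage("charts", {
    hat <- score_hat(models[["harmonized"]], harm$table)
    mort5 <- as.integer(harm$table$death_event == 1 & harm$table$death_time <= 5)
    sexes <- if (isTRUE(cfg$charts_by_sex)) c("female", "male") else "all"
    for (sx in sexes) {
      chart <- fit_quantile_curves(harm$table, sex = sx, hat = hat)
      sel <- if (sx == "all") rep(TRUE, nrow(harm$table)) else harm$table$sex == sx
      surf <- fit_risk_surface(harm$table[sel, , drop = FALSE], mort5[sel], hat[sel])
      files <- render_chart(chart, surf, file.path(out_dir, paste0("chart_", sx)),
                            png_plot = isTRUE(cfg$charts_png))
      for (f in files) add(f)
    }
    .stage_log(log_path, "charts", "ok")
    NULL
  })

  manifest <- .write_manifest(artifacts, out_dir)
  .stage_log(log_path, "manifest", "ok", sprintf("%d artifacts", nrow(manifest)))
  invisible(manifest)
}

.write_manifest <- function(artifacts, out_dir, partial = FALSE) {
  files <- artifacts[file.exists(artifacts)]
  manifest <- data.frame(
    file = basename(files),
    md5 = unname(tools::md5sum(files)),
    stringsAsFactors = FALSE
  )
  manifest <- manifest[order(manifest$file), , drop = FALSE]
  rownames(manifest) <- NULL
  path <- file.path(out_dir, if (partial) "manifest_partial.json" else "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  manifest
}

#' Minimal command-line entry point
#'
#' Subcommands: `simulate`, `run-all` (full pipeline), `build`,
#' `charts`; shared flags `--config <json>`, `--out <dir>`,
#' `--seed <int>`.  Exit codes: 0 success, 2 configuration error, 3 stage
#' failure.  Installed as `exec/hat`; call from R as
#' `hat_cli(c("run-all", "--out", "artifacts"))`.
#'
#' @param args character vector of CLI arguments.
#' @return exit code (integer), invisibly.
#' @export
hat_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- "usage: hat <simulate|run-all> [--config file.json] [--out dir] [--seed int]"
  if (!length(args)) { message(usage); return(invisible(2L)) }
  cmd <- args[1]
  opt <- function(flag, default = NULL) {
    i <- which(args == flag)
    if (length(i) && i < length(args)) args[i + 1L] else default
  }
  out_dir <- opt("--out", "hat_artifacts")
  cfg <- opt("--config")
  seed <- as.integer(opt("--seed", "20240610"))
  config <- tryCatch({
    base <- if (is.null(cfg)) list() else cfg
    resolved <- validate_run_config(base)
    resolved$seed <- seed
    resolved$generator$seed <- seed
    resolved
  }, error = function(e) { message("config error: ", conditionMessage(e)); NULL })
  if (is.null(config)) return(invisible(2L))
  code <- switch(cmd,
    "simulate" = tryCatch({
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      tab <- simulate_cohorts(config$generator)
      for (nm in unique(tab$cohort)) {
        write_cohort_csv(tab[tab$cohort == nm, , drop = FALSE],
                         file.path(out_dir, sprintf("cohort_%s.csv", nm)))
      }
      0L
    }, error = function(e) { message("stage error: ", conditionMessage(e)); 3L }),
    "run-all" = tryCatch({
      run_pipeline(config, out_dir)
      0L
    }, error = function(e) { message("stage error: ", conditionMessage(e)); 3L }),
    { message(usage); 2L }
  )
  invisible(code)
}
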