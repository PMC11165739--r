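# Cohort table I/O, unit standardization, complete-case harmonization.

# fixed CSV schema: column name -> type ("n" numeric, "i" integer, "c" character)
.cohort_schema <- c(
  participant_id = "c", cohort = "c", age = "n", sex = "c", education = "c",
  gait_speed = "n", mmse = "i", n_chronic = "i", iadl = "i", padl = "i",
  death_time = "n", death_event = "i", admit_1y = "i", admit_3y = "i",
  admissions_unplanned = "i", gait_imputed = "i"
)

.indicator_cols <- c("gait_speed", "mmse", "n_chronic", "iadl", "padl")

#' Cohort CSV schema
#'
#' @return named character vector mapping column names to storage type
#'   (`"n"` numeric, `"i"` integer, `"c"` character).  Missing values are
#'   encoded as empty fields in CSV.
#' @export
cohort_schema <- function() .cohort_schema

# range checks; returns character vector of violations ("" if clean)
.check_ranges <- function(table) {
  probs <- character(0)
  bad <- function(cond, col) {
    idx <- which(cond)
    if (length(idx)) sprintf("row %d: column '%s' out of range (value %s)",
                             idx, col, table[[col]][idx]) else character(0)
  }
  probs <- c(probs,
             bad(!is.na(table$mmse) & (table$mmse < 0 | table$mmse > 30), "mmse"),
             bad(!is.na(table$gait_speed) & table$gait_speed < 0, "gait_speed"),
             bad(!is.na(table$n_chronic) & (table$n_chronic < 0 | table$n_chronic > 60), "n_chronic"),
             bad(!is.na(table$iadl) & (table$iadl < 0 | table$iadl > 8), "iadl"),
             bad(!is.na(table$padl) & (table$padl < 0 | table$padl > 6), "padl"),
             bad(!is.na(table$death_time) & table$death_time <= 0, "death_time"),
             bad(!is.na(table$sex) & !table$sex %in% c("female", "male"), "sex"),
             bad(!is.na(table$education) &
                   !table$education %in% c("primary", "high_school", "university"), "education"))
  probs
}

.validate_cohort_table <- function(table, context = "cohort table") {
  miss <- setdiff(names(.cohort_schema), names(table))
  if (length(miss)) {
    stop(sprintf("%s: missing columns: %s", context, paste(miss, collapse = ", ")), call. = FALSE)
  }
  if (anyDuplicated(table$participant_id)) {
    stop(sprintf("%s: duplicate participant ids (e.g. '%s')", context,
                 table$participant_id[duplicated(table$participant_id)][1]), call. = FALSE)
  }
  probs <- .check_ranges(table)
  if (length(probs)) {
    stop(sprintf("%s: %s", context, paste(utils::head(probs, 5), collapse = "; ")), call. = FALSE)
  }
  invisible(table)
}

#' Read a cohort table from CSV
#'
#' Enforces the fixed schema (see [cohort_schema()]): missing columns,
#' duplicate ids, and out-of-range values are rejected with row/column
#' diagnostics.  Empty fields parse as missing, never as 0.
#'
#' @param path CSV file path.
#' @return validated cohort data.frame.
#' @export
read_cohort_csv <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  cls <- c(n = "numeric", i = "integer", c = "character")[.cohort_schema]
  names(cls) <- names(.cohort_schema)
  hdr <- names(utils::read.csv(path, nrows = 1, check.names = FALSE))
  miss <- setdiff(names(.cohort_schema), hdr)
  if (length(miss)) {
    stop(sprintf("'%s': missing columns: %s", path, paste(miss, collapse = ", ")), call. = FALSE)
  }
  tab <- utils::read.csv(path, colClasses = cls[hdr], na.strings = "",
                         check.names = FALSE, stringsAsFactors = FALSE)
  tab <- tab[, names(.cohort_schema), drop = FALSE]
  .validate_cohort_table(tab, context = sprintf("'%s'", path))
  tab
}

#' Write a cohort table to CSV
#'
#' Missing values are written as empty fields; internal generator columns
#' (names starting with `.`) are dropped.  Round-trips exactly through
#' [read_cohort_csv()] on legal tables.
#'
#' @param table cohort data.frame.
#' @param path output path.
#' @export
write_cohort_csv <- function(table, path) {
  table <- table[, names(.cohort_schema), drop = FALSE]
  .validate_cohort_table(table)
  utils::write.csv(table, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Standardize gait speed to meters per second
#'
#' If the table carries raw walk-test measurements (`gait_distance_m`,
#' `gait_time_s`), gait speed is computed as distance/time and the raw
#' columns dropped; a table already on the m/s scale is returned
#' unchanged.  Non-walkers keep their exact 0.
#'
#' @param table cohort data.frame.
#' @return table with a single `gait_speed` column in m/s.
#' @export
standardize_units <- function(table) {
  if (!all(c("gait_distance_m", "gait_time_s") %in% names(table))) return(table)
  d <- table$gait_distance_m; tm <- table$gait_time_s
  bad <- which(!is.na(d) & !is.na(tm) & tm <= 0 & d > 0)
  if (length(bad)) {
    stop(sprintf("row %d: positive gait distance with non-positive time", bad[1]), call. = FALSE)
  }
  speed <- ifelse(!is.na(d) & !is.na(tm) & tm > 0, d / tm, NA_real_)
  speed[!is.na(d) & d == 0] <- 0  # recorded non-walkers
  if (is.null(table$gait_speed)) {
    table$gait_speed <- speed
  } else {
    fill <- is.na(table$gait_speed) & !is.na(speed)
    table$gait_speed[fill] <- speed[fill]
  }
  table$gait_distance_m <- NULL
  table$gait_time_s <- NULL
  table
}

#' Merge cohorts into a harmonized complete-case dataset
#'
#' Stacks the cohort tables and applies a complete-case filter on the five
#' health indicators only — outcomes and covariates never trigger
#' exclusion.  If `impute_first` is `TRUE`, the caller asserts that
#' systematically missing gait has already been imputed (rows still
#' missing gait are excluded and counted like any other incomplete row).
#'
#' @param cohorts list of cohort data.frames.
#' @param impute_first flag recorded in the report; no behavioural change
#'   beyond documentation of the expected pipeline order.
#' @return list with `table` (harmonized data.frame) and `report`
#'   (per-cohort baseline/excluded/included counts plus totals).
#' @export
harmonize <- function(cohorts, impute_first = TRUE) {
  stopifnot(is.list(cohorts), length(cohorts) >= 1)
  all_ids <- unlist(lapply(cohorts, `[[`, "participant_id"))
  if (anyDuplicated(all_ids)) {
    stop(sprintf("overlapping participant ids across cohorts (e.g. '%s')",
                 all_ids[duplicated(all_ids)][1]), call. = FALSE)
  }
  keep_extra <- Reduce(intersect, lapply(cohorts, names))
  stacked <- do.call(rbind, lapply(cohorts, function(tb) tb[, keep_extra, drop = FALSE]))
  rownames(stacked) <- NULL
  complete <- stats::complete.cases(stacked[, .indicator_cols, drop = FALSE])
  out <- stacked[complete, , drop = FALSE]
  rownames(out) <- NULL

  per <- lapply(split(complete, stacked$cohort), function(ok) {
    c(baseline = length(ok), excluded = sum(!ok), included = sum(ok))
  })
  per <- per[unique(stacked$cohort)]  # input order
  report <- list(
    per_cohort = per,
    total_baseline = nrow(stacked),
    total_excluded = sum(!complete),
    total_included = sum(complete),
    exclusion_variables = .indicator_cols,
    impute_first = isTRUE(impute_first)
  )
  list(table = out, report = report)
}
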