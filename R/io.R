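# CSV and JSON plumbing: plate wells, tumor measurements, reports.
# Readers are strict: any malformed input raises a diagnosable error that
# names the offending column or row; no partial datasets are returned.

plate_cols <- c("plate_id", "condition_id", "agent1", "dose1", "agent2",
                "dose2", "dose_unit", "absorbance", "replicate", "is_control")
tumor_cols <- c("animal_id", "group", "day", "length_mm", "width_mm")

check_columns <- function(df, expected, path) {
  missing <- setdiff(expected, names(df))
  if (length(missing) > 0) {
    abort(sprintf("'%s' is missing required column(s): %s.",
                  path, paste(missing, collapse = ", ")))
  }
}

row_error <- function(path, rows, what) {
  abort(sprintf("'%s': %s (row%s %s).", path, what,
                if (length(rows) > 1) "s" else "",
                paste(head(rows, 5), collapse = ", ")))
}

#' Read a plate-assay CSV of well records
#'
#' Reads the well-level schema written by [write_plate_csv()] /
#' [simulate_plate()]: one row per well with agent identities, doses (µM),
#' raw absorbance (OD450), replicate index and a control flag. Every row is
#' validated: doses must be non-negative, absorbance finite and positive,
#' and `is_control` must agree with both doses being zero. Validation errors
#' cite the offending data rows.
#'
#' @param path Path to a CSV file.
#' @return A tibble of well records (columns as in [simulate_plate()]).
#' @seealso [normalize_viability()]
#' @export
read_plate_csv <- function(path) {
  if (!file.exists(path)) abort(sprintf("file '%s' does not exist.", path))
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  check_columns(df, plate_cols, path)
  df <- df[plate_cols]
  df$agent1 <- as.character(df$agent1)
  df$agent2 <- as.character(df$agent2)
  df$replicate <- as.integer(df$replicate)
  df$is_control <- as.logical(df$is_control)

  bad <- which(!is.finite(df$dose1) | !is.finite(df$dose2) |
                 df$dose1 < 0 | df$dose2 < 0)
  if (length(bad)) row_error(path, bad, "negative or non-finite dose")
  bad <- which(!is.finite(df$absorbance) | df$absorbance <= 0)
  if (length(bad)) row_error(path, bad, "absorbance must be finite and > 0")
  bad <- which(is.na(df$replicate) | df$replicate < 1)
  if (length(bad)) row_error(path, bad, "replicate must be an integer >= 1")
  bad <- which(df$is_control != (df$dose1 == 0 & df$dose2 == 0))
  if (length(bad)) row_error(path, bad, "is_control inconsistent with doses")
  as_tibble(df)
}

#' Write plate-assay well records to CSV
#'
#' @param wells A tibble of well records (see [simulate_plate()]).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_plate_csv <- function(wells, path) {
  check_columns(wells, plate_cols, "wells")
  readr::write_csv(wells[plate_cols], path, progress = FALSE)
  invisible(path)
}

#' Read a tumor-measurement CSV
#'
#' One row per animal per measurement day with caliper `length_mm` and
#' `width_mm`. Dimensions must be strictly positive and days non-negative;
#' rows where width exceeds length are swapped on read (the caliper
#' convention is length >= width) with a warning.
#'
#' @param path Path to a CSV file.
#' @return A tibble of tumor measurements.
#' @seealso [tumor_series()], [simulate_growth()]
#' @export
read_tumor_csv <- function(path) {
  if (!file.exists(path)) abort(sprintf("file '%s' does not exist.", path))
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  check_columns(df, tumor_cols, path)
  df <- df[tumor_cols]
  df$animal_id <- as.character(df$animal_id)
  df$group <- as.character(df$group)
  df$day <- as.integer(df$day)

  bad <- which(is.na(df$day) | df$day < 0)
  if (length(bad)) row_error(path, bad, "day must be an integer >= 0")
  bad <- which(!is.finite(df$length_mm) | !is.finite(df$width_mm) |
                 df$length_mm <= 0 | df$width_mm <= 0)
  if (length(bad)) row_error(path, bad, "length/width must be finite and > 0")
  swap <- which(df$width_mm > df$length_mm)
  if (length(swap)) {
    warn(sprintf("%d row(s) had width > length; dimensions swapped (rows %s).",
                 length(swap), paste(head(swap, 5), collapse = ", ")))
    tmp <- df$length_mm[swap]
    df$length_mm[swap] <- df$width_mm[swap]
    df$width_mm[swap] <- tmp
  }
  as_tibble(df)
}

#' Write tumor measurements to CSV
#'
#' @param measurements A tibble with the tumor-measurement schema.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_tumor_csv <- function(measurements, path) {
  check_columns(measurements, tumor_cols, "measurements")
  readr::write_csv(measurements[tumor_cols], path, progress = FALSE)
  invisible(path)
}

REPORT_SCHEMA_VERSION <- "1.0"

#' Write an analysis report as JSON
#'
#' Serializes a named list of results (estimates with confidence intervals,
#' test statistics with p-values, synergy verdicts, ...) to a versioned,
#' machine-readable JSON report. Objects with a [tidy()] representation
#' (e.g. [bootstrap_ed()] or [assess_synergy()] results) may be stored
#' directly; they are converted to plain lists. Numbers are written at full
#' precision so [read_report()] round-trips losslessly.
#'
#' @param results A named list of results; may be empty.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_report <- function(results, path) {
  if (length(results) && (is.null(names(results)) || any(!nzchar(names(results))))) {
    abort("`results` must be a named list.")
  }
  payload <- list(schema_version = REPORT_SCHEMA_VERSION,
                  results = purrr::map(results, as_report_entry))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null", pretty = TRUE)
  invisible(path)
}

#' Read a JSON analysis report
#'
#' @param path Path to a report written by [write_report()].
#' @return A list with elements `schema_version` and `results`.
#' @export
read_report <- function(path) {
  if (!file.exists(path)) abort(sprintf("file '%s' does not exist.", path))
  rep <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE, simplifyMatrix = FALSE)
  if (is.null(rep$schema_version)) abort(sprintf("'%s' is not a report (no schema_version).", path))
  if (is.null(rep$results)) rep$results <- setNames(list(), character())
  rep
}

# report serialization of result objects: plain lists of scalars/vectors
as_report_entry <- function(x) UseMethod("as_report_entry")

#' @export
as_report_entry.default <- function(x) x

#' @export
as_report_entry.ed_estimate <- function(x) {
  list(type = "ed_estimate", agent = x$agent, effect = x$effect,
       estimate = x$estimate, conf_low = x$conf_low, conf_high = x$conf_high,
       conf_level = x$conf_level, B = x$B, n_unreachable = x$n_unreachable,
       method = x$method)
}

#' @export
as_report_entry.potency_ratio <- function(x) {
  list(type = "potency_ratio", effect = x$effect, ratio = x$ratio,
       conf_low = x$conf_low, conf_high = x$conf_high, conf_level = x$conf_level)
}

#' @export
as_report_entry.synergy_assessment <- function(x) {
  list(type = "synergy_assessment",
       agents = x$agents,
       combo_dose = x$combo_dose,
       combo_effect = list(mean = x$combo$mean, se = x$combo$se, n = x$combo$n),
       escalation = list(level = x$escalation$level, t = x$escalation$statistic,
                         p = x$escalation$p_value),
       potency = list(r50 = x$r50$ratio, r_max = x$r_max$ratio,
                      max_common_effect = x$r_max$effect,
                      g_statistic = x$constancy$statistic,
                      g_p_value = x$constancy$p_value,
                      linear_isobole = x$constancy$linear_isobole),
       levels = lapply(seq_len(nrow(x$levels)), function(i) as.list(x$levels[i, ])),
       verdict = x$verdict)
}

#' @export
as_report_entry.group_comparison <- function(x) {
  list(type = "group_comparison", endpoint_day = x$day,
       anova = if (is.null(x$anova)) NULL else
         list(F = x$anova$statistic, p = x$anova$p_value,
              df1 = x$anova$df1, df2 = x$anova$df2),
       pairwise = lapply(seq_len(nrow(x$pairwise)), function(i) as.list(x$pairwise[i, ])))
}
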