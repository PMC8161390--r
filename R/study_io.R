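# Reading, validating and writing replicate-level bioassay tables.  All
# statistics downstream consume the canonical tibble produced here; file
# format decisions stay in this file.

#' Read a replicate-level bioassay table
#'
#' Reads a CSV of acute-toxicity replicate records (one row per exposure
#' well) and returns a validated tibble in canonical form. Source column
#' names are translated through `mapping`, so deposited datasets with
#' arbitrary headers can be ingested without editing the file. Controls are
#' encoded as `concentration == 0`; if the source carries a separate
#' control-flag column it can be mapped as `control_flag` and must agree
#' with the zero-concentration encoding.
#'
#' @param path Path to a CSV file (comma-separated, UTF-8, `.` decimal;
#'   scientific notation accepted). A header row is required.
#' @param mapping Named character vector or list translating canonical names
#'   to source columns, e.g.
#'   `c(compound = "chemical", salinity = "psu", ...)`. Canonical names:
#'   `compound`, `salinity`, `concentration` (mg/L), `replicate_id`,
#'   `n_exposed`, `n_dead`, optionally `control_flag`. `NULL` (default)
#'   assumes the file already uses the canonical names.
#' @return A tibble of class `bioassay_study` with the six canonical
#'   columns; extra source columns are dropped.
#' @seealso [validate_bioassay()], [bioassay_groups()]
#' @export
read_bioassay_table <- function(path, mapping = NULL) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (nrow(raw) == 0) abort("empty table: no replicate records in file.")
  mapping <- resolve_mapping(mapping)
  missing_src <- setdiff(unname(unlist(mapping)), names(raw))
  if (length(missing_src)) {
    abort(paste0("format error: required column(s) not in file: ",
                 paste(missing_src, collapse = ", ")))
  }
  data <- tibble::as_tibble(setNames(raw[unname(unlist(mapping))],
                                     names(mapping)))
  if ("control_flag" %in% names(data)) {
    flag <- as.logical(data$control_flag)
    mismatch <- which(xor(flag, data$concentration == 0))
    if (length(mismatch)) {
      abort(paste0("control flag disagrees with concentration == 0 at row(s): ",
                   paste(head(mismatch, 5), collapse = ", ")))
    }
    data$control_flag <- NULL
  }
  validate_bioassay(data)
}

resolve_mapping <- function(mapping) {
  if (is.null(mapping)) {
    return(setNames(as.list(BIOASSAY_COLUMNS), BIOASSAY_COLUMNS))
  }
  mapping <- as.list(mapping)
  missing_canon <- setdiff(BIOASSAY_COLUMNS, names(mapping))
  if (length(missing_canon)) {
    abort(paste0("format error: mapping lacks required column(s): ",
                 paste(missing_canon, collapse = ", ")))
  }
  mapping[c(BIOASSAY_COLUMNS, intersect("control_flag", names(mapping)))]
}

#' Validate a replicate-level bioassay table
#'
#' Checks the invariants every downstream computation relies on: counts
#' satisfy `0 <= n_dead <= n_exposed` with `n_exposed > 0`; concentrations
#' are non-negative (0 is the solvent control); salinities are positive;
#' every (compound, salinity) group has at least two distinct positive
#' concentrations plus at least one control record; and any compound present
#' at both salinities of a pair uses the same concentration series in both,
#' which the stratified permutation test requires.
#'
#' @param data A data frame with the canonical bioassay columns.
#' @return The validated data as a `bioassay_study` tibble (invisibly
#'   usable in a pipe).
#' @export
validate_bioassay <- function(data) {
  miss <- setdiff(BIOASSAY_COLUMNS, names(data))
  if (length(miss)) {
    abort(paste0("format error: missing required column(s): ",
                 paste(miss, collapse = ", ")))
  }
  if (nrow(data) == 0) abort("empty table: no replicate records.")
  num <- c("salinity", "concentration", "n_exposed", "n_dead")
  for (col in num) {
    if (!is.numeric(data[[col]]) || any(!is.finite(data[[col]]))) {
      abort(paste0("column `", col, "` must be finite numeric."))
    }
  }
  bad <- which(data$n_dead < 0 | data$n_dead > data$n_exposed |
                 data$n_exposed <= 0)
  if (length(bad)) {
    abort(paste0("validation error: counts violate 0 <= n_dead <= n_exposed ",
                 "at row(s): ", paste(head(bad, 5), collapse = ", ")))
  }
  if (any(data$concentration < 0)) abort("concentrations must be >= 0.")
  if (any(data$salinity <= 0)) abort("salinity (PSU) must be positive.")
  grp <- dplyr::summarise(
    dplyr::group_by(data, .data$compound, .data$salinity),
    n_pos = dplyr::n_distinct(.data$concentration[.data$concentration > 0]),
    n_ctrl = sum(.data$concentration == 0), .groups = "drop")
  bad_grp <- dplyr::filter(grp, .data$n_pos < 2 | .data$n_ctrl < 1)
  if (nrow(bad_grp)) {
    abort(paste0("group(s) lacking >= 2 positive concentrations plus a ",
                 "control: ",
                 paste(bad_grp$compound, bad_grp$salinity, sep = "@",
                       collapse = ", ")))
  }
  series <- dplyr::summarise(
    dplyr::group_by(data, .data$compound, .data$salinity),
    series = paste(sort(unique(.data$concentration)), collapse = ","),
    .groups = "drop")
  uneven <- dplyr::filter(
    dplyr::summarise(dplyr::group_by(series, .data$compound),
                     k = dplyr::n_distinct(.data$series), .groups = "drop"),
    .data$k > 1)
  if (nrow(uneven)) {
    abort(paste0("compound(s) with different concentration series across ",
                 "salinities: ", paste(uneven$compound, collapse = ", ")))
  }
  out <- tibble::as_tibble(data[BIOASSAY_COLUMNS])
  class(out) <- unique(c("bioassay_study", class(out)))
  out
}

#' Summarise the (compound, salinity) groups of a study
#'
#' @param data A validated bioassay table.
#' @return A tibble with one row per (compound, salinity) group:
#'   record count, number of positive concentrations, control records,
#'   organisms exposed and total deaths.
#' @export
bioassay_groups <- function(data) {
  data <- validate_bioassay(data)
  dplyr::summarise(
    dplyr::group_by(data, .data$compound, .data$salinity),
    n_records = dplyr::n(),
    n_concentrations = dplyr::n_distinct(.data$concentration),
    n_controls = sum(.data$concentration == 0),
    n_exposed = sum(.data$n_exposed),
    n_dead = sum(.data$n_dead),
    .groups = "drop")
}

#' Write a bioassay table to CSV
#'
#' Writes the canonical columns with full numeric precision so that a
#' write-then-read round trip reproduces every field exactly.
#'
#' @param data A validated bioassay table.
#' @param path Output CSV path.
#' @return `data`, invisibly.
#' @export
write_bioassay_table <- function(data, path) {
  data <- validate_bioassay(data)
  readr::write_csv(data, path)
  invisible(data)
}

#' Write the per-compound LC results table
#'
#' Lays out the analysis results as one row per compound: LC10 and LC50
#' point estimates and standard errors at each salinity, the pseudo-R-squared
#' of each fit, and the permutation p-value per LC level. All concentrations
#' are nominal mg/L. An empty result set produces a header-only file and a
#' warning.
#'
#' @param analysis An `lc_analysis` object from [run_full_analysis()], or a
#'   list with its `lc_estimates`, `fits` and `tests` tibbles.
#' @param path Output CSV path.
#' @return The wide results tibble, invisibly.
#' @export
write_lc_table <- function(analysis, path) {
  wide <- lc_result_table(analysis)
  if (nrow(wide) == 0) warn("no results to write; emitting header only.")
  readr::write_csv(wide, path)
  invisible(wide)
}

#' Assemble the wide per-compound results table
#'
#' @inheritParams write_lc_table
#' @return A tibble with one row per compound and columns
#'   `lc10_<salinity>`, `lc10_se_<salinity>`, `lc50_<salinity>`,
#'   `lc50_se_<salinity>`, `pseudo_r2_<salinity>`, `p_lc10`, `p_lc50`
#'   (level columns follow the requested LC levels).
#' @export
lc_result_table <- function(analysis) {
  lc <- analysis$lc_estimates
  fits <- analysis$fits
  tests <- analysis$tests
  if (is.null(lc) || nrow(lc) == 0) {
    return(tibble::tibble(compound = character()))
  }
  lc_wide <- tidyr::pivot_wider(
    dplyr::transmute(lc, .data$compound, .data$salinity,
                     lc = paste0("lc", round(100 * .data$level)),
                     .data$value, .data$se),
    names_from = c("lc", "salinity"), values_from = c("value", "se"),
    names_glue = "{lc}_{.value}_{salinity}")
  names(lc_wide) <- sub("_value", "", names(lc_wide))
  fit_wide <- tidyr::pivot_wider(
    dplyr::select(fits, "compound", "salinity", "pseudo_r2"),
    names_from = "salinity", values_from = "pseudo_r2",
    names_glue = "pseudo_r2_{salinity}")
  out <- dplyr::left_join(lc_wide, fit_wide, by = "compound")
  if (!is.null(tests) && nrow(tests) > 0) {
    p_wide <- tidyr::pivot_wider(
      dplyr::transmute(tests, .data$compound,
                       lc = paste0("p_lc", round(100 * .data$level)),
                       .data$p_value),
      names_from = "lc", values_from = "p_value")
    out <- dplyr::left_join(out, p_wide, by = "compound")
  }
  out
}
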