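# Measured-versus-nominal concentration QC: the analytical-chemistry sanity
# check that exposure solutions contained roughly the intended dose.

#' Percent of nominal concentration
#'
#' Arithmetic mean of the measured sample concentrations divided by the
#' nominal concentration, times 100, reported to 3 significant figures.
#' Missing samples (lost in shipping and the like) are dropped by the
#' caller, not imputed; no recovery-rate correction is applied.
#'
#' @param nominal Nominal concentration in mg/L, positive.
#' @param sample_means Measured sample mean concentrations in mg/L
#'   (non-negative; at least one).
#' @return Percent of nominal, a single number (3 significant figures).
#' @examples
#' percent_of_nominal(0.0005, c(0.00030, 0.00030, 0.00027))  # 58.0
#' percent_of_nominal(0.005, 0.00282)                        # 56.4
#' @export
percent_of_nominal <- function(nominal, sample_means) {
  if (length(nominal) != 1 || !is.finite(nominal) || nominal <= 0) {
    abort("`nominal` must be a single positive concentration.")
  }
  sample_means <- sample_means[!is.na(sample_means)]
  if (length(sample_means) == 0) abort("at least one measured sample required.")
  if (any(sample_means < 0)) abort("measured samples must be >= 0.")
  signif(mean(sample_means) / nominal * 100, 3)
}

#' QC table of measured versus nominal concentrations
#'
#' Applies [percent_of_nominal()] row-wise to a table with a `compound`
#' column, a `nominal` column, and one or more `sample_*` measurement
#' columns (`NA` = sample unavailable).
#'
#' @param data Data frame with columns `compound`, `nominal`, and
#'   measurement columns matching `sample_`.
#' @return A tibble: `compound`, `nominal`, `n_samples`,
#'   `mean_measured`, `percent_of_nominal`.
#' @examples
#' qc_table(table2_measured())
#' @export
qc_table <- function(data) {
  need <- c("compound", "nominal")
  if (!all(need %in% names(data))) {
    abort("`data` needs `compound` and `nominal` columns.")
  }
  sample_cols <- grep("^sample_", names(data), value = TRUE)
  if (length(sample_cols) == 0) abort("no `sample_*` measurement columns found.")
  purrr::map_dfr(seq_len(nrow(data)), function(i) {
    samples <- as.numeric(data[i, sample_cols])
    samples <- samples[!is.na(samples)]
    tibble::tibble(
      compound = data$compound[i],
      nominal = data$nominal[i],
      n_samples = length(samples),
      mean_measured = mean(samples),
      percent_of_nominal = percent_of_nominal(data$nominal[i], samples))
  })
}

#' Measured concentrations of the mid-series check samples
#'
#' The analytical check measurements for each compound's middle nominal
#' concentration: per-sample mean concentrations in mg/L, with `NA` where a
#' sample was lost in transit. Standard errors of the individual samples
#' are metadata only and are not propagated.
#'
#' @return A tibble with columns `compound`, `nominal`, `sample_1`,
#'   `sample_2`, `sample_3`, suitable for [qc_table()].
#' @export
table2_measured <- function() {
  tibble::tribble(
    ~compound,      ~nominal, ~sample_1, ~sample_2, ~sample_3,
    "bifenthrin",     0.0005,   0.00030,   0.00030,  0.00027,
    "chlorpyrifos",   0.005,    0.00282,   NA,       NA,
    "dicloran",       0.09,     0.0830,    0.079,    NA,
    "myclobutanil",   0.4,      0.493,     0.49,     NA,
    "paraquat",       6.7,      6.61,      7.19,     NA,
    "penconazole",    0.107,    0.0966,    0.112,    NA,
    "triadimefon",    1.0,      0.966,     0.896,    NA
  )
}
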