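# End-to-end analysis: fit every (compound, salinity) group, estimate LC10
# and LC50 with delta-method SEs, and run the salinity permutation test per
# compound.  This is the programmatic counterpart of the command-line
# `report` subcommand.

#' Run the full dose-response and salinity-comparison analysis
#'
#' For every (compound, salinity) group in the study: fits the LL.2 curve
#' ([fit_ll2()]), estimates the requested LC levels with standard errors
#' ([lc_estimate()]), and — for every compound present at both salinities of
#' the pair — runs the Monte Carlo permutation test for a difference in LC
#' values ([monte_carlo_lc_test()]). Groups whose observed fit fails are
#' reported with a failure flag and excluded from LC estimation and testing;
#' the run continues. All concentrations in the outputs are nominal mg/L.
#' The whole analysis is deterministic given `seed`.
#'
#' @param data A validated bioassay table ([read_bioassay_table()],
#'   [simulate_bioassay()] or [validate_bioassay()]).
#' @param compounds Compounds to analyse (default: all present).
#' @param salinities Length-2 salinity pair for the comparison (default:
#'   the two salinities in the data).
#' @param levels Mortality fractions for LC estimation and testing
#'   (default `c(0.10, 0.50)`).
#' @param n_sim Permutations per test, `B` (default 5000).
#' @param alpha Significance threshold recorded in the summary
#'   (default 0.05).
#' @param seed Integer seed for the permutation tests.
#' @param run_tests Run the permutation tests (default `TRUE`); `FALSE`
#'   stops after fitting and LC estimation.
#' @param quiet Suppress permutation progress messages (default `TRUE`).
#' @return An object of class `lc_analysis`: a list with
#'   \describe{
#'     \item{fits}{tibble, one row per (compound, salinity): parameters,
#'       log-likelihoods, pseudo-R2, convergence flag.}
#'     \item{fit_objects}{named list of the underlying `ll2_fit` objects.}
#'     \item{lc_estimates}{tibble, one row per (compound, salinity, level).}
#'     \item{tests}{tibble, one row per (compound, level), from
#'       [monte_carlo_lc_test()].}
#'     \item{summary}{list: seed, `n_sim`, alpha, counts of converged fits
#'       and failed permutations — enough to reproduce the run.}
#'   }
#' @seealso [write_lc_table()], [write_run_summary()], [lc_result_table()]
#' @export
run_full_analysis <- function(data, compounds = NULL, salinities = NULL,
                              levels = c(0.10, 0.50), n_sim = 5000,
                              alpha = 0.05, seed = NULL, run_tests = TRUE,
                              quiet = TRUE) {
  data <- validate_bioassay(data)
  if (!is.null(compounds)) {
    missing_cmp <- setdiff(compounds, unique(data$compound))
    if (length(missing_cmp)) {
      abort(paste0("compound(s) not in data: ",
                   paste(missing_cmp, collapse = ", ")))
    }
    data <- data[data$compound %in% compounds, ]
  }
  if (is.null(salinities)) salinities <- sort(unique(data$salinity))
  if (length(salinities) != 2) {
    abort("`salinities` must name exactly two treatments.")
  }
  data <- data[data$salinity %in% salinities, ]
  if (nrow(data) == 0) abort("no records left after filtering.")

  groups <- dplyr::distinct(data, .data$compound, .data$salinity)
  groups <- dplyr::arrange(groups, .data$compound, .data$salinity)
  fit_objects <- purrr::pmap(groups, function(compound, salinity) {
    fit_ll2(data[data$compound == compound & data$salinity == salinity, ])
  })
  names(fit_objects) <- paste(groups$compound, groups$salinity, sep = "@")
  fits <- purrr::map_dfr(fit_objects, function(f) {
    tibble::tibble(compound = f$compound, salinity = f$salinity,
                   b = f$b, e = f$e, loglik = f$loglik,
                   null_loglik = f$null_loglik, n_obs = f$n_obs,
                   pseudo_r2 = f$pseudo_r2, converged = f$converged)
  })

  lc_estimates <- purrr::map_dfr(
    fit_objects[purrr::map_lgl(fit_objects, "converged")],
    function(f) {
      dplyr::mutate(lc_estimate(f, levels),
                    compound = f$compound, salinity = f$salinity,
                    .before = 1)
    })

  both_ok <- dplyr::filter(
    dplyr::summarise(dplyr::group_by(fits, .data$compound),
                     ok = sum(.data$converged) == 2 &&
                       dplyr::n() == 2, .groups = "drop"),
    .data$ok)
  tests <- if (run_tests) {
    purrr::imap_dfr(set_names(both_ok$compound), function(cmp, i) {
      cmp_seed <- if (is.null(seed)) NULL
                  else seed + match(cmp, sort(unique(data$compound)))
      monte_carlo_lc_test(data, compound = cmp, salinities = salinities,
                          levels = levels, n_sim = n_sim, seed = cmp_seed,
                          quiet = quiet)
    })
  } else {
    tibble::tibble()
  }

  structure(list(
    fits = fits, fit_objects = fit_objects, lc_estimates = lc_estimates,
    tests = tests,
    summary = list(
      seed = seed, n_sim = n_sim, alpha = alpha, levels = levels,
      salinities = salinities,
      n_groups = nrow(groups),
      n_converged = sum(fits$converged),
      failed_groups = fits$compound[!fits$converged],
      n_tests = if (nrow(tests)) length(unique(tests$compound)) else 0L,
      failed_permutations = if (nrow(tests))
        stats::setNames(tests$n_failed[!duplicated(tests$compound)],
                        tests$compound[!duplicated(tests$compound)])
      else integer(),
      package_version = as.character(utils::packageVersion("salinelc")))
  ), class = "lc_analysis")
}

#' @export
print.lc_analysis <- function(x, ...) {
  s <- x$summary
  cat("Dose-response salinity comparison\n")
  cat(sprintf("  %d group fits (%d converged), %d permutation tests (B = %d)\n",
              s$n_groups, s$n_converged, s$n_tests, s$n_sim))
  if (nrow(x$tests)) {
    sig <- x$tests[x$tests$p_value <= s$alpha, ]
    if (nrow(sig)) {
      cat(sprintf("  significant at alpha = %.2f:\n", s$alpha))
      for (i in seq_len(nrow(sig))) {
        cat(sprintf("    %s LC%d: p = %.4f\n", sig$compound[i],
                    round(100 * sig$level[i]), sig$p_value[i]))
      }
    } else {
      cat(sprintf("  no difference significant at alpha = %.2f\n", s$alpha))
    }
  }
  invisible(x)
}

#' Write the JSON run summary
#'
#' Records seed, number of permutations, convergence and failure counts,
#' and the package version — what is needed to reproduce and audit a run.
#'
#' @param analysis An `lc_analysis` from [run_full_analysis()].
#' @param path Output JSON path.
#' @return The summary list, invisibly.
#' @export
write_run_summary <- function(analysis, path) {
  if (!inherits(analysis, "lc_analysis")) {
    abort("`analysis` must come from run_full_analysis().")
  }
  jsonlite::write_json(analysis$summary, path, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(analysis$summary)
}
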