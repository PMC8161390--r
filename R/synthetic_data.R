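# Synthetic bioassays with known truth: the verification engine for the
# fitting and permutation machinery.  The default design mirrors a standard
# estuarine-fish range-finding test: six concentrations including a solvent
# control, six replicates per concentration, two organisms per replicate,
# at 5 and 15 PSU.

#' Describe a bioassay design
#'
#' @param concentrations Ordered concentration series in mg/L, strictly
#'   increasing, starting at 0 (the solvent control).
#' @param n_replicates Replicates per concentration per salinity
#'   (default 6).
#' @param organisms_per_replicate Organisms per replicate well (default 2).
#' @param salinities Salinity treatments in PSU (default `c(5, 15)`).
#' @return A `sim_design` list.
#' @export
sim_design <- function(concentrations, n_replicates = 6,
                       organisms_per_replicate = 2, salinities = c(5, 15)) {
  if (length(concentrations) < 3 || concentrations[1] != 0 ||
      is.unsorted(concentrations, strictly = TRUE)) {
    abort("`concentrations` must be strictly increasing and start at 0.")
  }
  if (n_replicates < 2) abort("`n_replicates` must be >= 2.")
  if (organisms_per_replicate < 1) abort("`organisms_per_replicate` must be >= 1.")
  if (length(salinities) < 1 || any(salinities <= 0)) {
    abort("`salinities` must be positive PSU values.")
  }
  structure(list(concentrations = as.numeric(concentrations),
                 n_replicates = as.integer(n_replicates),
                 organisms_per_replicate = as.integer(organisms_per_replicate),
                 salinities = as.numeric(salinities)),
            class = "sim_design")
}

# Published range-finding series per compound (mg/L), five positive
# concentrations spanning the expected response region plus the control.
TABLE1_SERIES <- list(
  bifenthrin   = c(0.00001, 0.0001, 0.0005, 0.001, 0.01),
  chlorpyrifos = c(0.00005, 0.0005, 0.005, 0.05, 0.5),
  dicloran     = c(0.0009, 0.009, 0.09, 0.9, 9.0),
  myclobutanil = c(0.004, 0.04, 0.4, 4, 40),
  paraquat     = c(0.067, 0.67, 6.7, 67, 670),
  penconazole  = c(0.00107, 0.0107, 0.107, 1.07, 10.7),
  triadimefon  = c(0.01, 0.1, 1, 10, 100)
)

#' The study's range-finding design for one compound
#'
#' Returns the published five-concentration series for the named compound
#' plus the solvent control at 0 mg/L, in the study's default design
#' (6 replicates x 2 organisms, 5 and 15 PSU).
#'
#' @param compound One of `r paste(names(TABLE1_SERIES), collapse = ", ")`
#'   (case-insensitive).
#' @inheritParams sim_design
#' @return A `sim_design`.
#' @examples
#' table1_design("triadimefon")$concentrations  # 0, 0.01, 0.1, 1, 10, 100
#' @export
table1_design <- function(compound, n_replicates = 6,
                          organisms_per_replicate = 2, salinities = c(5, 15)) {
  key <- tolower(compound)
  if (!key %in% names(TABLE1_SERIES)) {
    abort(paste0("unknown compound `", compound, "`; valid names: ",
                 paste(names(TABLE1_SERIES), collapse = ", ")))
  }
  d <- sim_design(c(0, TABLE1_SERIES[[key]]), n_replicates,
                  organisms_per_replicate, salinities)
  d$compound <- key
  d
}

#' True dose-response curves per salinity treatment
#'
#' @param salinities Salinity labels (PSU).
#' @param b,e LL.2 parameters per salinity, recycled to
#'   `length(salinities)`.
#' @return A `treatment_truth` tibble with columns `salinity`, `b`, `e`.
#' @examples
#' treatment_truth(c(5, 15), b = 2, e = c(1, 0.1))
#' @export
treatment_truth <- function(salinities, b, e) {
  out <- tibble::tibble(salinity = as.numeric(salinities),
                        b = as.numeric(b), e = as.numeric(e))
  if (any(out$b <= 0) || any(out$e <= 0)) abort("truth requires b > 0, e > 0.")
  structure(out, class = c("treatment_truth", class(out)))
}

#' Simulate a bioassay study from known truth
#'
#' Draws replicate-level deaths
#' `n_dead ~ Binomial(organisms_per_replicate, 1 - f(x))` under the true
#' LL.2 curve of each salinity treatment. Mortality is generated at
#' replicate level with no overdispersion by default, matching the pure
#' binomial likelihood the fitter assumes; `overdispersion > 0` switches to
#' a beta-binomial with that intra-class correlation for robustness
#' experiments.
#'
#' @param design A [sim_design()].
#' @param truth A [treatment_truth()] covering every salinity in the design.
#' @param seed Integer seed; the result is fully determined by
#'   `(design, truth, seed)`. `NULL` uses (and advances) the session RNG.
#' @param compound Compound label for the generated records; defaults to the
#'   design's compound or `"synthetic"`.
#' @param overdispersion Beta-binomial intra-class correlation `rho` in
#'   `[0, 1)`; 0 (default) is pure binomial.
#' @return A validated `bioassay_study` tibble.
#' @export
simulate_bioassay <- function(design, truth, seed = NULL, compound = NULL,
                              overdispersion = 0) {
  stopifnot(inherits(design, "sim_design"))
  if (!inherits(truth, "treatment_truth")) {
    abort("`truth` must be a `treatment_truth` (see treatment_truth()).")
  }
  miss <- setdiff(design$salinities, truth$salinity)
  if (length(miss)) {
    abort(paste0("truth lacks salinities: ", paste(miss, collapse = ", ")))
  }
  if (overdispersion < 0 || overdispersion >= 1) {
    abort("`overdispersion` must be in [0, 1).")
  }
  compound <- compound %||% design$compound %||% "synthetic"
  grid <- tidyr::expand_grid(
    salinity = design$salinities,
    concentration = design$concentrations,
    replicate_id = paste0("R", seq_len(design$n_replicates))
  )
  m <- design$organisms_per_replicate
  draw <- function() {
    p_dead <- 1 - purrr::map2_dbl(
      grid$concentration, grid$salinity,
      function(x, s) {
        tr <- truth[truth$salinity == s, ]
        ll2_survival(x, tr$b[1], tr$e[1])
      })
    n_dead <- if (overdispersion == 0) {
      rbinom(nrow(grid), m, p_dead)
    } else {
      # beta-binomial via a per-replicate beta draw with icc rho
      theta <- (1 - overdispersion) / overdispersion
      shape1 <- pmax(p_dead * theta, 1e-8)
      shape2 <- pmax((1 - p_dead) * theta, 1e-8)
      rbinom(nrow(grid), m, stats::rbeta(nrow(grid), shape1, shape2))
    }
    tibble::tibble(compound = compound, salinity = grid$salinity,
                   concentration = grid$concentration,
                   replicate_id = grid$replicate_id,
                   n_exposed = m, n_dead = n_dead)
  }
  out <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  validate_bioassay(out)
}

#' Parameter-recovery experiment
#'
#' Simulates `n_datasets` studies from one truth, fits every
#' (salinity) group, and summarises estimation error for the slope `b`, the
#' inflection `e` (LC50) and the LC10. Non-converged fits are excluded from
#' the summaries and reported.
#'
#' @inheritParams simulate_bioassay
#' @param n_datasets Number of simulated studies (>= 10).
#' @param seed Integer root seed; dataset `i` uses `seed + i`.
#' @return A tibble with one row per (salinity, parameter): truth, median
#'   estimate, median bias, RMSE, plus `n_fit`/`n_failed` accounting.
#'   Attribute `estimates` holds the per-dataset fitted values.
#' @export
run_recovery <- function(design, truth, n_datasets, seed = 1) {
  if (n_datasets < 10) abort("`n_datasets` must be >= 10.")
  fits <- purrr::map_dfr(seq_len(n_datasets), function(i) {
    study <- simulate_bioassay(design, truth, seed = seed + i)
    purrr::map_dfr(design$salinities, function(s) {
      g <- study[study$salinity == s, ]
      core <- ll2_fit_core(g$concentration, g$n_exposed, g$n_dead)
      tibble::tibble(
        dataset = i, salinity = s, converged = core$converged,
        b = exp(core$theta[1]), e = exp(core$theta[2]),
        lc10 = if (core$converged)
          lc_quantile(exp(core$theta[1]), exp(core$theta[2]), 0.1)
        else NA_real_)
    })
  })
  fail_frac <- mean(!fits$converged)
  if (fail_frac > 0.5) {
    abort(paste0(sprintf("%.0f%% of fits failed to converge; ", 100 * fail_frac),
                 "increase organisms_per_replicate or replicates."))
  }
  ok <- dplyr::filter(fits, .data$converged)
  long <- tidyr::pivot_longer(ok, c("b", "e", "lc10"),
                              names_to = "parameter", values_to = "estimate")
  truth_long <- tidyr::pivot_longer(
    dplyr::mutate(truth, lc10 = lc_quantile_vec(.data$b, .data$e, 0.1)),
    c("b", "e", "lc10"), names_to = "parameter", values_to = "truth")
  out <- dplyr::summarise(
    dplyr::group_by(dplyr::left_join(long, truth_long,
                                     by = c("salinity", "parameter")),
                    .data$salinity, .data$parameter),
    truth = .data$truth[1],
    median_estimate = median(.data$estimate),
    median_bias = median(.data$estimate - .data$truth),
    rmse = sqrt(mean((.data$estimate - .data$truth)^2)),
    n_fit = dplyr::n(), .groups = "drop")
  out$n_failed <- sum(!fits$converged)
  attr(out, "estimates") <- fits
  out
}

# elementwise LCp for vectors of (b, e) pairs
lc_quantile_vec <- function(b, e, level) {
  e * (level / (1 - level))^(1 / b)
}

#' Null and power calibration of the salinity permutation test
#'
#' Simulates studies under a null truth (identical curves at both
#' salinities) and an alternative truth, runs [monte_carlo_lc_test()] on
#' each, and reports the fraction of datasets rejecting at `alpha` per LC
#' level — the empirical type-I error under the null and power under the
#' alternative.
#'
#' @inheritParams run_recovery
#' @param truth_null A [treatment_truth()] with equal parameters across the
#'   design's two salinities.
#' @param truth_alt Alternative truth: a [treatment_truth()], a named list
#'   of them (one scenario each), or `NULL` to run the null arm only.
#' @param n_sim Permutations per test (`B`).
#' @param alpha Significance threshold (default 0.05).
#' @param levels Mortality fractions tested (default `c(0.10, 0.50)`).
#' @return A tibble with one row per (scenario, level): rejection rate,
#'   number of datasets analysed/failed, mean failed permutations.
#'   Attribute `p_values` holds every per-dataset p-value.
#' @export
run_null_and_power <- function(design, truth_null, truth_alt = NULL,
                               n_datasets = 200, n_sim = 199, alpha = 0.05,
                               levels = c(0.10, 0.50), seed = 1) {
  if (length(design$salinities) != 2) {
    abort("the permutation test compares exactly two salinities.")
  }
  nb <- truth_null[order(truth_null$salinity), ]
  if (nrow(nb) != 2 || nb$b[1] != nb$b[2] || nb$e[1] != nb$e[2]) {
    abort("`truth_null` must share identical (b, e) across both salinities.")
  }
  scenarios <- list(null = truth_null)
  if (inherits(truth_alt, "treatment_truth")) {
    scenarios$alternative <- truth_alt
  } else if (is.list(truth_alt) && length(truth_alt)) {
    if (is.null(names(truth_alt)) || any(!nzchar(names(truth_alt)))) {
      abort("a list of alternatives must be named, one scenario each.")
    }
    scenarios <- c(scenarios, truth_alt)
  }
  pvals <- purrr::imap_dfr(scenarios, function(truth, name) {
    purrr::map_dfr(seq_len(n_datasets), function(i) {
      ds_seed <- seed + i + 1000L * match(name, names(scenarios))
      study <- simulate_bioassay(design, truth, seed = ds_seed)
      res <- tryCatch(
        monte_carlo_lc_test(study, salinities = design$salinities,
                            levels = levels, n_sim = n_sim,
                            seed = ds_seed + 1L, quiet = TRUE),
        error = function(e) NULL)
      if (is.null(res)) {
        return(tibble::tibble(scenario = name, dataset = i, level = levels,
                              p_value = NA_real_, n_failed = NA_integer_))
      }
      tibble::tibble(scenario = name, dataset = i, level = res$level,
                     p_value = res$p_value, n_failed = res$n_failed)
    })
  })
  out <- dplyr::summarise(
    dplyr::group_by(pvals, .data$scenario, .data$level),
    rejection_rate = mean(.data$p_value <= alpha, na.rm = TRUE),
    n_datasets = sum(!is.na(.data$p_value)),
    n_dataset_failures = sum(is.na(.data$p_value)),
    mean_failed_permutations = mean(.data$n_failed, na.rm = TRUE),
    .groups = "drop")
  attr(out, "p_values") <- pvals
  out
}
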