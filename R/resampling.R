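# Monte Carlo label-permutation test for a difference in LC values between
# two salinity treatments, with an exhaustive-enumeration oracle.  The null
# distribution is built by reassigning salinity labels to replicates
# (within concentration strata by default, so every pseudo-treatment keeps
# the full design), refitting both LL.2 curves, and recomputing the LC
# difference.

#' Observed LC difference between two fitted curves
#'
#' @param fit_a,fit_b Converged [fit_ll2()] objects (salinity A and B).
#' @param level Mortality fraction in (0, 1).
#' @return `lc_quantile(A, level) - lc_quantile(B, level)` in mg/L;
#'   antisymmetric in its arguments.
#' @export
observed_lc_diff <- function(fit_a, fit_b, level) {
  if (!inherits(fit_a, "ll2_fit") || !inherits(fit_b, "ll2_fit")) {
    abort("`fit_a` and `fit_b` must be `ll2_fit` objects.")
  }
  if (!fit_a$converged || !fit_b$converged) {
    abort("both fits must have converged to compare LC values.")
  }
  lc_quantile(fit_a$b, fit_a$e, level) - lc_quantile(fit_b$b, fit_b$e, level)
}

#' Permute salinity labels across the replicates of two groups
#'
#' Reassigns the two salinity labels to replicate records while keeping the
#' per-salinity sample sizes fixed. With `stratified = TRUE` (default)
#' labels are shuffled within each concentration stratum, so each
#' pseudo-treatment retains the complete concentration series; unstratified
#' shuffling permutes labels across the pooled replicate set and can
#' produce designs with empty strata that no curve can be fitted to.
#' Uses the session RNG: seed with `set.seed()` (or `withr::with_seed()`)
#' for reproducibility.
#'
#' @param data Replicate records of one compound at exactly the two
#'   salinities in `salinities`.
#' @param salinities Length-2 vector naming the two treatments.
#' @param stratified Shuffle within concentration strata (default `TRUE`).
#' @return `data` with its `salinity` column permuted.
#' @export
permute_salinity_labels <- function(data, salinities = NULL,
                                    stratified = TRUE) {
  prep <- prepare_two_groups(data, salinities, require_matched = stratified)
  idx <- draw_assignment(prep, stratified)
  out <- prep$data
  out$salinity <- prep$salinities[2]
  out$salinity[idx] <- prep$salinities[1]
  out
}

# Validate, subset and index a two-salinity comparison.  Returns the pooled
# records, the row indices currently labelled A, and the stratum structure
# used for stratified reassignment.
prepare_two_groups <- function(data, salinities = NULL, compound = NULL,
                               require_matched = TRUE) {
  if (!is.null(compound)) data <- data[data$compound == compound, ]
  if ("compound" %in% names(data) && length(unique(data$compound)) > 1) {
    abort("`data` holds several compounds; name one via `compound`.")
  }
  if (is.null(salinities)) salinities <- sort(unique(data$salinity))
  if (length(salinities) != 2) {
    abort("exactly two salinities are required for the comparison.")
  }
  data <- data[data$salinity %in% salinities, ]
  if (nrow(data) == 0) abort("no records for the requested groups.")
  a <- data$salinity == salinities[1]
  if (!any(a) || all(a)) abort("both salinity groups must be non-empty.")
  strata <- split(seq_len(nrow(data)), data$concentration)
  if (require_matched) {
    ok <- vapply(strata, function(ix) {
      na <- sum(a[ix])
      na > 0 && na < length(ix) && na == length(ix) - na
    }, logical(1))
    if (!all(ok)) {
      abort(paste("stratified permutation requires both groups to share the",
                  "same concentration series with equal replicate counts;",
                  "use stratified = FALSE for unmatched designs."))
    }
  }
  list(data = data, salinities = salinities, is_a = a, n_a = sum(a),
       strata = strata)
}

# Tie-robust tail count: ties count as extreme, and a relative tolerance
# keeps structurally tied assignments (e.g. the label swap, whose |diff|
# equals the observed one exactly in exact arithmetic) in the tail even when
# floating-point summation order perturbs the last bits.
tail_proportion <- function(null_diffs, observed) {
  tol <- 1e-8 * (1 + abs(observed))
  mean(abs(null_diffs) >= abs(observed) - tol)
}

# One random label assignment: indices of rows sent to pseudo-group A.
draw_assignment <- function(prep, stratified = TRUE) {
  if (stratified) {
    unlist(lapply(prep$strata, function(ix) sample(ix, sum(prep$is_a[ix]))),
           use.names = FALSE)
  } else {
    sample(seq_len(nrow(prep$data)), prep$n_a)
  }
}

# All distinct stratified assignments, as a list of index vectors; errors
# beyond `cap` assignments.
enumerate_assignments <- function(prep, cap = 200000) {
  per_stratum <- lapply(prep$strata, function(ix) {
    k <- sum(prep$is_a[ix])
    combn(ix, k, simplify = FALSE)
  })
  total <- prod(vapply(per_stratum, length, numeric(1)))
  if (total > cap) {
    abort(sprintf(paste("%.0f distinct assignments exceed the enumeration cap",
                        "(%d); use the Monte Carlo test."), total, cap))
  }
  grid <- expand.grid(lapply(per_stratum, seq_along), KEEP.OUT.ATTRS = FALSE)
  lapply(seq_len(nrow(grid)), function(r) {
    unlist(purrr::map2(per_stratum, as.integer(grid[r, ]),
                       function(ch, j) ch[[j]]),
           use.names = FALSE)
  })
}

# Fit both pseudo-groups of one assignment and return LC diffs per level,
# or NULL when either refit fails.
assignment_lc_diffs <- function(prep, idx_a, levels) {
  in_a <- logical(nrow(prep$data))
  in_a[idx_a] <- TRUE
  d <- prep$data
  fa <- ll2_fit_core(d$concentration[in_a], d$n_exposed[in_a], d$n_dead[in_a])
  if (!fa$converged) return(NULL)
  fb <- ll2_fit_core(d$concentration[!in_a], d$n_exposed[!in_a],
                     d$n_dead[!in_a])
  if (!fb$converged) return(NULL)
  lc_quantile_vec(exp(fa$theta[1]), exp(fa$theta[2]), levels) -
    lc_quantile_vec(exp(fb$theta[1]), exp(fb$theta[2]), levels)
}

#' Monte Carlo permutation test for LC differences between salinities
#'
#' Tests whether the LC values (by default LC10 and LC50) of one compound
#' differ between two salinity treatments. For each of `n_sim` permutations
#' the salinity labels are reassigned (stratified within concentration by
#' default, keeping per-salinity sample sizes fixed), both LL.2 curves are
#' refitted, and the LC difference is recorded; permutations where either
#' refit fails are excluded from the null distribution and counted. The
#' two-sided p-value is the proportion of successful permutations whose
#' absolute LC difference is at least the absolute observed difference
#' (ties count as extreme; no small-sample correction).
#'
#' With `exhaustive = TRUE` every distinct stratified assignment is visited
#' exactly once instead of sampling, which makes the Monte Carlo machinery
#' directly comparable with [exact_lc_test()].
#'
#' @param data Replicate records containing the compound at both
#'   salinities.
#' @param compound Compound to test; may be omitted when `data` holds a
#'   single compound.
#' @param salinities Length-2 salinity pair (default the two present).
#' @param levels Mortality fractions tested (default `c(0.10, 0.50)`).
#' @param n_sim Number of permutations `B` (default 5000).
#' @param seed Integer seed making the whole test reproducible.
#' @param stratified Permute within concentration strata (default `TRUE`).
#' @param exhaustive Enumerate all assignments instead of sampling.
#' @param min_converged_fraction Warn when fewer than this fraction of
#'   permutations yields two converged refits (default 0.95).
#' @param quiet Suppress progress messages (default `FALSE`; progress is
#'   reported every 500 permutations).
#' @return A tibble of class `lc_perm_test`, one row per level: `compound`,
#'   `level`, `observed_diff`, `p_value`, `n_sim`, `n_failed`, and the null
#'   differences as a list column `null_diffs`.
#' @export
monte_carlo_lc_test <- function(data, compound = NULL, salinities = NULL,
                                levels = c(0.10, 0.50), n_sim = 5000,
                                seed = NULL, stratified = TRUE,
                                exhaustive = FALSE,
                                min_converged_fraction = 0.95,
                                quiet = FALSE) {
  if (n_sim < 1) abort("`n_sim` must be >= 1.")
  if (any(levels <= 0) || any(levels >= 1)) abort("`levels` must be in (0, 1).")
  prep <- prepare_two_groups(data, salinities, compound,
                             require_matched = stratified)
  compound <- compound %||% unique(prep$data$compound)[1]
  d <- prep$data
  fa <- ll2_fit_core(d$concentration[prep$is_a], d$n_exposed[prep$is_a],
                     d$n_dead[prep$is_a])
  fb <- ll2_fit_core(d$concentration[!prep$is_a], d$n_exposed[!prep$is_a],
                     d$n_dead[!prep$is_a])
  if (!fa$converged || !fb$converged) {
    abort("observed fits did not converge; the permutation test is undefined.")
  }
  observed <- lc_quantile_vec(exp(fa$theta[1]), exp(fa$theta[2]), levels) -
    lc_quantile_vec(exp(fb$theta[1]), exp(fb$theta[2]), levels)
  assignments <- if (exhaustive) {
    enumerate_assignments(prep)
  } else {
    gen <- function() replicate(n_sim, draw_assignment(prep, stratified),
                                simplify = FALSE)
    if (is.null(seed)) gen() else withr::with_seed(seed, gen())
  }
  n_total <- length(assignments)
  null_diffs <- matrix(NA_real_, nrow = n_total, ncol = length(levels))
  for (i in seq_len(n_total)) {
    diffs <- assignment_lc_diffs(prep, assignments[[i]], levels)
    if (!is.null(diffs)) null_diffs[i, ] <- diffs
    if (!quiet && i %% 500 == 0) {
      message(sprintf("permutation %d / %d", i, n_total))
    }
  }
  ok <- !is.na(null_diffs[, 1])
  n_failed <- sum(!ok)
  if (all(!ok)) abort("every permuted refit failed; no null distribution.")
  if (mean(ok) < min_converged_fraction) {
    warn(sprintf("only %.1f%% of permutations produced converged refits.",
                 100 * mean(ok)))
  }
  out <- purrr::map_dfr(seq_along(levels), function(j) {
    nd <- null_diffs[ok, j]
    tibble::tibble(
      compound = compound, level = levels[j],
      salinity_a = prep$salinities[1], salinity_b = prep$salinities[2],
      observed_diff = observed[j],
      p_value = tail_proportion(nd, observed[j]),
      n_sim = n_total, n_failed = n_failed,
      null_diffs = list(nd))
  })
  structure(out, class = c("lc_perm_test", class(out)))
}

#' Exact permutation test by exhaustive enumeration
#'
#' Enumerates every distinct stratified label assignment (the product over
#' concentration strata of the binomial choices per stratum), refits both
#' curves for each, and computes the permutation p-value exactly under the
#' same two-sided tail rule as [monte_carlo_lc_test()]. Serves as the
#' oracle for the Monte Carlo procedure on small designs.
#'
#' @inheritParams monte_carlo_lc_test
#' @param cap Maximum number of assignments to enumerate (default 200000).
#' @return A tibble, one row per level: `level`, `observed_diff`,
#'   `p_value`, `n_assignments`, `n_failed`.
#' @export
exact_lc_test <- function(data, compound = NULL, salinities = NULL,
                          levels = c(0.10, 0.50), cap = 200000) {
  prep <- prepare_two_groups(data, salinities, compound,
                             require_matched = TRUE)
  compound <- compound %||% unique(prep$data$compound)[1]
  d <- prep$data

  # Independent machinery from the Monte Carlo path: full fit_ll2() fits and
  # an explicit odometer over the per-stratum label choices.
  diff_for <- function(rows_a) {
    rows_a <- sort(rows_a)  # canonical order: the statistic is set-valued
    fa <- tryCatch(fit_ll2(d[rows_a, ]), error = function(e) NULL)
    if (is.null(fa) || !fa$converged) return(NULL)
    fb <- tryCatch(fit_ll2(d[-rows_a, ]), error = function(e) NULL)
    if (is.null(fb) || !fb$converged) return(NULL)
    vapply(levels, function(p) {
      lc_quantile(fa$b, fa$e, p) - lc_quantile(fb$b, fb$e, p)
    }, numeric(1))
  }
  observed <- diff_for(which(prep$is_a))
  if (is.null(observed)) {
    abort("observed fits did not converge; the permutation test is undefined.")
  }

  choices <- lapply(prep$strata, function(ix) {
    combn(ix, sum(prep$is_a[ix]), simplify = FALSE)
  })
  n_per <- vapply(choices, length, numeric(1))
  total <- prod(n_per)
  if (total > cap) {
    abort(sprintf(paste("%.0f distinct assignments exceed the enumeration cap",
                        "(%d); use the Monte Carlo test."), total, cap))
  }
  odometer <- rep(1L, length(choices))
  nd <- matrix(NA_real_, nrow = total, ncol = length(levels))
  for (i in seq_len(total)) {
    rows_a <- unlist(purrr::map2(choices, odometer, function(ch, j) ch[[j]]),
                     use.names = FALSE)
    diffs <- diff_for(rows_a)
    if (!is.null(diffs)) nd[i, ] <- diffs
    for (k in seq_along(odometer)) {  # advance odometer
      odometer[k] <- odometer[k] + 1L
      if (odometer[k] <= n_per[k]) break
      odometer[k] <- 1L
    }
  }
  ok <- !is.na(nd[, 1])
  if (!any(ok)) abort("every enumerated refit failed; no null distribution.")
  purrr::map_dfr(seq_along(levels), function(j) {
    tibble::tibble(
      compound = compound, level = levels[j],
      observed_diff = observed[j],
      p_value = tail_proportion(nd[ok, j], observed[j]),
      n_assignments = as.integer(total), n_failed = sum(!ok))
  })
}
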