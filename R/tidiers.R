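# broom-style accessors for fitted objects.

#' Tidy an LL.2 fit
#'
#' One row per parameter (`b`, `e`) with natural-scale estimates.
#' Standard errors and Wald confidence limits are obtained on the
#' `(log b, log e)` scale, where the sampling distribution is closer to
#' normal, and mapped back by `exp()`; the natural-scale standard error is
#' `estimate * se_log`.
#'
#' @param x An `ll2_fit`.
#' @param conf_level Confidence level (default 0.95).
#' @param ... Unused.
#' @return A tibble with columns `term`, `estimate`, `std.error`,
#'   `conf.low`, `conf.high`.
#' @export
tidy.ll2_fit <- function(x, conf_level = 0.95, ...) {
  if (!x$converged) {
    return(tibble::tibble(term = c("b", "e"), estimate = NA_real_,
                          std.error = NA_real_, conf.low = NA_real_,
                          conf.high = NA_real_))
  }
  z <- qnorm(1 - (1 - conf_level) / 2)
  se_log <- sqrt(pmax(0, diag(x$vcov)))
  est <- c(x$b, x$e)
  tibble::tibble(
    term = c("b", "e"),
    estimate = est,
    std.error = est * se_log,
    conf.low = est * exp(-z * se_log),
    conf.high = est * exp(z * se_log))
}

#' One-row fit summary
#'
#' @param x An `ll2_fit`.
#' @param ... Unused.
#' @return A tibble: `logLik`, `null_loglik`, `pseudo_r2`, `n_obs`,
#'   `converged`.
#' @export
glance.ll2_fit <- function(x, ...) {
  tibble::tibble(logLik = x$loglik, null_loglik = x$null_loglik,
                 pseudo_r2 = x$pseudo_r2, n_obs = x$n_obs,
                 converged = x$converged)
}

#' Tidy a permutation-test result
#'
#' Drops the null-distribution list column, leaving one summary row per
#' LC level.
#'
#' @param x An `lc_perm_test`.
#' @param ... Unused.
#' @return A tibble without the `null_diffs` column.
#' @export
tidy.lc_perm_test <- function(x, ...) {
  tibble::as_tibble(x[setdiff(names(x), "null_diffs")])
}
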