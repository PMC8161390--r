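# Two-parameter log-logistic (LL.2) dose-response model with fixed asymptotes:
#   survival f(x) = 1 / (1 + (x / e)^b),  b > 0, e > 0,
# fitted to replicate-level binomial survival counts by maximum likelihood on
# the unconstrained (log b, log e) scale.

#' Two-parameter log-logistic survival curve
#'
#' Survival fraction at concentration `x` under the LL.2 model
#' `f(x) = 1 / (1 + (x/e)^b)` with lower asymptote 0 and upper asymptote 1
#' fixed. `f(0)` is defined as 1 by continuity (`b > 0`), so a zero
#' concentration encodes the solvent control. The curve is non-increasing in
#' `x`, equals 0.5 at `x = e`, and `e` is therefore the median lethal
#' concentration (LC50).
#'
#' @param x Concentration in mg/L, non-negative. Vectorised.
#' @param b Slope parameter, strictly positive.
#' @param e Inflection concentration (LC50) in mg/L, strictly positive.
#' @return Survival fraction in `[0, 1]`, same length as `x`.
#' @examples
#' ll2_survival(c(0, 1, 10), b = 2, e = 1)
#' @export
ll2_survival <- function(x, b, e) {
  check_ll2_params(b, e)
  if (any(!is.finite(x)) || any(x < 0)) {
    abort("`x` must be finite and non-negative (0 encodes the control).")
  }
  out <- rep(1, length(x))
  pos <- x > 0
  # computed on the logit scale for numerical stability at extreme x/e ratios
  out[pos] <- plogis(-b * (log(x[pos]) - log(e)))
  out
}

#' Binomial log-likelihood of an LL.2 curve on one treatment group
#'
#' Sums, over replicate records, the binomial log-likelihood
#' `(n_exposed - n_dead) * log f(x) + n_dead * log(1 - f(x))` with survival
#' probabilities clipped to `[eps, 1 - eps]` (`eps = 1e-12`) so that control
#' records, where `f(0) = 1`, contribute finitely even when control deaths
#' occur.
#'
#' @param data A data frame of replicate records for a single
#'   (compound, salinity) group with columns `concentration`, `n_exposed`,
#'   `n_dead`.
#' @inheritParams ll2_survival
#' @return The log-likelihood, a single non-positive number.
#' @examples
#' d <- tibble::tibble(concentration = 1, n_exposed = 2, n_dead = 1)
#' binom_loglik(d, b = 3, e = 1)  # 2 * log(0.5)
#' @export
binom_loglik <- function(data, b, e) {
  check_ll2_params(b, e)
  check_counts(data)
  f <- ll2_survival(data$concentration, b, e)
  f <- clip_prob(f)
  sum((data$n_exposed - data$n_dead) * log(f) + data$n_dead * log(1 - f))
}

PROB_EPS <- 1e-12

clip_prob <- function(p) pmin(pmax(p, PROB_EPS), 1 - PROB_EPS)

check_ll2_params <- function(b, e) {
  if (length(b) != 1 || length(e) != 1 || !is.finite(b) || !is.finite(e) ||
      b <= 0 || e <= 0) {
    abort("LL.2 parameters require scalar b > 0 and e > 0.")
  }
  invisible(NULL)
}

check_counts <- function(data) {
  need <- c("concentration", "n_exposed", "n_dead")
  miss <- setdiff(need, names(data))
  if (length(miss)) {
    abort(paste0("missing required column(s): ", paste(miss, collapse = ", ")))
  }
  if (nrow(data) == 0) abort("empty group: no replicate records.")
  bad <- which(data$n_dead < 0 | data$n_dead > data$n_exposed |
                 data$n_exposed <= 0)
  if (length(bad)) {
    abort(paste0("invalid counts (need 0 <= n_dead <= n_exposed, n_exposed > 0) ",
                 "at row(s): ", paste(head(bad, 5), collapse = ", ")))
  }
  invisible(NULL)
}

# Closures for the negative log-likelihood and its analytic gradient on
# theta = (log b, log e). Control records (x = 0) have f = 1 regardless of
# theta, so they enter as a constant and drop out of the gradient.
ll2_objective <- function(conc, n_exposed, n_dead) {
  pos <- conc > 0
  lnx <- log(conc[pos])
  alive <- (n_exposed - n_dead)[pos]
  dead <- n_dead[pos]
  const <- sum((n_exposed - n_dead)[!pos]) * log(1 - PROB_EPS) +
    sum(n_dead[!pos]) * log(PROB_EPS)
  negll <- function(theta) {
    b <- exp(theta[1])
    eta <- b * (lnx - theta[2])
    f <- clip_prob(plogis(-eta))
    -(sum(alive * log(f) + dead * log(1 - f)) + const)
  }
  neggrad <- function(theta) {
    b <- exp(theta[1])
    eta <- b * (lnx - theta[2])
    f <- plogis(-eta)
    # d loglik / d eta = -(alive * (1 - f) - dead * f)
    dl_deta <- -(alive * (1 - f) - dead * f)
    c(-sum(dl_deta * eta), sum(dl_deta) * b)
  }
  list(negll = negll, neggrad = neggrad, const = const)
}

# Deterministic initialisation: logit-linear regression of
# continuity-corrected survival proportions (alive + 0.5) / (n + 1) on ln x
# over the positive concentrations.  logit f = -b ln x + b ln e, so
# b0 = -slope and log e0 = intercept / b0.
ll2_init <- function(conc, n_exposed, n_dead) {
  pos <- conc > 0
  lnx <- log(conc[pos])
  s <- ((n_exposed - n_dead)[pos] + 0.5) / (n_exposed[pos] + 1)
  y <- qlogis(s)
  mx <- mean(lnx)
  sxx <- sum((lnx - mx)^2)
  slope <- sum((lnx - mx) * (y - mean(y))) / sxx
  intercept <- mean(y) - slope * mx
  b0 <- if (is.finite(slope) && slope < 0) -slope else 1
  le0 <- intercept / b0
  if (!is.finite(le0)) le0 <- median(lnx)
  c(log(b0), le0)
}

# Internal fast path: maximise the LL.2 likelihood, return parameters and
# convergence state only (no vcov / null model).  Used verbatim inside the
# permutation loop where thousands of refits are needed.
ll2_fit_core <- function(conc, n_exposed, n_dead, grad_tol = 1e-6,
                         max_iter = 500) {
  total_dead <- sum(n_dead)
  total_alive <- sum(n_exposed - n_dead)
  if (total_dead == 0 || total_alive == 0) {
    return(list(converged = FALSE, theta = c(NA_real_, NA_real_),
                loglik = NA_real_, reason = "no dose signal"))
  }
  obj <- ll2_objective(conc, n_exposed, n_dead)
  init <- ll2_init(conc, n_exposed, n_dead)
  opt <- tryCatch(
    optim(init, obj$negll, obj$neggrad, method = "L-BFGS-B",
          lower = c(-30, -30), upper = c(30, 30),
          control = list(maxit = max_iter, factr = 10)),
    error = function(e) NULL
  )
  if (is.null(opt) || any(!is.finite(opt$par))) {
    return(list(converged = FALSE, theta = c(NA_real_, NA_real_),
                loglik = NA_real_, reason = "optimizer failure"))
  }
  theta <- opt$par
  g <- obj$neggrad(theta)
  # Newton polish towards gradient-norm convergence
  iter <- 0
  while (sqrt(sum(g^2)) >= grad_tol && iter < 25) {
    H <- tryCatch(optimHess(theta, obj$negll, obj$neggrad),
                  error = function(e) NULL)
    step <- if (is.null(H)) NULL else tryCatch(solve(H, g),
                                               error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step))) break
    cand <- theta - step
    if (any(abs(cand) > 30) || obj$negll(cand) > obj$negll(theta) + 1e-9) break
    theta <- cand
    g <- obj$neggrad(theta)
    iter <- iter + 1
  }
  gnorm <- sqrt(sum(g^2))
  list(converged = is.finite(gnorm) && gnorm < grad_tol,
       theta = theta, loglik = -obj$negll(theta), gnorm = gnorm,
       init = init, init_loglik = -obj$negll(init),
       reason = if (is.finite(gnorm) && gnorm < grad_tol) NA_character_
                else "gradient tolerance not reached")
}

# Intercept-only binomial null: every record shares the pooled mortality
# fraction; closed form, probabilities clipped like the fitted model.
null_loglik_pooled <- function(n_exposed, n_dead) {
  p <- clip_prob(sum(n_dead) / sum(n_exposed))
  sum(n_dead) * log(p) + sum(n_exposed - n_dead) * log(1 - p)
}

#' Fit the two-parameter log-logistic model to one treatment group
#'
#' Maximises the binomial likelihood of [ll2_survival()] over
#' `(log b, log e)` with a quasi-Newton search from a deterministic
#' logit-regression start, so repeated fits of the same data are identical.
#' Convergence is declared when the gradient norm falls below `grad_tol`.
#' The result carries the observed-information covariance matrix on the
#' `(log b, log e)` scale, the intercept-only (pooled mortality) null
#' log-likelihood, and Nagelkerke's pseudo-R-squared with `n` equal to the
#' number of replicate records.
#'
#' Groups with no dose signal (zero deaths everywhere, or zero survivors
#' everywhere) cannot identify the curve; the fit is returned with
#' `converged = FALSE` and missing parameters rather than an error, so
#' callers such as the permutation test can account for failures.
#'
#' @param data A data frame of replicate records for a single
#'   (compound, salinity) group (columns `concentration`, `n_exposed`,
#'   `n_dead`; other columns are ignored).
#' @param grad_tol Gradient-norm convergence tolerance (default `1e-6`).
#' @param max_iter Maximum optimizer iterations (default 500).
#' @return An object of class `ll2_fit`: a list with elements `b`, `e`
#'   (natural scale), `theta` (`log b`, `log e`), `loglik`, `null_loglik`,
#'   `n_obs`, `vcov` (2x2, `(log b, log e)` scale), `pseudo_r2`, `converged`,
#'   and the data used. Methods: [tidy()], [glance()], [autoplot()],
#'   `print()`.
#' @seealso [lc_estimate()], [lc_quantile()], [nagelkerke_r2()]
#' @examples
#' study <- simulate_bioassay(
#'   sim_design(c(0, 0.01, 0.1, 1, 10, 100), organisms_per_replicate = 10,
#'              salinities = 5),
#'   treatment_truth(5, b = 2, e = 1), seed = 1)
#' fit <- fit_ll2(study)
#' glance(fit)
#' @export
fit_ll2 <- function(data, grad_tol = 1e-6, max_iter = 500) {
  check_counts(data)
  conc <- data$concentration
  if (!any(conc > 0)) abort("group has no positive concentrations.")
  core <- ll2_fit_core(conc, data$n_exposed, data$n_dead,
                       grad_tol = grad_tol, max_iter = max_iter)
  n_obs <- nrow(data)
  l0 <- null_loglik_pooled(data$n_exposed, data$n_dead)
  out <- list(
    b = NA_real_, e = NA_real_, theta = core$theta,
    loglik = core$loglik, null_loglik = l0, n_obs = n_obs,
    vcov = matrix(NA_real_, 2, 2,
                  dimnames = list(c("log_b", "log_e"), c("log_b", "log_e"))),
    pseudo_r2 = NA_real_, converged = core$converged,
    failure_reason = core$reason,
    compound = if ("compound" %in% names(data)) unique(data$compound)[1] else NA,
    salinity = if ("salinity" %in% names(data)) unique(data$salinity)[1] else NA,
    data = data
  )
  if (core$converged) {
    out$b <- exp(core$theta[1])
    out$e <- exp(core$theta[2])
    obj <- ll2_objective(conc, data$n_exposed, data$n_dead)
    H <- tryCatch(optimHess(core$theta, obj$negll, obj$neggrad),
                  error = function(e) NULL)
    V <- if (is.null(H)) NULL else tryCatch(solve(H), error = function(e) NULL)
    if (!is.null(V) && all(is.finite(V)) && all(diag(V) >= 0)) {
      V <- (V + t(V)) / 2
      dimnames(V) <- dimnames(out$vcov)
      out$vcov <- V
    } else {
      warn("observed-information matrix is singular; vcov unavailable.")
    }
    out$pseudo_r2 <- nagelkerke_r2(core$loglik, l0, n_obs)
  }
  structure(out, class = "ll2_fit")
}

#' @export
print.ll2_fit <- function(x, ...) {
  cat("Two-parameter log-logistic fit (binomial ML)\n")
  if (!is.na(x$compound[1])) {
    cat(sprintf("  group: %s @ %s PSU\n", x$compound, format(x$salinity)))
  }
  if (x$converged) {
    cat(sprintf("  b = %.4g, e (LC50) = %.4g mg/L\n", x$b, x$e))
    cat(sprintf("  logLik = %.4f (null %.4f, n = %d), pseudo-R2 = %.3f\n",
                x$loglik, x$null_loglik, x$n_obs, x$pseudo_r2))
  } else {
    cat(sprintf("  NOT CONVERGED (%s)\n", x$failure_reason))
  }
  invisible(x)
}

#' Lethal concentration LCp of an LL.2 curve
#'
#' Closed-form inversion of the LL.2 mortality curve: the concentration at
#' which a fraction `level` of organisms dies,
#' `LC_p = e * (p / (1 - p))^(1/b)`. At `level = 0.5` this is exactly `e`.
#'
#' @param b,e LL.2 parameters (slope, inflection), or pass a fitted
#'   [fit_ll2()] object as `b` and leave `e` missing.
#' @param level Mortality fraction `p` in (0, 1). Vectorised.
#' @return Concentration(s) in mg/L.
#' @examples
#' lc_quantile(b = 1, e = 1, level = 0.1)  # 1/9
#' @export
lc_quantile <- function(b, e, level) {
  if (inherits(b, "ll2_fit")) {
    fit <- b
    if (!fit$converged) abort("fit did not converge; LC values undefined.")
    if (missing(level) && !missing(e)) level <- e  # lc_quantile(fit, p)
    e <- fit$e
    b <- fit$b
  }
  check_ll2_params(b, e)
  if (any(!is.finite(level)) || any(level <= 0) || any(level >= 1)) {
    abort("`level` must lie strictly inside (0, 1).")
  }
  e * (level / (1 - level))^(1 / b)
}

#' LCp point estimate with delta-method standard error
#'
#' Propagates the `(log b, log e)` covariance of a converged [fit_ll2()]
#' through the closed form `log LC_p = log e + log(p/(1-p)) / b` by the delta
#' method. The gradient with respect to `(log b, log e)` is
#' `(-log(p/(1-p)) / b, 1)`, the confidence interval is
#' `exp(log LC_p +/- 1.96 * se_log)`, and the standard error is reported on
#' the concentration scale as `LC_p * se_log`.
#'
#' @param fit A converged `ll2_fit`.
#' @param level Mortality fraction(s) in (0, 1); default `c(0.10, 0.50)`.
#' @param conf_level Confidence level for the interval (default 0.95).
#' @return A tibble with one row per level: `level`, `value`, `se`,
#'   `ci_low`, `ci_high` (all concentrations in mg/L).
#' @export
lc_estimate <- function(fit, level = c(0.10, 0.50), conf_level = 0.95) {
  if (!inherits(fit, "ll2_fit")) abort("`fit` must be an `ll2_fit` object.")
  if (!fit$converged) {
    abort(paste("fit did not converge; no Wald LC interval is available",
                "(a resampling-based fallback is out of scope)."))
  }
  if (any(level <= 0) || any(level >= 1)) abort("`level` must be in (0, 1).")
  V <- fit$vcov
  if (any(!is.finite(V))) abort("fit has no covariance matrix; SE undefined.")
  z <- qnorm(1 - (1 - conf_level) / 2)
  purrr::map_dfr(level, function(p) {
    value <- lc_quantile(fit$b, fit$e, p)
    g <- c(-log(p / (1 - p)) / fit$b, 1)
    se_log <- sqrt(max(0, drop(t(g) %*% V %*% g)))
    tibble::tibble(
      level = p, value = value, se = value * se_log,
      ci_low = value * exp(-z * se_log), ci_high = value * exp(z * se_log)
    )
  })
}

#' Nagelkerke's pseudo-R-squared
#'
#' Rescaled likelihood-ratio goodness-of-fit index
#' `R2 = (1 - exp(-(2/n) (l1 - l0))) / (1 - exp((2/n) l0))`,
#' where `l1` is the fitted-model log-likelihood, `l0` the intercept-only
#' log-likelihood and `n` the number of binomial observations (replicate
#' records). Equals 0 when the model does not improve on the null and 1 for
#' a saturated model (`l1 = 0`); tiny negative numerical residue is clipped
#' to 0.
#'
#' @param loglik Fitted-model log-likelihood `l1` (non-positive).
#' @param null_loglik Null-model log-likelihood `l0`; must satisfy
#'   `loglik >= null_loglik - 1e-6`.
#' @param n_obs Number of observations `n`, at least 1.
#' @return A value in `[0, 1]`, or `NA` when `null_loglik == 0` exactly
#'   (degenerate null, denominator 0).
#' @examples
#' nagelkerke_r2(-3.0, -6.93, 10)
#' @export
nagelkerke_r2 <- function(loglik, null_loglik, n_obs) {
  if (n_obs < 1) abort("`n_obs` must be >= 1.")
  if (loglik < null_loglik - 1e-6) {
    abort("`loglik` must be >= `null_loglik` (the models are nested).")
  }
  if (null_loglik == 0) {
    warn("null log-likelihood is exactly 0; pseudo-R2 undefined.")
    return(NA_real_)
  }
  num <- 1 - exp(-(2 / n_obs) * (loglik - null_loglik))
  den <- 1 - exp((2 / n_obs) * null_loglik)
  min(1, max(0, num / den))
}
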