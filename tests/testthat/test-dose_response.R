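test_that("the LL.2 survival curve obeys its closed-form identities", {
  for (b in c(0.5, 2, 7)) expect_equal(ll2_survival(1.3, b, 1.3), 0.5)
  expect_equal(ll2_survival(0, 2, 1), 1)            # control, by continuity
  expect_equal(ll2_survival(10, 2, 1), 1 / 101)
  x <- sort(runif(50, 0, 50))
  f <- ll2_survival(x, 1.7, 3)
  expect_true(all(diff(f) <= 0))                    # non-increasing
  expect_true(all(f >= 0 & f <= 1))
  expect_error(ll2_survival(-1, 2, 1), "non-negative")
  expect_error(ll2_survival(1, -2, 1), "b > 0")
})

test_that("binom_loglik matches a term-by-term hand summation", {
  d <- tibble::tibble(concentration = 1, n_exposed = 2, n_dead = 1)
  expect_equal(binom_loglik(d, b = 3, e = 1), 2 * log(0.5))
  # all survivors at control: contribution ~ 0
  ctrl <- tibble::tibble(concentration = 0, n_exposed = 2, n_dead = 0)
  expect_equal(binom_loglik(ctrl, 2, 1), 0, tolerance = 1e-10)
  # brute-force oracle on random groups and parameters
  withr::with_seed(42, {
    for (i in 1:20) {
      g <- tibble::tibble(
        concentration = c(0, sort(runif(5, 0.01, 20))),
        n_exposed = sample(2:12, 6, replace = TRUE))
      g$n_dead <- vapply(g$n_exposed, function(n) sample(0:n, 1), integer(1))
      b <- runif(1, 0.3, 5); e <- runif(1, 0.05, 10)
      hand <- 0
      for (r in seq_len(nrow(g))) {
        f <- if (g$concentration[r] == 0) 1 else
          1 / (1 + (g$concentration[r] / e)^b)
        f <- min(max(f, 1e-12), 1 - 1e-12)
        hand <- hand + (g$n_exposed[r] - g$n_dead[r]) * log(f) +
          g$n_dead[r] * log(1 - f)
      }
      expect_equal(binom_loglik(g, b, e), hand)
    }
  })
})

test_that("lc_quantile inverts the curve in closed form", {
  expect_equal(lc_quantile(b = 2, e = 3.7, level = 0.5), 3.7)
  expect_equal(lc_quantile(b = 1, e = 1, level = 0.1), 1 / 9)
  # root-finding oracle at the 15 PSU LC50 scale
  lc10 <- lc_quantile(b = 2, e = 0.218, level = 0.1)
  expect_equal(lc10, 0.218 / 3)
  root <- uniroot(function(x) 1 - ll2_survival(x, 2, 0.218) - 0.1,
                  c(1e-8, 10), tol = 1e-14)$root
  expect_equal(lc10, root, tolerance = 1e-9)
  expect_error(lc_quantile(b = 2, e = 1, level = 1), "inside")
  expect_error(lc_quantile(b = 2, e = 1, level = 0), "inside")
})

test_that("inversion and monotonicity identities hold on a parameter grid", {
  grid <- expand.grid(b = c(0.3, 1, 2.5, 8), e = c(0.004, 1, 250),
                      p = c(0.01, 0.1, 0.5, 0.9, 0.99))
  for (i in seq_len(nrow(grid))) {
    with(grid[i, ], {
      lcp <- lc_quantile(b = b, e = e, level = p)
      expect_equal(1 - ll2_survival(lcp, b, e), p, tolerance = 1e-10)
    })
  }
  # lc_quantile strictly increasing in p
  p <- seq(0.05, 0.95, by = 0.05)
  expect_true(all(diff(lc_quantile(b = 1.4, e = 2, level = p)) > 0))
})

test_that("maximum likelihood fit agrees with an independent logit-glm", {
  # With fixed asymptotes, LL.2 survival is a logistic regression on ln x:
  # P(alive) = plogis(b0 + b1 ln x) with b = -b1, e = exp(b0 / b).  Controls
  # contribute a constant, so glm on the positive records is an independent
  # route to the same MLE.
  study <- simulate_bioassay(
    table1_design("triadimefon", organisms_per_replicate = 25, salinities = 5),
    treatment_truth(5, b = 2, e = 1), seed = 8)
  fit <- fit_ll2(study)
  pos <- study[study$concentration > 0, ]
  gfit <- glm(cbind(n_exposed - n_dead, n_dead) ~ log(concentration),
              family = binomial("logit"), data = pos)
  b_glm <- -unname(coef(gfit)[2])
  e_glm <- exp(unname(coef(gfit)[1]) / b_glm)
  expect_equal(fit$b, b_glm, tolerance = 1e-5)
  expect_equal(fit$e, e_glm, tolerance = 1e-5)
})

test_that("fit_ll2 is deterministic and dominates its initialization and null", {
  study <- simulate_bioassay(
    table1_design("dicloran", organisms_per_replicate = 10, salinities = 5),
    treatment_truth(5, b = 1.5, e = 0.09), seed = 13)
  f1 <- fit_ll2(study)
  f2 <- fit_ll2(study)
  expect_identical(f1$theta, f2$theta)
  expect_true(f1$converged)
  expect_gte(f1$loglik, f1$null_loglik - 1e-6)
  # likelihood at the optimum is at least the likelihood at the init
  core <- salinelc:::ll2_fit_core(study$concentration, study$n_exposed,
                                  study$n_dead)
  expect_gte(core$loglik, core$init_loglik)
  # vcov well-formed
  expect_equal(f1$vcov, t(f1$vcov))
  expect_true(all(diag(f1$vcov) >= 0))
})

test_that("groups without a dose signal are flagged, not fitted", {
  design <- table1_design("paraquat", organisms_per_replicate = 5,
                          salinities = 5)
  # truth far above the top concentration: essentially no deaths
  alive <- simulate_bioassay(design, treatment_truth(5, 2, 1e9), seed = 3)
  expect_equal(sum(alive$n_dead), 0)
  fit <- fit_ll2(alive)
  expect_false(fit$converged)
  expect_true(is.na(fit$b))
  expect_error(lc_estimate(fit), "converge")
})

test_that("rescaling concentrations rescales e and every LCp by the same factor", {
  study <- simulate_bioassay(
    table1_design("myclobutanil", organisms_per_replicate = 15, salinities = 5),
    treatment_truth(5, b = 2.2, e = 3.8), seed = 21)
  fit <- fit_ll2(study)
  for (c0 in c(0.01, 1000)) {
    scaled <- dplyr::mutate(study, concentration = concentration * c0)
    fs <- fit_ll2(scaled)
    # tolerance allows for optimizer wobble along the flat near-separation
    # ridge this steep fit sits on; the likelihood itself must be invariant
    expect_equal(fs$b, fit$b, tolerance = 1e-4)
    expect_equal(fs$e, fit$e * c0, tolerance = 1e-4)
    expect_equal(lc_quantile(fs, 0.1), lc_quantile(fit, 0.1) * c0,
                 tolerance = 1e-4)
    expect_equal(fs$loglik, fit$loglik, tolerance = 1e-8)
  }
})

test_that("delta-method LC standard errors behave as the closed form dictates", {
  study <- simulate_bioassay(
    table1_design("triadimefon", organisms_per_replicate = 10, salinities = 5),
    treatment_truth(5, b = 2, e = 1), seed = 30)
  fit <- fit_ll2(study)
  est <- lc_estimate(fit, level = c(0.1, 0.5))
  # at p = 0.5 the gradient collapses to (0, 1): se_log^2 = V[log e, log e]
  lc50 <- est[est$level == 0.5, ]
  expect_equal(lc50$se, fit$e * sqrt(fit$vcov["log_e", "log_e"]))
  # CI brackets the point estimate, positive throughout
  expect_true(all(est$ci_low > 0))
  expect_true(all(est$ci_low < est$value & est$value < est$ci_high))
  # degenerate zero-variance case
  fit0 <- fit
  fit0$vcov <- matrix(0, 2, 2, dimnames = dimnames(fit$vcov))
  est0 <- lc_estimate(fit0, 0.1)
  expect_equal(est0$se, 0)
  expect_equal(est0$ci_low, est0$value)
  expect_equal(est0$ci_high, est0$value)
})

test_that("Nagelkerke pseudo-R2 matches direct arithmetic and its bounds", {
  expect_equal(nagelkerke_r2(-5, -5, 12), 0)
  expect_equal(nagelkerke_r2(0, -6.93, 10), 1)
  hand <- (1 - exp(-(2 / 10) * (-3 - -6.93))) / (1 - exp((2 / 10) * -6.93))
  expect_equal(nagelkerke_r2(-3, -6.93, 10), hand)
  expect_equal(hand, 0.726, tolerance = 1e-3)
  expect_warning(out <- nagelkerke_r2(0, 0, 5), "undefined")
  expect_true(is.na(out))
  expect_error(nagelkerke_r2(-7, -5, 10), "nested")
})

test_that("tidy and glance expose the fit the broom way", {
  study <- simulate_bioassay(
    table1_design("triadimefon", organisms_per_replicate = 10, salinities = 5),
    treatment_truth(5, b = 2, e = 1), seed = 2)
  fit <- fit_ll2(study)
  td <- tidy(fit)
  expect_named(td, c("term", "estimate", "std.error", "conf.low", "conf.high"))
  expect_equal(td$term, c("b", "e"))
  expect_true(all(td$conf.low < td$estimate & td$estimate < td$conf.high))
  gl <- glance(fit)
  expect_equal(gl$n_obs, 36)
  expect_true(gl$converged)
  expect_gte(gl$pseudo_r2, 0)
  expect_lte(gl$pseudo_r2, 1)
})
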