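test_that("observed LC differences are antisymmetric and zero for equal curves", {
  fa <- fake_fit(b = 2, e = 1)
  expect_equal(observed_lc_diff(fa, fa, 0.5), 0)
  fb <- fake_fit(b = 3.1, e = 0.218)
  expect_equal(observed_lc_diff(fa, fb, 0.1),
               -observed_lc_diff(fb, fa, 0.1))
  # LC50 difference is e_A - e_B regardless of slopes
  expect_equal(observed_lc_diff(fake_fit(1.1, 2.74), fake_fit(4, 0.218), 0.5),
               2.522)
  bad <- fake_fit(2, 1); bad$converged <- FALSE
  expect_error(observed_lc_diff(fa, bad, 0.5), "converged")
})

test_that("stratified label permutation conserves the design", {
  study <- toy_study(seed = 1)
  withr::with_seed(4, {
    perm <- permute_salinity_labels(study)
    # per-stratum, per-salinity sizes unchanged
    sizes <- function(d) dplyr::count(d, concentration, salinity)
    expect_equal(sizes(perm), sizes(study))
  })
  # determinism under an identical seed
  p1 <- withr::with_seed(7, permute_salinity_labels(study))
  p2 <- withr::with_seed(7, permute_salinity_labels(study))
  expect_identical(p1, p2)
  # unmatched design: drop one 15 PSU replicate from a stratum
  unmatched <- study[-which(study$salinity == 15 &
                              study$concentration == 3)[1], ]
  expect_error(permute_salinity_labels(unmatched), "equal replicate counts")
  expect_silent(withr::with_seed(1,
    permute_salinity_labels(unmatched, stratified = FALSE)))
})

test_that("each replicate lands in either pseudo-group with frequency ~ 1/2", {
  study <- toy_study(seed = 2)
  n_draw <- 4000
  hits <- withr::with_seed(99, {
    rowSums(replicate(n_draw, {
      perm <- permute_salinity_labels(study)
      perm$salinity == 5
    }))
  })
  freq <- hits / n_draw
  expect_true(all(abs(freq - 0.5) < 0.05))
})

test_that("the Monte Carlo test is reproducible and accounts for every permutation", {
  study <- toy_study(seed = 11)
  r1 <- monte_carlo_lc_test(study, n_sim = 99, seed = 5, quiet = TRUE)
  r2 <- monte_carlo_lc_test(study, n_sim = 99, seed = 5, quiet = TRUE)
  expect_identical(tidy(r1), tidy(r2))
  expect_identical(r1$null_diffs, r2$null_diffs)
  expect_equal(r1$n_failed + lengths(r1$null_diffs), rep(99L, 2),
               ignore_attr = TRUE)
  expect_true(all(r1$p_value > 0 & r1$p_value <= 1))
})

test_that("a group compared against its own copy yields zero difference and p = 1", {
  g5 <- toy_study(seed = 8)
  g5 <- g5[g5$salinity == 5, ]
  copy <- g5
  copy$salinity <- 15
  study <- validate_bioassay(dplyr::bind_rows(g5, copy))
  res <- monte_carlo_lc_test(study, n_sim = 49, seed = 2, quiet = TRUE)
  expect_equal(res$observed_diff, c(0, 0))
  expect_equal(res$p_value, c(1, 1))
  ex <- exact_lc_test(study)
  expect_equal(ex$p_value, c(1, 1))
})

test_that("exhaustive enumeration visits exactly the combinatorial count", {
  study <- toy_study(seed = 3)
  ex <- exact_lc_test(study)
  expect_equal(unique(ex$n_assignments), choose(4, 2)^3)  # 216
  expect_error(exact_lc_test(study, cap = 100), "exceed")
})

test_that("Monte Carlo over the complete permutation set matches the exact oracle", {
  for (seed in c(11, 42)) {
    study <- toy_study(seed = seed)
    ex <- exact_lc_test(study)
    mc <- monte_carlo_lc_test(study, exhaustive = TRUE, quiet = TRUE)
    expect_identical(mc$p_value, ex$p_value)
    expect_equal(mc$observed_diff, ex$observed_diff, tolerance = 1e-9)
  }
})

test_that("non-convergent observed fits abort the test", {
  design <- sim_design(c(0, 0.3, 3), n_replicates = 2,
                       organisms_per_replicate = 20, salinities = c(5, 15))
  alive <- simulate_bioassay(design, treatment_truth(c(5, 15), 2, 1e9),
                             seed = 1)
  expect_error(monte_carlo_lc_test(alive, n_sim = 9, seed = 1, quiet = TRUE),
               "did not converge")
})

test_that("null p-values are approximately uniform", {
  # Under identical truth at both salinities the permutation p-value should
  # be (discretely) uniform; Kolmogorov-Smirnov at alpha = 0.01.
  design <- table1_design("triadimefon", organisms_per_replicate = 10)
  np <- run_null_and_power(design, treatment_truth(c(5, 15), 2, 1),
                           n_datasets = 100, n_sim = 99, seed = 17)
  p <- attr(np, "p_values")
  p50 <- p$p_value[p$level == 0.5 & !is.na(p$p_value)]
  ks <- suppressWarnings(ks.test(p50, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("rejection of a true LC50 shift grows with the size of the shift", {
  design <- table1_design("triadimefon", organisms_per_replicate = 10)
  null_tr <- treatment_truth(c(5, 15), 2, 1)
  np <- run_null_and_power(
    design, null_tr,
    truth_alt = list(ratio_2 = treatment_truth(c(5, 15), 2, c(1, 0.5)),
                     ratio_10 = treatment_truth(c(5, 15), 2, c(1, 0.1))),
    n_datasets = 200, n_sim = 199, seed = 23)
  r50 <- np[np$level == 0.5, ]
  rates <- r50$rejection_rate[match(c("null", "ratio_2", "ratio_10"),
                                    r50$scenario)]
  expect_true(all(diff(rates) >= 0))
  expect_lt(rates[1], rates[3])
})
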