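---
title: "Dose-response curves, LC estimation and the salinity permutation test"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dose-response curves, LC estimation and the salinity permutation test}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(salinelc)
```

## The model and its assumptions

`salinelc` analyses replicate-level acute-toxicity survival tables: one row
per exposure well, carrying compound, salinity (PSU), nominal concentration
(mg/L, with 0 encoding the solvent control), organisms exposed and organisms
dead. Survival follows the two-parameter log-logistic curve

$$f(x) = \frac{1}{1 + (x/e)^b}, \qquad b > 0,\; e > 0,$$

with the lower asymptote fixed at 0 and the upper at 1: every organism is
assumed to survive at zero dose and to die at infinite dose over the test
duration. The parameter $e$ is the inflection and therefore the LC50; $b$
controls steepness. Deaths per well are binomial,
$n_\text{dead} \sim \mathrm{Bin}(n_\text{exposed},\, 1 - f(x))$, i.e. the
replicate is the modelling unit and organisms within a well are treated as
independent — no overdispersion or shared-frailty term, which mirrors the
likelihood being fitted. Fixing the upper asymptote means no Abbott
correction for natural control mortality: control wells contribute a
constant to the likelihood, and substantial control mortality would be a
model violation worth catching in QC rather than absorbing silently.

Lethal concentrations come from the closed-form inversion
$\mathrm{LC}_p = e\,(p/(1-p))^{1/b}$; at $p = 0.5$ this is $e$ exactly.
Standard errors are delta-method: with
$\log \mathrm{LC}_p = \log e + \log(p/(1-p))/b$, the gradient with respect
to $(\log b, \log e)$ is $(-\log(p/(1-p))/b,\ 1)$, variance
$g^\top V g$ with $V$ the observed-information covariance, confidence
limits $\exp(\log \mathrm{LC}_p \pm 1.96\,\mathrm{se}_{\log})$, and the
concentration-scale standard error $\mathrm{LC}_p \cdot \mathrm{se}_{\log}$.

Goodness of fit is Nagelkerke's pseudo-$R^2$ with $\ell_0$ the
intercept-only (pooled mortality) binomial log-likelihood and $n$ the
number of replicate records. Using records rather than organisms as $n$ is
a genuine choice — the records are the binomial observations the likelihood
is a product over — and it is the conservative one, since smaller $n$
shrinks the index less.

## Numerical choices

Fitting maximises the binomial likelihood over $(\log b, \log e)$, which
enforces positivity without constraints. The initialisation is
deterministic — a logit-linear regression of continuity-corrected survival
proportions $(\text{alive} + 0.5)/(n + 1)$ on $\ln x$ over the positive
concentrations — so identical data always produce identical fits. The
search is L-BFGS-B (bounds $\pm 30$ on both log parameters, a box no
realistic bioassay approaches) followed by Newton polishing; convergence is
declared when the gradient norm falls below $10^{-6}$. Survival
probabilities are clipped to $[\varepsilon, 1-\varepsilon]$ with
$\varepsilon = 10^{-12}$ so control records ($f = 1$) and extreme doses
stay finite; the clip is far below the resolution of any feasible design
and does not move estimates. Groups with no dose signal — zero deaths
everywhere or zero survivors everywhere — cannot identify the curve and are
returned as non-converged fits with missing parameters; callers decide what
to do, and the pipeline flags the group and continues. Near-complete
separation (a jump from full survival to full death between adjacent
concentrations) drives $\hat b$ large along a flat likelihood ridge; the
gradient criterion still stops, but such fits carry wide slope intervals,
which is the honest answer at this design size.

## The permutation test

Whether LC10 or LC50 differs between two salinities is tested by
randomisation: salinity labels are reassigned to replicates, both curves
are refitted, and the LC difference is recomputed; the p-value is the
proportion of permutations whose $|\Delta \mathrm{LC}|$ is at least the
observed one. Three conventions deserve explanation.

* **Two-sided tail.** The scientific question — does toxicity differ with
  salinity — is directionless, so the tail rule uses absolute differences.
* **Ties count as extreme** ($\ge$), the conservative choice. Because
  refits of equivalent record sets can differ in their last bits, the tail
  comparison uses a relative tolerance of $10^{-8}$ so that structurally
  tied assignments (the full label swap, for instance, whose difference is
  exactly the negated observed one) are always counted. Without this, the
  discreteness of small designs makes the p-value depend on floating-point
  summation order.
* **Stratified by concentration** (default). Both salinity groups share a
  concentration series, and shuffling within each concentration stratum
  guarantees every pseudo-treatment retains the full design; unstratified
  shuffling can produce unfittable pseudo-groups (an empty stratum) and is
  kept behind a flag for comparison. Permutations where either refit fails
  are excluded from the null distribution and reported (`n_failed`), and a
  warning fires when fewer than 95% of permutations converge. The p-value
  denominator is the successful-permutation count — no $+1$ correction, a
  literal proportion.

`exact_lc_test()` is the oracle: it enumerates every distinct stratified
assignment (the product over strata of $\binom{n_A + n_B}{n_A}$ choices,
capped at 200,000) through an independent code path — full `fit_ll2()`
fits and an odometer enumeration rather than the sampling machinery — and
must agree exactly with `monte_carlo_lc_test(exhaustive = TRUE)`. Subsets
are always evaluated in canonical (ascending row) order so the statistic is
a function of the record set, not of enumeration order.

## What the synthetic generator emulates — and what it does not

`table1_design()` reproduces the study design the package targets: per
compound, five positive concentrations spanning four orders of magnitude
plus a solvent control, six replicates of two organisms per concentration,
at 5 and 15 PSU. `simulate_bioassay()` draws replicate-level binomial
deaths from known true curves, so recovery of $(b, e)$, the test's type-I
error, and its power are all checkable without any external data. The
generator intentionally omits features of real bioassays: no daily
mortality structure (terminal counts only), no natural control mortality,
no chemistry degradation between water changes, no between-replicate
heterogeneity (an optional beta-binomial knob exists, off by default, for
robustness experiments). Passing tests therefore demonstrate that the
estimator and test do what they claim **under the binomial model at this
design**, not that real data satisfy that model.

Two experiment scales appear in the validation suite, chosen once:

* **Recovery** runs at 60 replicates × 10 organisms per concentration
  (200 datasets): at the native 6 replicate × 2 organism design, sampling noise dominates
  and non-convergence is common by chance, so correctness of the code is
  checked where the estimator should be accurate — and the 6-replicate
  design is checked separately for the coarser property that RMSE falls as
  organisms grow over {2, 10, 50}.
* **Calibration and power** run at 6 replicates × 10 organisms, 200
  datasets with $B = 199$ permutations each: enough for a binomial
  95% band of roughly $\pm 0.03$ around a 0.05 rejection rate, while a
  ten-fold LC50 shift — the effect scale the design was built to flag — is
  detected with power near 1. A two-fold shift, by contrast, is mostly
  missed at this sample size (the README's worked example shows one at
  $p = 0.14$), which is a fact about the design, not a defect of the test.

## Design decisions that were genuinely open

* **Parameterisation.** Dose-response software often writes the logistic
  exponent with a sign convention tied to increasing response; this package
  fixes survival $= 1/(1 + (x/e)^b)$ with $b > 0$ for decreasing survival,
  making $\mathrm{LC}_p$ closed-form and unambiguous.
* **Column mapping, not fixed headers.** Deposited bioassay tables rarely
  share column names, so `read_bioassay_table()` takes a mapping config; a
  control-flag column, if mapped, must agree with the zero-concentration
  encoding.
* **Seeding.** Every stochastic routine takes an explicit seed and derives
  per-dataset or per-compound sub-seeds deterministically, so whole
  analyses are reproducible byte-for-byte regardless of execution order.
* **Terminal counts.** Survival is consumed as end-of-test counts; daily
  observation records must be collapsed by the user first. Time-to-event
  modelling is out of scope.

## Known limitations

Non-converged fits have no Wald intervals and no bootstrap fallback;
3- and 4-parameter log-logistic variants, hormesis, and model selection are
out of scope; the permutation p-values are not multiplicity-corrected
across compounds or LC levels; and LC estimates refer to nominal
concentrations — the chemistry QC (`qc_table()`) quantifies how far
measured concentrations sat from nominal (58% and 56.4% of nominal for the
two SPE-extracted compounds in the bundled check table) but no correction
is propagated into the fits.
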