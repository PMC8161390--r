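# Shared fixtures, built in code.

# A small two-salinity study on a 3-point series (control + 2 positive),
# 2 replicates per concentration per salinity: 216 distinct stratified
# assignments, enumerable exactly.
toy_study <- function(seed = 11, e15 = 0.4, organisms = 20) {
  simulate_bioassay(
    sim_design(c(0, 0.3, 3), n_replicates = 2,
               organisms_per_replicate = organisms, salinities = c(5, 15)),
    treatment_truth(c(5, 15), b = 2, e = c(1, e15)), seed = seed)
}

# A full-design two-compound study (6 concentrations x 6 replicates x 2
# salinities) with enough organisms per well for reliable fits.
two_compound_study <- function(seed = 5, organisms = 10) {
  dplyr::bind_rows(
    simulate_bioassay(
      table1_design("triadimefon", organisms_per_replicate = organisms),
      treatment_truth(c(5, 15), b = 2, e = c(1, 0.5)), seed = seed),
    simulate_bioassay(
      table1_design("dicloran", organisms_per_replicate = organisms),
      treatment_truth(c(5, 15), b = 1.5, e = c(0.09, 0.05)), seed = seed + 1))
}

# A bare ll2_fit carrying only what LC arithmetic needs; vcov zero.
fake_fit <- function(b, e) {
  structure(list(b = b, e = e, theta = c(log(b), log(e)),
                 loglik = -1, null_loglik = -2, n_obs = 10,
                 vcov = matrix(0, 2, 2), pseudo_r2 = 0.5,
                 converged = TRUE, compound = "x", salinity = 5),
            class = "ll2_fit")
}
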