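# Shared study setup for the numbered analysis scripts: one simulated
# source population, frozen percentile reference, population incidence
# curve, and the case-control analysis cohort. Everything is deterministic
# given the seeds below; re-running any script reproduces its outputs
# byte-for-byte.

library(phstrat)

COHORT_SEED <- 11L     # source population
SAMPLING_SEED <- 12L   # case-control subsampling
BOOT_SEED <- 13L       # bootstrap confidence intervals
N_POPULATION <- 40000L
TARGET_CASE_FRACTION <- 0.62
N_BOOT <- 200L

dir.create("results", showWarnings = FALSE)

study <- local({
  cfg <- sim_config(n_individuals = N_POPULATION, seed = COHORT_SEED)
  coh <- simulate_cohort(cfg)
  scores <- compute_phs(coh$genotypes, coh$weights)
  ph <- coh$phenotypes
  # percentile anchors frozen from young men without prostate cancer
  ref <- build_percentile_reference(
    scores[ph$case == 0 & ph$age_followup < 70])
  incidence <- population_incidence(ph)
  cohort <- sample_case_control(ph, TARGET_CASE_FRACTION,
                                seed = SAMPLING_SEED)
  list(config = cfg, cohort_full = coh, population = ph, scores = scores,
       ref = ref, incidence = incidence, cohort = cohort,
       cohort_scores = scores[cohort$individual_id])
})
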