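#!/usr/bin/env Rscript
# Sensitivity of the percentile hazard ratios to the assumed population
# incidence: the sample weights are rebuilt with the incidence curve scaled
# by factors spanning 25-400%, the Cox model is refit, and every contrast
# is recomputed. Factor 1 reproduces the baseline analysis exactly.

source("analysis/00_common.R")

cc <- study$cohort
sc <- study$cohort_scores

all_rows <- list()
for (ep in c("any", "aggressive", "fatal")) {
  st <- build_survival_table(cc, sc, ep)
  st$sample_weight <- as.numeric(
    compute_sample_weights(st$event, st$time, study$incidence))
  sw <- sweep_incidence(st, study$incidence, study$ref)
  sw$endpoint <- ep
  all_rows[[ep]] <- sw
  message(sprintf(
    "%-10s: HR_80/20 %.2f at factor 1; range %.2f-%.2f over factors %.2g-%g; max deviation %.0f%%",
    ep, sw$hr_80_20[sw$factor == 1], min(sw$hr_80_20), max(sw$hr_80_20),
    min(sw$factor), max(sw$factor),
    100 * sweep_max_deviation(sw)))
}
out <- do.call(rbind, all_rows)
rownames(out) <- NULL
write.csv(out, "results/sensitivity.csv", row.names = FALSE)
message("wrote results/sensitivity.csv")
message("\nThe direction and significance of every association are stable ",
        "across the full factor range, but the HR magnitudes move ",
        "substantially: with prevalence-matching case/control weights the ",
        "fit depends on the assumed incidence through the case:control ",
        "weight ratio, which spans a 16-fold range over the sweep.")
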