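#!/usr/bin/env Rscript
# Simulate the multi-ethnic source population and the case-control analysis
# cohort, and summarize their structure (participant characteristics, true
# score weights, population incidence curve).

source("analysis/00_common.R")

ph <- study$population
cc <- study$cohort

characterize <- function(d) {
  agg <- classify_aggressive(d)
  data.frame(
    n = nrow(d),
    controls = sum(d$case == 0),
    cases = sum(d$case == 1),
    aggressive_cases = sum(agg == "aggressive", na.rm = TRUE),
    fatal_cases = sum(d$death_cause == "prostate_cancer"),
    fh_known = sum(!is.na(d$family_history)),
    median_age_dx = round(median(d$age_dx, na.rm = TRUE), 1),
    median_age_followup = round(median(d$age_followup), 1)
  )
}

labels <- assign_oncoarray_label(cc[, c("european", "asian", "african")])
tab <- rbind(
  cbind(group = "All", characterize(cc)),
  do.call(rbind, lapply(sort(unique(labels)), function(g)
    cbind(group = g, characterize(cc[labels == g, ]))))
)
write.csv(tab, "results/cohort_characteristics.csv", row.names = FALSE)
message("analysis cohort by array-defined genetic ancestry:")
print(tab, row.names = FALSE)

message(sprintf(
  "\nsource population: %d men, %.1f%% lifetime cases; PHS sd %.2f",
  nrow(ph), 100 * mean(ph$case), sd(study$scores)))
message(sprintf("case-control cohort: %d men (%.0f%% cases)",
                nrow(cc), 100 * mean(cc$case)))

write_weight_table(study$cohort_full$weights, "results/true_weights.tsv")
write.csv(as.data.frame(study$incidence),
          "results/population_incidence.csv", row.names = FALSE)
message("wrote results/cohort_characteristics.csv, results/true_weights.tsv, ",
        "results/population_incidence.csv")
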