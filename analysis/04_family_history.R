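#!/usr/bin/env Rscript
# Joint model of first-degree family history and PHS for age at any
# prostate cancer diagnosis, overall and per genetic-ancestry stratum, on
# the subset with known family history. Reports the multivariable
# coefficients, the family-history HR (exponentiated beta), the PHS HR as
# the 80/20 percentile contrast, and the likelihood-ratio comparison of
# the joint model against family history alone.

source("analysis/00_common.R")

cc <- study$cohort
cc$ancestry_label <- assign_oncoarray_label(
  cc[, c("european", "asian", "african")])
st <- build_survival_table(cc, study$cohort_scores, "any")
st$ancestry_label <- cc$ancestry_label
st$sample_weight <- as.numeric(
  compute_sample_weights(st$event, st$time, study$incidence))

rows <- list()
for (g in c("All", sort(unique(st$ancestry_label)))) {
  d <- if (g == "All") st else st[st$ancestry_label == g, ]
  if (sum(d$event[!is.na(d$family_history)]) < 50) {
    message(g, ": too few events with known family history; skipped")
    next
  }
  d$sample_weight <- as.numeric(
    compute_sample_weights(d$event, d$time, study$incidence))
  fm <- family_history_model(d, study$ref)
  rows[[g]] <- data.frame(
    stratum = g, n = fm$n, variable = fm$table$variable,
    beta = fm$table$beta, z = fm$table$z, log10_p = fm$table$log10_p,
    hr = fm$table$hr, lr_statistic = fm$lr$statistic,
    lr_log10_p = fm$lr$log10_p)
  message(sprintf(
    "%-9s (n = %5d): FH beta %.2f (HR %.2f), PHS HR_80/20 %.2f; joint vs FH-only LR %.0f (log10 p %.1f)",
    g, fm$n, fm$table$beta[2], fm$table$hr[2], fm$table$hr[1],
    fm$lr$statistic, fm$lr$log10_p))
}
out <- do.call(rbind, rows)
rownames(out) <- NULL
write.csv(out, "results/family_history.csv", row.names = FALSE)
message("wrote results/family_history.csv")
message("\nIn this generator family history is a noisy correlate of the ",
        "score with no direct effect, so its conditional coefficient is ",
        "near zero once PHS enters the model; the joint model still beats ",
        "family history alone decisively because PHS carries the signal.")
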