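#' Classify prostate cancer cases as aggressive
#'
#' Aggressive disease is any of: Gleason score >= 7, PSA >= 10 ng/mL,
#' clinical stage T3-T4, nodal metastases (N1), or distant metastases (M1).
#' Because the criteria form a disjunction, a single met criterion
#' classifies a case as aggressive even when other fields are missing; a
#' case is `unevaluable` only when no recorded field decides and at least
#' one field is missing. Controls are returned as `NA`.
#'
#' @param phenotypes phenotype `data.frame` with columns `case`, `gleason`,
#'   `psa`, `t_stage`, `n_stage`, `m_stage` (stage fields as character,
#'   e.g. "T2", "N0", "M1"; `NA` allowed everywhere).
#' @return character vector: `"aggressive"`, `"non_aggressive"`,
#'   `"unevaluable"` for cases; `NA` for controls.
#' @export
classify_aggressive <- function(phenotypes) {
  need <- c("case", "gleason", "psa", "t_stage", "n_stage", "m_stage")
  if (!all(need %in% names(phenotypes)))
    stop("phenotype table lacks columns: ",
         paste(setdiff(need, names(phenotypes)), collapse = ", "))
  t34 <- phenotypes$t_stage %in% c("T3", "T4")
  t34[is.na(phenotypes$t_stage)] <- NA
  crit <- cbind(
    phenotypes$gleason >= 7,
    phenotypes$psa >= 10,
    t34,
    phenotypes$n_stage == "N1",
    phenotypes$m_stage == "M1"
  )
  any_met <- apply(crit, 1, function(r) isTRUE(any(r, na.rm = TRUE)))
  any_missing <- apply(crit, 1, anyNA)
  out <- ifelse(any_met, "aggressive",
                ifelse(any_missing, "unevaluable", "non_aggressive"))
  out[phenotypes$case != 1] <- NA_character_
  out
}

#' Build a survival table for a given endpoint
#'
#' Maps a phenotype table and per-individual scores to the (time, event)
#' pairs each endpoint needs; individuals not meeting the endpoint are
#' censored at age of last follow-up.
#'
#' * `any`: event = prostate cancer case; time = age at diagnosis, controls
#'   censored at last follow-up.
#' * `aggressive`: event = aggressive case; time = age at diagnosis;
#'   unevaluable cases are excluded (the analysis requires known stage,
#'   Gleason and PSA); non-aggressive cases are censored at last follow-up.
#' * `fatal`: event = death from prostate cancer; time = age at death,
#'   everyone else (including cases, regardless of staging completeness,
#'   and deaths from other causes) censored at last follow-up.
#'
#' @param phenotypes phenotype `data.frame` (see
#'   [simulate_survival_phenotypes()] for the column contract).
#' @param scores named numeric PHS vector covering every phenotype row.
#' @param endpoint one of `"any"`, `"aggressive"`, `"fatal"`.
#' @return `data.frame` with `individual_id`, `time`, `event`, `phs`, plus
#'   pass-through columns `family_history` and `ancestry` when present.
#' @export
build_survival_table <- function(phenotypes, scores,
                                 endpoint = c("any", "aggressive", "fatal")) {
  endpoint <- match.arg(endpoint)
  ph <- phenotypes
  if (is.null(names(scores))) {
    stopifnot(length(scores) == nrow(ph))
  } else {
    miss <- setdiff(ph$individual_id, names(scores))
    if (length(miss))
      stop("no score for individuals: ",
           paste(utils::head(miss, 5), collapse = ", "),
           if (length(miss) > 5) " ...")
    scores <- scores[ph$individual_id]
  }
  bad_case <- ph$case == 1 & is.na(ph$age_dx)
  if (any(bad_case))
    stop("cases with missing age at diagnosis: ",
         paste(utils::head(ph$individual_id[bad_case], 5), collapse = ", "))
  if (anyNA(ph$age_followup))
    stop("missing age at last follow-up for: ",
         paste(utils::head(ph$individual_id[is.na(ph$age_followup)], 5),
               collapse = ", "))
  keep <- rep(TRUE, nrow(ph))
  if (endpoint == "any") {
    event <- ph$case
    time <- ifelse(ph$case == 1, ph$age_dx, ph$age_followup)
  } else if (endpoint == "aggressive") {
    cls <- classify_aggressive(ph)
    keep <- !(ph$case == 1 & cls %in% "unevaluable")
    event <- as.integer(ph$case == 1 & cls %in% "aggressive")
    time <- ifelse(event == 1, ph$age_dx, ph$age_followup)
    if (sum(event[keep]) == 0)
      stop("aggressive endpoint: no evaluable aggressive cases in cohort")
  } else {
    event <- as.integer(ph$death_cause %in% "prostate_cancer")
    time <- ifelse(event == 1, ph$age_death, ph$age_followup)
    if (any(event == 1 & is.na(ph$age_death)))
      stop("prostate-cancer deaths with missing age at death")
  }
  out <- data.frame(individual_id = ph$individual_id,
                    time = time, event = event,
                    phs = as.numeric(scores),
                    stringsAsFactors = FALSE)
  for (col in c("family_history", "ancestry", "ancestry_label"))
    if (col %in% names(ph)) out[[col]] <- ph[[col]]
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Joint model of family history and PHS
#'
#' On the subset with known family history, fits a family-history-only
#' weighted Cox model and a joint family-history + PHS model, and compares
#' them by likelihood-ratio test. The family-history hazard ratio is the
#' exponent of its coefficient from the multivariable fit; the PHS hazard
#' ratio is reported as the 80/20 percentile contrast from the same fit.
#'
#' @param data survival `data.frame` with `time`, `event`, `phs`,
#'   `family_history` (0/1 or `NA`), optional `sample_weight`.
#' @param ref a [build_percentile_reference()] for the 80/20 contrast.
#' @return list with `fit_fh` (nested), `fit_full`, `lr`
#'   ([lr_test()] result), `n`, and `table`: a `data.frame` of beta, z,
#'   log10_p and HR per variable (PHS row carries the 80/20 HR).
#' @export
family_history_model <- function(data, ref) {
  stopifnot(all(c("family_history", "phs") %in% names(data)))
  sub <- data[!is.na(data$family_history), , drop = FALSE]
  if (!nrow(sub)) stop("no individuals with known family history")
  fit_fh <- fit_weighted_cox(sub, covariates = "family_history")
  fit_full <- fit_weighted_cox(sub, covariates = c("family_history", "phs"))
  lr <- lr_test(fit_fh, fit_full)
  bins <- assign_percentile_bins(sub$phs, ref)
  hr_phs <- hazard_ratio_between_groups(fit_full, sub$phs, bins,
                                        c("80", "20"))
  tab <- data.frame(
    variable = c("phs", "family_history"),
    beta = unname(fit_full$coefficients[c("phs", "family_history")]),
    z = unname(fit_full$z[c("phs", "family_history")]),
    log10_p = unname(fit_full$log10_p[c("phs", "family_history")]),
    hr = c(hr_phs, unname(exp(fit_full$coefficients["family_history"]))),
    stringsAsFactors = FALSE
  )
  list(fit_fh = fit_fh, fit_full = fit_full, lr = lr, n = nrow(sub),
       table = tab)
}

#' Run the full PHS analysis on a cohort
#'
#' Orchestrates one endpoint analysis: builds the survival table, attaches
#' incidence-corrected sample weights, fits the overall weighted Cox model,
#' produces the percentile hazard-ratio report for the whole cohort and
#' (optionally) per ancestry stratum, and runs the incidence sensitivity
#' sweep. Deterministic given `seed`.
#'
#' @param phenotypes phenotype table.
#' @param scores named PHS vector.
#' @param ref percentile reference (frozen from a designated reference
#'   cohort).
#' @param incidence population [incidence_curve()].
#' @param endpoint `"any"`, `"aggressive"` or `"fatal"`.
#' @param stratify `"none"` or the name of a label column in `phenotypes`
#'   (e.g. `"ancestry"`); strata with fewer than `min_stratum_events`
#'   events are skipped with a message. The fatal endpoint is conventionally
#'   run unstratified (event counts are low); stratification remains
#'   available by passing a column name.
#' @param n_boot bootstrap replicates for HR confidence intervals (0 skips
#'   CIs).
#' @param seed integer seed for the bootstrap.
#' @param sensitivity_factors incidence multipliers for the sensitivity
#'   sweep; `NULL` skips the sweep.
#' @param min_stratum_events minimum events for a stratum fit (default 10).
#' @return list of class `phs_analysis`: `report` (one row per stratum plus
#'   "All"), `sensitivity` (sweep table or `NULL`), `fit` (overall
#'   `phs_coxfit`), `provenance` (seed, endpoint, n, package version).
#' @export
run_phs_analysis <- function(phenotypes, scores, ref, incidence,
                             endpoint = "any", stratify = "none",
                             n_boot = 0, seed = 1,
                             sensitivity_factors = NULL,
                             min_stratum_events = 10) {
  surv <- build_survival_table(phenotypes, scores, endpoint)
  surv$sample_weight <- as.numeric(
    compute_sample_weights(surv$event, surv$time, incidence))
  fit <- fit_weighted_cox(surv, covariates = "phs")
  report <- hr_report(surv, ref, stratum = "All", n_boot = n_boot,
                      seed = seed)
  if (!identical(stratify, "none")) {
    if (!stratify %in% names(surv))
      stop("stratification column not found: ", stratify)
    for (g in sort(unique(surv[[stratify]]))) {
      d <- surv[surv[[stratify]] == g, , drop = FALSE]
      if (sum(d$event) < min_stratum_events) {
        message("stratum ", g, ": fewer than ", min_stratum_events,
                " events; skipped")
        next
      }
      d$sample_weight <- as.numeric(
        compute_sample_weights(d$event, d$time, incidence))
      report <- rbind(report,
                      hr_report(d, ref, stratum = as.character(g),
                                n_boot = n_boot, seed = seed))
    }
  }
  sens <- if (!is.null(sensitivity_factors))
    sweep_incidence(surv, incidence, ref, factors = sensitivity_factors)
  structure(list(
    report = report,
    sensitivity = sens,
    fit = fit,
    provenance = list(endpoint = endpoint, stratify = stratify,
                      n = nrow(surv), n_events = sum(surv$event),
                      n_boot = n_boot, seed = seed,
                      package_version = as.character(
                        utils::packageVersion("phstrat")))
  ), class = "phs_analysis")
}

#' @export
print.phs_analysis <- function(x, ...) {
  cat("PHS analysis (endpoint:", x$provenance$endpoint, ")\n")
  print(x$report, digits = 3)
  invisible(x)
}
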