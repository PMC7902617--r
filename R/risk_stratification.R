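#' Freeze percentile thresholds from a reference population
#'
#' Risk-group boundaries are anchored to a designated reference cohort
#' (in the original framework, young men without prostate cancer) rather
#' than recomputed per analysis stratum, so that "the top 2%" means the
#' same score in every stratum. Empirical quantiles use linear
#' interpolation between order statistics.
#'
#' @param scores numeric vector of reference PHS values (length >= 100).
#' @return object of class `percentile_reference`: list with `thresholds`
#'   (named vector at the 20th, 30th, 70th, 80th and 98th percentiles) and
#'   `n`.
#' @export
build_percentile_reference <- function(scores) {
  scores <- scores[!is.na(scores)]
  if (length(scores) < 100)
    stop("need at least 100 reference scores; got ", length(scores))
  probs <- c(0.20, 0.30, 0.70, 0.80, 0.98)
  th <- stats::quantile(scores, probs = probs, names = FALSE, type = 7)
  structure(list(thresholds = stats::setNames(th, paste0("p", probs * 100)),
                 n = length(scores)),
            class = "percentile_reference")
}

#' @export
print.percentile_reference <- function(x, ...) {
  cat("percentile_reference (n =", x$n, "):\n")
  print(x$thresholds)
  invisible(x)
}

#' Assign percentile risk groups
#'
#' Group membership relative to frozen reference thresholds:
#' `low` = score <= 20th percentile, `mid` (average risk) = within the
#' 30th-70th percentile band, `high` = score >= 80th percentile, `top` =
#' score >= 98th percentile (a subset of `high`; boundaries inclusive).
#' Scores falling between the 20th-30th or 70th-80th percentiles belong to
#' no contrast group.
#'
#' @param scores numeric PHS vector.
#' @param ref a [build_percentile_reference()] object.
#' @return `data.frame` of logical columns `low`, `mid`, `high`, `top`.
#' @export
assign_percentile_bins <- function(scores, ref) {
  stopifnot(inherits(ref, "percentile_reference"))
  t <- ref$thresholds
  data.frame(
    low  = scores <= t[["p20"]],
    mid  = scores >= t[["p30"]] & scores <= t[["p70"]],
    high = scores >= t[["p80"]],
    top  = scores >= t[["p98"]]
  )
}

contrast_groups <- c("20" = "low", "50" = "mid", "80" = "high", "98" = "top")

#' Hazard ratio between two percentile groups
#'
#' `HR_a/b = exp(beta_PHS * (mean PHS in group a - mean PHS in group b))`,
#' with group means taken over the evaluation cohort. This continuous-score
#' formulation lets every contrast (including against the 30th-70th band)
#' come from one fit, and makes `HR_80/20 = HR_80/50 / HR_20/50` an exact
#' identity.
#'
#' @param fit a `phs_coxfit` containing a `phs` coefficient.
#' @param scores numeric PHS of the evaluation cohort.
#' @param bins group membership from [assign_percentile_bins()] on `scores`.
#' @param contrast length-2 character vector from `{"20","50","80","98"}`,
#'   e.g. `c("80", "20")` for HR_80/20.
#' @param coef_name name of the score coefficient in `fit` (default
#'   `"phs"`).
#' @return the hazard ratio (numeric scalar).
#' @export
hazard_ratio_between_groups <- function(fit, scores, bins, contrast,
                                        coef_name = "phs") {
  stopifnot(inherits(fit, "phs_coxfit"), length(contrast) == 2,
            all(contrast %in% names(contrast_groups)))
  if (!coef_name %in% names(fit$coefficients))
    stop("fit contains no coefficient named '", coef_name, "'")
  ga <- bins[[contrast_groups[[contrast[1]]]]]
  gb <- bins[[contrast_groups[[contrast[2]]]]]
  if (!any(ga) || !any(gb))
    stop("empty percentile group in contrast ",
         paste(contrast, collapse = "/"))
  beta <- fit$coefficients[[coef_name]]
  exp(beta * (mean(scores[ga]) - mean(scores[gb])))
}

default_contrasts <- list(c("20", "50"), c("80", "50"),
                          c("98", "50"), c("80", "20"))

#' Stratified bootstrap confidence interval for a hazard-ratio contrast
#'
#' Each replicate resamples cases with replacement among cases and controls
#' among controls (preserving both counts), refits the weighted Cox model,
#' recomputes group means on the resampled scores, and recomputes the HR.
#' The CI is the 2.5th/97.5th percentile of the replicate HRs. Rows carry
#' their sample weights into the replicate. Deterministic given `seed`.
#'
#' @param data survival `data.frame` (`time`, `event`, optional
#'   `sample_weight`) including a `phs` column used as the model covariate.
#' @param ref percentile reference for group assignment.
#' @param contrast length-2 contrast, e.g. `c("80", "20")`.
#' @param covariates model covariates (default `"phs"`).
#' @param n_boot number of replicates (>= 100; default 1000).
#' @param seed integer RNG seed (required, for reproducibility).
#' @param max_fail_frac error if more than this fraction of replicate fits
#'   fail (default 0.2).
#' @return list with `ci` (length-2 vector), `replicates` (the HR draws),
#'   `n_fail`.
#' @export
bootstrap_hr_ci <- function(data, ref, contrast, covariates = "phs",
                            n_boot = 1000, seed, max_fail_frac = 0.2) {
  stopifnot(n_boot >= 100, "phs" %in% names(data))
  if (missing(seed)) stop("seed is required for a reproducible bootstrap")
  idx_case <- which(data$event == 1)
  idx_ctrl <- which(data$event == 0)
  if (!length(idx_case) || !length(idx_ctrl))
    stop("both case and control strata must be non-empty")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  hrs <- rep(NA_real_, n_boot)
  for (b in seq_len(n_boot)) {
    take <- c(sample(idx_case, length(idx_case), replace = TRUE),
              sample(idx_ctrl, length(idx_ctrl), replace = TRUE))
    d <- data[take, , drop = FALSE]
    hrs[b] <- tryCatch({
      f <- fit_weighted_cox(d, covariates = covariates)
      hazard_ratio_between_groups(f, d$phs,
                                  assign_percentile_bins(d$phs, ref),
                                  contrast)
    }, error = function(e) NA_real_)
  }
  n_fail <- sum(is.na(hrs))
  if (n_fail > max_fail_frac * n_boot)
    stop("bootstrap unstable: ", n_fail, " of ", n_boot,
         " replicate fits failed")
  ci <- stats::quantile(hrs, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
  list(ci = ci, replicates = hrs, n_fail = n_fail)
}

#' Percentile hazard-ratio report for one stratum
#'
#' Fits the weighted Cox model with PHS as sole covariate (plus any extra
#' covariates supplied), computes all four percentile contrasts (20/50,
#' 80/50, 98/50, 80/20) from the single fit, and optionally attaches
#' stratified-bootstrap CIs per contrast.
#'
#' @param data survival `data.frame` with `time`, `event`, `phs`, optional
#'   `sample_weight`.
#' @param ref a [build_percentile_reference()] object.
#' @param stratum label for the output row (default `"All"`).
#' @param n_boot bootstrap replicates for CIs; `0` skips CIs.
#' @param seed RNG seed for the bootstrap (required when `n_boot > 0`).
#' @return one-row `data.frame`: `stratum`, `n`, `n_events`, `z`,
#'   `log10_p`, then `hr_<a>_<b>` (and `hr_<a>_<b>_lo` / `_hi` when
#'   bootstrapped) for each contrast.
#' @export
hr_report <- function(data, ref, stratum = "All", n_boot = 0, seed = NULL) {
  fit <- fit_weighted_cox(data, covariates = "phs")
  bins <- assign_percentile_bins(data$phs, ref)
  row <- data.frame(stratum = stratum, n = fit$n, n_events = fit$n_events,
                    z = unname(fit$z["phs"]),
                    log10_p = unname(fit$log10_p["phs"]),
                    stringsAsFactors = FALSE)
  for (ct in default_contrasts) {
    nm <- paste0("hr_", ct[1], "_", ct[2])
    row[[nm]] <- tryCatch(
      hazard_ratio_between_groups(fit, data$phs, bins, ct),
      error = function(e) {
        message("stratum ", stratum, ": contrast ",
                paste(ct, collapse = "/"), " unavailable (",
                conditionMessage(e), ")")
        NA_real_
      })
    if (n_boot > 0) {
      if (is.null(seed)) stop("seed required when n_boot > 0")
      ci <- c(NA_real_, NA_real_)
      if (!is.na(row[[nm]])) {
        bs <- bootstrap_hr_ci(data, ref, ct, n_boot = n_boot,
                              seed = seed + match(nm, paste0(
                                "hr_", sapply(default_contrasts, `[`, 1), "_",
                                sapply(default_contrasts, `[`, 2))))
        ci <- bs$ci
      }
      row[[paste0(nm, "_lo")]] <- ci[1]
      row[[paste0(nm, "_hi")]] <- ci[2]
    }
  }
  row
}
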