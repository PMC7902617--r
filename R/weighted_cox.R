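#' Construct a population incidence curve
#'
#' Ordered (age, cumulative incidence) pairs describing the cumulative
#' probability of diagnosis by each age in the general population. Used to
#' derive case/control sample weights that counter case enrichment in
#' consortium-style datasets.
#'
#' @param age strictly increasing numeric vector of ages (years).
#' @param cum_incidence non-decreasing cumulative incidence in \[0, 1\].
#' @return `data.frame` of class `incidence_curve`.
#' @export
incidence_curve <- function(age, cum_incidence) {
  stopifnot(length(age) == length(cum_incidence), length(age) >= 2)
  if (any(diff(age) <= 0)) stop("ages must be strictly increasing")
  if (any(diff(cum_incidence) < 0) || any(cum_incidence < 0) ||
      any(cum_incidence > 1))
    stop("cumulative incidence must be non-decreasing within [0, 1]")
  structure(data.frame(age = age, cum_incidence = cum_incidence),
            class = c("incidence_curve", "data.frame"))
}

#' Evaluate a cumulative incidence curve at given ages
#'
#' Linear interpolation between tabulated ages; constant extrapolation
#' beyond the tabulated range.
#'
#' @param curve an [incidence_curve()].
#' @param ages numeric vector of ages.
#' @return cumulative incidence at each age.
#' @export
incidence_at <- function(curve, ages) {
  stopifnot(inherits(curve, "incidence_curve"))
  stats::approx(curve$age, curve$cum_incidence, xout = ages, rule = 2)$y
}

#' Case-control sample weights from population incidence
#'
#' Consortium case-control data over-represent cases relative to the
#' population. This computes the population-expected case fraction
#' `pi = mean(min(1, scale_factor * F(age_i)))` over the cohort's observed
#' ages, then weights each case by `pi / s` and each control by
#' `(1 - pi) / (1 - s)` where `s` is the sample case fraction, so that the
#' weighted case fraction equals `pi` exactly. Weights are normalized to
#' mean 1 (Cox estimates are invariant to the scale of the weights).
#'
#' @param case 0/1 (or logical) case indicator.
#' @param age observed age (at diagnosis for cases, last follow-up for
#'   controls), years.
#' @param incidence an [incidence_curve()].
#' @param scale_factor positive multiplier on the incidence curve; used by
#'   the sensitivity analysis (default 1).
#' @return numeric vector of positive weights, mean 1; attribute `pi` holds
#'   the population-expected case fraction used.
#' @export
compute_sample_weights <- function(case, age, incidence, scale_factor = 1) {
  stopifnot(length(case) == length(age), scale_factor > 0)
  case <- as.numeric(case)
  if (!all(case %in% c(0, 1))) stop("case must be 0/1")
  s <- mean(case)
  if (s <= 0 || s >= 1)
    stop("degenerate design: sample contains only cases or only controls")
  pii <- mean(pmin(1, scale_factor * incidence_at(incidence, age)))
  if (pii >= 1) {
    warning("scaled population case fraction reached 1; capped")
    pii <- 1 - 1e-8
  }
  if (pii <= 0) stop("population case fraction is zero on this cohort")
  w <- ifelse(case == 1, pii / s, (1 - pii) / (1 - s))
  w <- w / mean(w)
  attr(w, "pi") <- pii
  w
}

#' Fit a sample-weighted Cox proportional hazards model
#'
#' Maximizes the weighted Cox partial likelihood on the age scale with
#' Efron handling of tied event times (the default of the underlying
#' survival engine). Standard errors are model-based (inverse observed
#' information) by default; a robust sandwich estimator is available.
#' Two-tailed p-values are carried on the log10 scale so that extreme
#' z-scores (|z| > 38) do not underflow to zero.
#'
#' @param data `data.frame` with columns `time` (> 0), `event` (0/1),
#'   optional `sample_weight` (> 0, default all 1), and the covariate
#'   columns.
#' @param covariates character vector of covariate column names.
#' @param ties `"efron"` (default) or `"breslow"`.
#' @param robust use robust sandwich standard errors (default `FALSE`).
#' @return object of class `phs_coxfit`: list with `coefficients`, `se`,
#'   `z`, `log10_p`, `loglik` (weighted partial log-likelihood at the
#'   optimum), `loglik_null`, `n`, `n_events`, `converged`, `iter`, `ties`,
#'   and the model `formula` terms.
#' @export
fit_weighted_cox <- function(data, covariates, ties = c("efron", "breslow"),
                             robust = FALSE) {
  ties <- match.arg(ties)
  stopifnot(is.data.frame(data),
            all(c("time", "event") %in% names(data)),
            length(covariates) >= 1,
            all(covariates %in% names(data)))
  if (any(data$time <= 0)) stop("times must be positive")
  if (!all(data$event %in% c(0, 1))) stop("event must be 0/1")
  if (sum(data$event) < 2) stop("need at least 2 events")
  w <- if ("sample_weight" %in% names(data)) data$sample_weight
       else rep(1, nrow(data))
  if (any(!is.finite(w)) || any(w <= 0)) stop("sample weights must be > 0")
  mm <- as.matrix(data[, covariates, drop = FALSE])
  if (anyNA(mm)) stop("missing values in modelled covariates")
  wvar <- apply(mm, 2, function(x) stats::weighted.mean((x - stats::weighted.mean(x, w))^2, w))
  if (any(wvar == 0))
    stop("covariates with zero weighted variance: ",
         paste(covariates[wvar == 0], collapse = ", "))
  fdat <- data.frame(time = data$time, event = data$event,
                     mm, check.names = FALSE)
  fdat$`(wt)` <- w
  fml <- stats::as.formula(paste(
    "survival::Surv(time, event) ~",
    paste(sprintf("`%s`", covariates), collapse = " + ")))
  fit <- survival::coxph(fml, data = fdat, weights = `(wt)`,
                         ties = ties, robust = robust,
                         control = survival::coxph.control(eps = 1e-9,
                                                           iter.max = 100))
  beta <- stats::coef(fit)
  names(beta) <- covariates
  se <- sqrt(diag(fit$var))
  names(se) <- covariates
  z <- beta / se
  structure(list(
    coefficients = beta,
    se = se,
    z = z,
    log10_p = log10_p_from_z(z),
    loglik = fit$loglik[2],
    loglik_null = fit$loglik[1],
    n = fit$n,
    n_events = fit$nevent,
    converged = fit$iter < 100 && all(is.finite(beta)) && all(is.finite(se)),
    iter = fit$iter,
    ties = ties,
    robust = robust,
    covariates = covariates
  ), class = "phs_coxfit")
}

#' @export
print.phs_coxfit <- function(x, ...) {
  cat("Weighted Cox fit (", x$ties, " ties): n = ", x$n,
      ", events = ", x$n_events, "\n", sep = "")
  print(data.frame(coef = x$coefficients, se = x$se, z = x$z,
                   log10_p = x$log10_p))
  invisible(x)
}

#' Two-tailed normal p-value on the log10 scale
#'
#' Stable for arbitrarily large `|z|`: a z-score of 50 gives about
#' -545 rather than underflowing to `-Inf`.
#'
#' @param z numeric z-score(s).
#' @return log10 of the two-tailed p-value.
#' @export
log10_p_from_z <- function(z) {
  (stats::pnorm(abs(z), lower.tail = FALSE, log.p = TRUE) + log(2)) / log(10)
}

#' Likelihood-ratio test between nested weighted Cox fits
#'
#' Compares two fits of the same data and weights where the nested model's
#' covariates are a subset of the full model's. The statistic is twice the
#' difference in weighted partial log-likelihood, referred to a chi-square
#' distribution with degrees of freedom equal to the covariate-count
#' difference; the p-value is carried on the log10 scale.
#'
#' @param nested,full `phs_coxfit` objects from [fit_weighted_cox()].
#' @return list with `statistic`, `df`, `log10_p`.
#' @export
lr_test <- function(nested, full) {
  stopifnot(inherits(nested, "phs_coxfit"), inherits(full, "phs_coxfit"))
  if (!all(nested$covariates %in% full$covariates))
    stop("models are not nested: nested covariates must be a subset")
  if (nested$n != full$n || nested$n_events != full$n_events)
    stop("fits appear to use different data")
  stat <- 2 * (full$loglik - nested$loglik)
  if (stat < -1e-6)
    stop("full-model log-likelihood below nested model's: inconsistent fits")
  stat <- max(stat, 0)
  df <- length(full$covariates) - length(nested$covariates)
  # identical models: statistic 0, p = 1
  log10_p <- if (df == 0) 0 else
    stats::pchisq(stat, df = df, lower.tail = FALSE, log.p = TRUE) / log(10)
  list(statistic = stat, df = df, log10_p = log10_p)
}
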