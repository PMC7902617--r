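---
title: "Polygenic hazard score survival analysis: models, choices, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Polygenic hazard score survival analysis: models, choices, and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The model

A polygenic hazard score (PHS) summarizes a man's common-variant
predisposition for prostate cancer as a weighted sum of effect-allele
dosages,

$$\mathrm{PHS}_j = \sum_{i=1}^{n} X_{ji}\,\beta_i,$$

where $X_{ji} \in [0,2]$ is individual $j$'s dosage of SNP $i$'s effect
allele and $\beta_i$ is a per-allele log-hazard weight estimated by Cox
regression in a development cohort. Unlike an odds-scale polygenic risk
score, the PHS is a covariate in a proportional-hazards model of **age at
diagnosis**: the clinically relevant question is not only *whether* a man
develops prostate cancer but *when*, since age drives screening and
treatment decisions. Men who have not reached an endpoint are censored at
their age at last follow-up, so unaffected men still contribute
information about ages they survived event-free.

`phstrat` implements this framework end to end: score computation and
cross-platform adaptation, sample-weighted Cox fitting, percentile-anchored
hazard-ratio reporting with stratified bootstrap intervals,
admixture-threshold ancestry grouping, an incidence sensitivity sweep, and
a synthetic cohort generator so the whole pipeline is testable without
access-controlled consortium data.

# Score computation and platform adaptation

`compute_phs()` is a plain weighted dosage sum; it is linear in both
dosages and weights, and missing dosages default to mean imputation
(twice the effect-allele frequency estimated from the non-missing column),
which preserves the expected score. `harmonize_alleles()` re-orients
dosage columns that count the score's *other* allele ($d \mapsto 2-d$) and
by default rejects strand-ambiguous variants (A/T, C/G pairs), whose
orientation cannot be resolved from unphased dosages without frequency
heuristics.

When a score developed on one genotyping array is applied to another, some
score SNPs are simply not genotyped. `find_proxies()` replaces each absent
SNP by the platform variant in highest linkage disequilibrium with it in a
reference panel, subject to a floor (default $r^2 \ge 0.94$). Two choices
here were genuinely open:

* **LD statistic.** We use $r^2$, the squared Pearson correlation of
  dosages over pairwise-complete individuals. It is computable from
  unphased data, coincides with haplotype $r^2$ under Hardy–Weinberg
  equilibrium and random mating, and is sign-invariant, so a proxy in
  repulsion phase is still found (its re-estimated weight absorbs the
  orientation). The floor is a configurable argument, not a constant.
* **Weight re-estimation.** `adapt_weights()` refits **all** adapted-panel
  weights in a single multivariable weighted Cox model of age at diagnosis,
  rather than per-SNP univariable fits. The joint fit is the estimator that
  makes the adapted score the best linear predictor on the new panel and
  correctly reapportions signal between a proxy and any correlated direct
  SNPs; with an essentially uncorrelated panel the two approaches agree.

Ties in proxy selection are broken deterministically (larger $r^2$, then
lexicographic candidate id) so the adaptation is reproducible.

# Weighted Cox models

Consortium case-control datasets contain far more cases than an unselected
population, which biases Cox estimates. `compute_sample_weights()` applies
an inverse-fraction correction: with population-expected case fraction
$\pi$ (the mean of the — optionally scaled — cumulative incidence evaluated
at each subject's observed age, capped at 1) and sample case fraction $s$,
cases receive weight $\pi/s$ and controls $(1-\pi)/(1-s)$, normalized to
mean 1. The weighted case fraction then equals $\pi$ exactly. The exact
weighting used with the original consortium analyses is not fully public;
this scheme is the natural prevalence-matching member of the
inverse-probability family and is stated as such (see *Limitations*).

`fit_weighted_cox()` maximizes the weighted partial likelihood through the
`survival` package's engine (Efron tie handling by default, convergence
tolerance $10^{-9}$, at most 100 Newton iterations), with model-based
standard errors from the inverse observed information by default and a
robust sandwich option. Two-tailed p-values are carried as $\log_{10} p$
throughout — at the z-scores this framework produces on large cohorts
(above 38), a linear-scale p-value would underflow to zero.
`lr_test()` compares nested fits (twice the weighted partial log-likelihood
difference against a $\chi^2$ with the covariate-count difference as
degrees of freedom), again on the log scale.

Test oracles for this module are hand-written implementations of the
weighted partial likelihood (both tie conventions) maximized by
golden-section search on tiny cohorts; the suite also checks weight-scale
invariance, duplication/half-weight invariance (under Breslow ties, where
it is exact), and the Efron-equals-Breslow identity for tie-free data.

# Percentile-anchored hazard ratios

Risk stratification is reported as hazard ratios between percentile groups
of the score: lowest 20% (`low`), 30–70% band (`mid`, "average risk"),
top 20% (`high`) and top 2% (`top`). The thresholds are **frozen from a
designated reference population** — young men without prostate cancer —
and reused for every stratum and endpoint, so "top 2%" refers to the same
score everywhere; they are never recomputed per stratum. Boundaries are
inclusive, so a score exactly at the 98th percentile is in both `high` and
`top`, and scores in the 20–30 and 70–80 gaps belong to no contrast group.

The contrast $\mathrm{HR}_{a/b}$ is computed from the single
continuous-score fit as
$\exp\{\hat\beta\,(\bar{\mathrm{PHS}}_a - \bar{\mathrm{PHS}}_b)\}$
with group means taken over the evaluation cohort. This percentile
formulation (rather than refitting with group indicator variables) is what
makes a contrast against the 30–70% band well-defined, and it yields the
exact identity
$\mathrm{HR}_{80/20} = \mathrm{HR}_{80/50} / \mathrm{HR}_{20/50}$ within a
fit, which the suite asserts to $10^{-9}$.

Confidence intervals come from a stratified bootstrap: each replicate
resamples cases with replacement among cases and controls among controls
(both counts preserved), refits the model, recomputes group means, and the
CI is the 2.5th/97.5th percentile of replicate HRs. The **point estimate is
always the full-data fit**, never a bootstrap summary — deterministic and
free of resampling noise; the bootstrap is used only for intervals. The
resampling is seed-controlled and bit-reproducible, and a replicate-failure
rate above 20% aborts with an instability error rather than returning a
quietly truncated interval.

# Ancestry grouping

Two rules operate on admixture-proportion profiles, which are *inputs* —
the package does not re-implement admixture inference or the
principal-component ancestry map that produces them:

* **Named continental rule**, evaluated in fixed order: European if the
  European proportion exceeds 0.80, else Asian if Asian exceeds 0.40, else
  African if African exceeds 0.20, else `other`. The order matters only for
  profiles exceeding several floors at once; first match wins,
  deterministically.
* **Agnostic cluster rule** for K-component output: assign the argmax
  component when its proportion is at least 0.8 (boundary inclusive),
  otherwise `admixed`. A tie at the maximum resolves to the lowest-index
  cluster with a warning.

Both are validated against independently hand-coded oracles over an
exhaustive simplex grid.

# Sensitivity to the assumed incidence

`sweep_incidence()` rebuilds the sample weights with the incidence curve
scaled by each factor of a grid (default nine geometric points spanning
0.25–4), refits, and recomputes every contrast; factor 1 reproduces the
baseline bit-identically, and factors that push the scaled population case
fraction to 1 are flagged rather than fatal.

A structural observation, demonstrated by `analysis/05_sensitivity.R` and
the acceptance script: because the prevalence-matching weights enter the
partial likelihood only through the case:control weight ratio
$\rho = \pi(1-s)/[s(1-\pi)]$, and $\rho$ scales essentially linearly with
the assumed incidence, a 16-fold sweep of the incidence moves the fitted
coefficient substantially (the any-cancer $\mathrm{HR}_{80/20}$ can move
by tens of percent under 62% case enrichment, even though its direction
and significance never change). Any weighting satisfying the
"weighted case fraction $= \pi$" constraint produces the *same* fit, so
this is a property of the correction family, not of the implementation.
The default 10% deviation tolerance encodes the stability one would hope
for; on this generator's study conditions the measured deviation exceeds
it, and the corresponding acceptance test is allowed to fail rather than
the tolerance being widened.

# The synthetic cohort generator

No public individual-level dataset carries this pipeline's full input
structure (multi-ancestry genotypes, age at diagnosis, staging, cause of
death, family history, admixture), so `simulate_cohort()` generates
cohorts with the statistical features the analysis assumes:

* **Genetics.** Global effect-allele frequencies $\sim U(0.05, 0.95)$;
  per-ancestry frequencies from the Balding–Nichols model at
  $F_{st} = 0.10$ (typical continental divergence); Hardy–Weinberg dosages
  $\mathrm{Bin}(2, f)$; optional LD proxy pairs built by allele copying
  with re-draw probability $1-\sqrt{r^2}$, giving the target dosage
  $r^2$ in expectation. True weights $\sim N(0, 0.15^2)$ over 46 SNPs give
  a PHS standard deviation near 0.6, so at unit effect the implied
  80/20 hazard-ratio spread is near 5 — the order of magnitude reported
  for prostate-cancer polygenic hazard scores.
* **Onset.** Age at onset by inverse transform from
  $H(t) = (t/\lambda)^k \exp\{\beta_{\mathrm{PHS}}(\mathrm{PHS} -
  \overline{\mathrm{PHS}})\}$ with $k = 7$, $\lambda = 92$ years;
  censoring age truncated-normal (70, 9) on [40, 100]. These values were
  calibrated once so the simulated demographics resemble published
  consortium tables — median age at diagnosis ≈ 66 (IQR ≈ 59–73), median
  follow-up 70 (IQR ≈ 64–76), lifetime case fraction ≈ 19% — and were not
  revisited afterwards. The Weibull-proportional-hazards form gives
  closed-form sampling and exact agreement with the fitted model class, so
  parameter-recovery tests have a well-defined truth.
* **Endpoints.** 80% of cases carry complete Gleason/PSA/stage data; 53%
  of staged cases are aggressive, with clinical fields generated to satisfy
  the aggressive definition (any of Gleason ≥ 7, PSA ≥ 10 ng/mL, stage
  T3–T4, N1, M1) exactly; 15% of aggressive cases die of prostate cancer
  after a gamma-distributed delay (mean 5 years); 7% of the remainder die
  of other causes. Aggressiveness is assigned **independently of the
  score**: no germline score has been shown to separate aggressive from
  indolent risk, and the generator deliberately reflects that, which is
  also why the aggressive and fatal contrasts it produces are attenuated
  relative to the any-cancer endpoint.
* **Family history.** A first-degree family history indicator is drawn
  from a logistic link on the centred score, with the intercept solved
  numerically to hit a 15% marginal rate and slope 1.0 per PHS unit. The
  slope makes family history a *detectable* marginal correlate of the
  score (implied marginal HR ≈ 1.3) while leaving it conditionally null
  given PHS — the qualitative structure in which a joint model must beat
  family history alone. A parental-liability mode (explicit transmitted
  genotypes, giving family history an independent effect) is a noted
  extension, not implemented.
* **Sampling.** `sample_case_control()` retains all cases and subsamples
  controls to a 62% case fraction, the enrichment typical of consortium
  data, recording the source population's case fraction for the weight
  correction. The population incidence curve used for weighting is the
  empirical cumulative onset distribution of the simulated population.

What the generator does **not** emulate: realistic genome-wide LD beyond
the designated proxy pairs, ethnicity-specific effect sizes, screening
intensity differences between strata, differential clinical-data
availability by ancestry, and competing-risks structure in survival after
diagnosis. Passing tests therefore demonstrate the pipeline's correctness
under its own model assumptions, not robustness to the messiness of real
consortium data.

# Numerical and degenerate-input choices

* Cox convergence: relative log-likelihood change $< 10^{-9}$ or 100
  iterations; non-convergence and singular information surface as errors.
* p-values and LR tests on the $\log_{10}$ scale end to end.
* Percentile thresholds by linear interpolation between order statistics
  (quantile type 7); a reference of fewer than 100 scores is refused.
* Empty contrast groups are an error at the single-contrast level; the
  report builder degrades them to `NA` with a message so one thin stratum
  cannot abort a multi-stratum analysis.
* Zero-variance covariates, non-positive times and weights, degenerate
  all-case/all-control designs, and a scaled population case fraction
  reaching 1 are all rejected or capped-with-warning explicitly.
* All stochastic steps (generator, subsampling, bootstrap) require
  explicit seeds and restore the caller's RNG state.

# Problem sizes used by the tests and acceptance script

Chosen to make every stochastic check statistically decisive while the
whole suite stays fast: null calibration uses 500 cohorts of n = 2,000
(the binomial 95% band around a 1% rejection rate is then 1–10 rejections);
coefficient recovery uses one cohort of n = 20,000 (expected standard
error ≈ 0.02 against a ±0.1 acceptance band); bootstrap coverage uses 20
replicate cohorts of n = 4,000 with 200 bootstrap draws; the acceptance
script simulates a 40,000-man population (≈ 12,000 after case-control
sampling) with 200 bootstrap draws per contrast.

# Known limitations

* The weighting scheme is a stated stand-in for a correction whose exact
  published form is not public, and its prevalence-matching constraint
  makes fitted effect sizes genuinely sensitive to the assumed incidence
  under heavy case enrichment (see the sensitivity section).
* The fatal endpoint censors men dying of other causes at last follow-up —
  cause-specific hazards, not a competing-risks model; with post-diagnosis
  survival influenced by unmodelled factors, fatal-endpoint hazard ratios
  should be read as associations.
* Proxy search evaluates one candidate at a time; no multi-SNP tagging.
* No genome-coordinate liftover, phasing, or reference-panel imputation;
  inputs are assumed pre-harmonized up to allele orientation.
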