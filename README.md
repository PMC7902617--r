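# phstrat

Survival-analysis toolkit for **polygenic hazard scores (PHS)** in prostate
cancer, built for statistical geneticists and cancer epidemiologists who
need to compute a SNP-weighted hazard score, carry it across genotyping
platforms, and quantify how well it stratifies men by age at diagnosis or
death — including in multi-ancestry cohorts.

## The model

The score for individual *j* is a weighted sum of effect-allele dosages,

```
PHS_j = Σ_i X_ji * β_i
```

used as the sole covariate in a Cox proportional-hazards model of **age at
prostate cancer diagnosis** (or aggressive diagnosis, or prostate-cancer
death), with men not reaching the endpoint censored at last follow-up.
Because case-control consortium data over-represent cases, all fits apply
sample weights that restore the population-expected case fraction derived
from an external incidence curve. Risk stratification is reported as
percentile-anchored hazard ratios

```
HR_a/b = exp( β̂ * (mean PHS in percentile group a − mean PHS in group b) )
```

for the contrasts 20/50, 80/50, 98/50 and 80/20, with percentile thresholds
frozen from a reference population of young cancer-free men and confidence
intervals from a case/control-stratified bootstrap. Supporting machinery
covers LD-proxy substitution and weight re-estimation when a score moves to
a platform missing some of its SNPs, admixture-threshold ancestry grouping,
an incidence sensitivity sweep, and a fully seeded synthetic cohort
generator that makes the entire pipeline testable without access-controlled
consortium data.

## Worked example

Simulate a 20,000-man multi-ethnic population with a 46-SNP score whose
true effect is 1.0 log-hazard per PHS unit, enrich it to a 62%-case
analysis cohort, and run the weighted analysis:

```r
library(phstrat)

cfg     <- sim_config(n_individuals = 20000, seed = 1)
cohort  <- simulate_cohort(cfg)
scores  <- compute_phs(cohort$genotypes, cohort$weights)
ph      <- cohort$phenotypes

# percentile anchors from young men without prostate cancer
ref <- build_percentile_reference(scores[ph$case == 0 & ph$age_followup < 70])
inc <- population_incidence(ph)
cc  <- sample_case_control(ph, 0.62, seed = 2)

analysis <- run_phs_analysis(cc, scores[cc$individual_id], ref, inc,
                             endpoint = "any", n_boot = 200, seed = 3)
analysis$report
```

which prints (abridged):

```
 stratum    n n_events    z log10_p hr_20_50 hr_80_50 hr_98_50 hr_80_20 hr_80_20_lo hr_80_20_hi
     All 6101     3783 17.3   -66.4    0.421      2.3     3.97     5.46        4.56        6.72
```

Reading: the weighted Cox fit associates the score with age at diagnosis at
z = 17.3 (p ≈ 10⁻⁶⁶); men in the lowest score quintile have 0.42 times the
hazard of average-risk men (30–70th percentile band), the top quintile 2.3
times, the top 2% almost 4 times; and the top-versus-bottom-quintile
contrast is HR_80/20 = 5.46 with bootstrap 95% CI [4.56, 6.72] — close to
the generative value implied by the simulated effect.

## The analysis workflow

Numbered drivers under `analysis/` run the full study on a simulated
consortium-style cohort and write tables under `results/`:

| script | what it does |
|---|---|
| `01_simulate_cohort.R` | source population + case-control cohort; participant-characteristics table |
| `02_adapt_score.R` | 54-SNP score onto a platform with 24 direct SNPs and 22 LD proxies → 46-SNP adapted score |
| `03_fit_endpoints.R` | weighted fits + HR contrasts for any/aggressive/fatal endpoints, ancestry-stratified |
| `04_family_history.R` | joint family-history + PHS models and likelihood-ratio comparison |
| `05_sensitivity.R` | HR stability as the assumed population incidence scales 0.25–4× |

Run them from the repository root, e.g.
`Rscript analysis/03_fit_endpoints.R`.

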