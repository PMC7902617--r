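#' Configuration for the synthetic cohort generator
#'
#' Defaults emulate the statistical structure of a large multi-ethnic
#' prostate-cancer consortium cohort: a 46-SNP score, three continental
#' ancestries with Balding-Nichols allele-frequency divergence, a Weibull
#' baseline age-at-onset process with proportional hazards on the centred
#' PHS, right censoring around age 70, roughly half of staged cases
#' aggressive, a minority of aggressive cases fatal, and first-degree
#' family history positively linked to the score through a logistic model.
#'
#' @param n_individuals cohort size before any case-control sampling.
#' @param n_snps number of score SNPs (default 46).
#' @param ancestry_props named mixture proportions over
#'   european/asian/african (default 0.893/0.030/0.077).
#' @param fst Balding-Nichols divergence of per-ancestry allele frequencies
#'   from the global frequency (default 0.10).
#' @param sigma_beta SD of the true per-SNP log-hazard weights (default
#'   0.15; with 46 SNPs this yields a PHS SD near 0.6 and an 80/20
#'   percentile hazard-ratio spread near 5 at unit effect).
#' @param weibull_shape,weibull_scale baseline cumulative hazard
#'   `H0(t) = (t / scale)^shape` in years (defaults 7 and 92, calibrated so
#'   median age at diagnosis and its spread, and lifetime cumulative
#'   incidence, resemble published consortium demographics: median
#'   diagnosis ~66, IQR ~59-73, ~19% lifetime case fraction under the
#'   default censoring).
#' @param phs_effect true log-hazard per unit of centred PHS (default 1).
#' @param censor_mean,censor_sd,censor_range truncated-normal age at last
#'   follow-up (defaults 70, 9, \[40, 100\]).
#' @param p_staged probability a case has complete Gleason/PSA/stage data.
#' @param p_aggressive probability a staged case is aggressive (independent
#'   of PHS: no germline score has been shown to separate aggressive from
#'   indolent risk, and the generator reflects that).
#' @param p_fatal probability an aggressive case dies of prostate cancer.
#' @param death_delay_shape,death_delay_mean gamma diagnosis-to-death delay
#'   (years) for fatal cases.
#' @param p_other_death probability a non-fatal individual's follow-up ended
#'   in death from another cause.
#' @param fh_rate target marginal rate of positive family history.
#' @param fh_slope log-odds of family history per unit centred PHS.
#' @param fh_known probability family-history status is recorded.
#' @param admix_shape2 second shape of the Beta(1, shape2) minor-admixture
#'   fraction (default 19: dominant component ~0.95 on average).
#' @param ld_pairs number of extra platform variants generated in LD with
#'   the first `ld_pairs` score SNPs.
#' @param ld_r2 target dosage r-squared of each LD pair.
#' @param seed integer RNG seed (mandatory).
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_individuals = 10000,
                       n_snps = 46,
                       ancestry_props = c(european = 0.893, asian = 0.030,
                                          african = 0.077),
                       fst = 0.10,
                       sigma_beta = 0.15,
                       weibull_shape = 7,
                       weibull_scale = 92,
                       phs_effect = 1,
                       censor_mean = 70, censor_sd = 9,
                       censor_range = c(40, 100),
                       p_staged = 0.8,
                       p_aggressive = 0.53,
                       p_fatal = 0.15,
                       death_delay_shape = 2, death_delay_mean = 5,
                       p_other_death = 0.07,
                       fh_rate = 0.15,
                       fh_slope = 1,
                       fh_known = 0.6,
                       admix_shape2 = 19,
                       ld_pairs = 0,
                       ld_r2 = 0.95,
                       seed) {
  if (missing(seed)) stop("sim_config requires an explicit seed")
  stopifnot(n_individuals > 0, n_snps > 0,
            abs(sum(ancestry_props) - 1) < 1e-6,
            fst >= 0, fst < 1, sigma_beta >= 0,
            weibull_shape > 0, weibull_scale > 0,
            all(c(p_staged, p_aggressive, p_fatal, p_other_death,
                  fh_rate, fh_known) >= 0),
            all(c(p_staged, p_aggressive, p_fatal, p_other_death,
                  fh_rate, fh_known) <= 1),
            ld_pairs >= 0, ld_r2 >= 0, ld_r2 <= 1)
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  cfg
}

# non-complementary allele pairs, so simulated panels are never
# strand-ambiguous by construction
allele_pairs <- matrix(c("A", "G", "A", "C", "T", "G", "T", "C"),
                       ncol = 2, byrow = TRUE)

#' Simulate a SNP panel: true weights and per-ancestry allele frequencies
#'
#' Global effect-allele frequencies are Uniform(0.05, 0.95); per-ancestry
#' frequencies follow the Balding-Nichols model,
#' `f_anc ~ Beta(f (1 - Fst) / Fst, (1 - f)(1 - Fst) / Fst)`; true weights
#' are Normal(0, sigma_beta^2).
#'
#' @param cfg a [sim_config()]. The caller controls the RNG state; use
#'   [simulate_cohort()] for seed-managed end-to-end generation.
#' @return list with `weights` (a [snp_weight_table()]), `freq` (ancestry x
#'   SNP matrix of effect-allele frequencies) and `global_freq`.
#' @export
simulate_snp_panel <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  ids <- sprintf("rs%06d", seq_len(cfg$n_snps))
  f <- stats::runif(cfg$n_snps, 0.05, 0.95)
  anc <- names(cfg$ancestry_props)
  if (cfg$fst > 0) {
    a <- f * (1 - cfg$fst) / cfg$fst
    b <- (1 - f) * (1 - cfg$fst) / cfg$fst
    freq <- t(vapply(anc, function(g) stats::rbeta(cfg$n_snps, a, b),
                     numeric(cfg$n_snps)))
  } else {
    freq <- matrix(f, nrow = length(anc), ncol = cfg$n_snps, byrow = TRUE)
  }
  dimnames(freq) <- list(anc, ids)
  pair <- allele_pairs[sample.int(nrow(allele_pairs), cfg$n_snps,
                                  replace = TRUE), , drop = FALSE]
  w <- snp_weight_table(ids, pair[, 1], pair[, 2],
                        stats::rnorm(cfg$n_snps, 0, cfg$sigma_beta))
  list(weights = w, freq = freq, global_freq = stats::setNames(f, ids))
}

#' Simulate Hardy-Weinberg genotypes with optional LD proxy pairs
#'
#' Dosages are Binomial(2, f_ancestry) independently per SNP. When
#' `cfg$ld_pairs > 0`, one extra variant (id suffix `_ld`) is generated per
#' parent SNP by copying each of its two allele draws and re-drawing it
#' with probability `1 - sqrt(ld_r2)`, which gives dosage correlation
#' `sqrt(ld_r2)` and hence r-squared `ld_r2` in expectation.
#'
#' @param panel output of [simulate_snp_panel()].
#' @param assignments character vector of ancestry labels (rows of
#'   `panel$freq`), one per individual.
#' @param cfg the [sim_config()].
#' @return a [genotype_matrix()] with allele annotations (effect allele
#'   counted, so harmonization is the identity on simulated data).
#' @export
simulate_genotypes <- function(panel, assignments, cfg) {
  stopifnot(inherits(cfg, "sim_config"),
            all(assignments %in% rownames(panel$freq)))
  n <- length(assignments)
  ids <- colnames(panel$freq)
  fmat <- panel$freq[assignments, , drop = FALSE]  # n x p
  n_ld <- min(cfg$ld_pairs, length(ids))
  dos <- matrix(NA_real_, n, length(ids) + n_ld)
  ld_ids <- if (n_ld > 0) paste0(ids[seq_len(n_ld)], "_ld") else character(0)
  colnames(dos) <- c(ids, ld_ids)
  rownames(dos) <- sprintf("ind_%05d", seq_len(n))
  for (j in seq_along(ids)) {
    if (j <= n_ld) {
      a1 <- stats::rbinom(n, 1, fmat[, j])
      a2 <- stats::rbinom(n, 1, fmat[, j])
      dos[, j] <- a1 + a2
      eps <- 1 - sqrt(cfg$ld_r2)
      redraw1 <- stats::runif(n) < eps
      redraw2 <- stats::runif(n) < eps
      b1 <- ifelse(redraw1, stats::rbinom(n, 1, fmat[, j]), a1)
      b2 <- ifelse(redraw2, stats::rbinom(n, 1, fmat[, j]), a2)
      dos[, length(ids) + j] <- b1 + b2
    } else {
      dos[, j] <- stats::rbinom(n, 2, fmat[, j])
    }
  }
  ea <- c(panel$weights$effect_allele,
          panel$weights$effect_allele[seq_len(n_ld)])
  oa <- c(panel$weights$other_allele,
          panel$weights$other_allele[seq_len(n_ld)])
  genotype_matrix(dos,
                  counted_allele = stats::setNames(ea, colnames(dos)),
                  other_allele = stats::setNames(oa, colnames(dos)))
}

#' Simulate survival phenotypes under a PHS-driven Weibull hazard
#'
#' Age at onset is drawn by inverse transform from the cumulative hazard
#' `H(t) = (t / scale)^shape * exp(effect * (PHS - mean(PHS)))`; an
#' individual is a case if onset precedes the (truncated-normal) age at
#' last follow-up. Staging completeness, aggressiveness (with clinical
#' fields generated to match the aggressive definition), prostate-cancer
#' death with a gamma diagnosis-to-death delay, family history via a
#' logistic link on centred PHS (intercept solved so the marginal rate hits
#' `fh_rate`), and admixture profiles concentrated on the true ancestry are
#' then attached.
#'
#' @param genotypes a [genotype_matrix()].
#' @param weights the true [snp_weight_table()].
#' @param assignments ancestry label per individual.
#' @param cfg the [sim_config()].
#' @return `data.frame` phenotype table: `individual_id`, `ancestry`,
#'   admixture columns (`european`, `asian`, `african` or generic), `case`,
#'   `onset_age` (latent, retained for diagnostics and population-incidence
#'   construction), `age_dx`, `age_followup`, `gleason`, `psa`, `t_stage`,
#'   `n_stage`, `m_stage`, `death_cause`, `age_death`, `family_history`.
#' @export
simulate_survival_phenotypes <- function(genotypes, weights, assignments,
                                         cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  phs <- compute_phs(genotypes, weights)
  n <- length(phs)
  eta <- cfg$phs_effect * (phs - mean(phs))
  e <- stats::rexp(n)
  onset <- cfg$weibull_scale * (e / exp(eta))^(1 / cfg$weibull_shape)
  cens <- rtruncnorm(n, cfg$censor_mean, cfg$censor_sd, cfg$censor_range)
  case <- as.integer(onset <= cens)
  age_dx <- ifelse(case == 1, onset, NA_real_)

  staged <- case == 1 & stats::runif(n) < cfg$p_staged
  aggressive <- staged & stats::runif(n) < cfg$p_aggressive
  cl <- simulate_clinical_fields(n, staged, aggressive)

  fatal <- aggressive & stats::runif(n) < cfg$p_fatal
  delay <- stats::rgamma(n, shape = cfg$death_delay_shape,
                         scale = cfg$death_delay_mean / cfg$death_delay_shape)
  age_death <- rep(NA_real_, n)
  death_cause <- rep("alive", n)
  age_death[fatal] <- age_dx[fatal] + delay[fatal]
  death_cause[fatal] <- "prostate_cancer"
  other <- !fatal & stats::runif(n) < cfg$p_other_death
  age_followup <- pmax(cens, ifelse(case == 1, onset, cens))
  age_death[other] <- age_followup[other]
  death_cause[other] <- "other"

  phs_c <- phs - mean(phs)
  a <- stats::uniroot(function(a) mean(stats::plogis(a + cfg$fh_slope * phs_c)) -
                        cfg$fh_rate, c(-20, 20))$root
  fh <- stats::rbinom(n, 1, stats::plogis(a + cfg$fh_slope * phs_c))
  fh[stats::runif(n) >= cfg$fh_known] <- NA_integer_

  adm <- simulate_admixture(assignments, names(cfg$ancestry_props),
                            cfg$admix_shape2)
  data.frame(
    individual_id = rownames(genotypes$dosage),
    ancestry = assignments,
    adm,
    case = case,
    onset_age = onset,
    age_dx = age_dx,
    age_followup = age_followup,
    cl,
    death_cause = death_cause,
    age_death = age_death,
    family_history = fh,
    stringsAsFactors = FALSE
  )
}

# clinical fields consistent with the aggressive definition:
# aggressive iff any of Gleason >= 7, PSA >= 10, T3-T4, N1, M1
simulate_clinical_fields <- function(n, staged, aggressive) {
  gleason <- rep(NA_integer_, n)
  psa <- rep(NA_real_, n)
  t_stage <- rep(NA_character_, n)
  n_stage <- rep(NA_character_, n)
  m_stage <- rep(NA_character_, n)
  idx_na <- which(staged & !aggressive)
  if (length(idx_na)) {
    gleason[idx_na] <- 6L
    psa[idx_na] <- pmin(stats::rlnorm(length(idx_na), log(5), 0.4), 9.9)
    t_stage[idx_na] <- sample(c("T1", "T2"), length(idx_na), replace = TRUE)
    n_stage[idx_na] <- "N0"
    m_stage[idx_na] <- "M0"
  }
  idx_a <- which(aggressive)
  if (length(idx_a)) {
    k <- length(idx_a)
    gleason[idx_a] <- sample(c(6L, 7L, 8L, 9L), k, replace = TRUE,
                             prob = c(0.2, 0.5, 0.2, 0.1))
    psa[idx_a] <- stats::rlnorm(k, log(9), 0.7)
    t_stage[idx_a] <- sample(c("T1", "T2", "T3", "T4"), k, replace = TRUE,
                             prob = c(0.15, 0.55, 0.25, 0.05))
    n_stage[idx_a] <- sample(c("N0", "N1"), k, replace = TRUE,
                             prob = c(0.9, 0.1))
    m_stage[idx_a] <- sample(c("M0", "M1"), k, replace = TRUE,
                             prob = c(0.93, 0.07))
    # guarantee at least one met criterion
    none <- gleason[idx_a] < 7 & psa[idx_a] < 10 &
      t_stage[idx_a] %in% c("T1", "T2") & n_stage[idx_a] == "N0" &
      m_stage[idx_a] == "M0"
    if (any(none)) psa[idx_a][none] <- 10 + stats::rlnorm(sum(none), log(5), 0.5)
  }
  data.frame(gleason = gleason, psa = psa, t_stage = t_stage,
             n_stage = n_stage, m_stage = m_stage, stringsAsFactors = FALSE)
}

simulate_admixture <- function(assignments, components, shape2) {
  n <- length(assignments)
  k <- length(components)
  minor <- stats::rbeta(n, 1, shape2)
  p <- matrix(0, n, k, dimnames = list(NULL, components))
  split <- matrix(stats::rexp(n * (k - 1)), n, k - 1)
  split <- split / rowSums(split)
  for (i in seq_len(n)) {
    main <- match(assignments[i], components)
    p[i, main] <- 1 - minor[i]
    p[i, -main] <- minor[i] * split[i, ]
  }
  as.data.frame(p)
}

rtruncnorm <- function(n, mean, sd, range) {
  lo <- stats::pnorm(range[1], mean, sd)
  hi <- stats::pnorm(range[2], mean, sd)
  stats::qnorm(stats::runif(n, lo, hi), mean, sd)
}

#' Case-control sampling with a target case fraction
#'
#' Emulates consortium case enrichment: all cases are retained and controls
#' are subsampled (without replacement) so that cases make up
#' `target_case_fraction` of the output. If there are too few controls for
#' that, all controls are retained and cases are randomly subsampled
#' instead. The input cohort's case fraction is recorded in attribute
#' `population_case_fraction` for downstream weight computation.
#'
#' @param phenotypes phenotype `data.frame` with a 0/1 `case` column.
#' @param target_case_fraction desired case fraction in (0, 1).
#' @param seed integer RNG seed.
#' @return row subset of `phenotypes` (original row order preserved).
#' @export
sample_case_control <- function(phenotypes, target_case_fraction, seed) {
  stopifnot(target_case_fraction > 0, target_case_fraction < 1)
  if (missing(seed)) stop("seed is required")
  idx_case <- which(phenotypes$case == 1)
  idx_ctrl <- which(phenotypes$case == 0)
  if (!length(idx_case) || !length(idx_ctrl))
    stop("cannot sample: need both cases and controls")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  f <- target_case_fraction
  n_ctrl_want <- floor(length(idx_case) * (1 - f) / f)
  if (n_ctrl_want <= length(idx_ctrl)) {
    keep <- c(idx_case,
              if (n_ctrl_want < length(idx_ctrl))
                sample(idx_ctrl, n_ctrl_want) else idx_ctrl)
  } else {
    n_case_want <- floor(length(idx_ctrl) * f / (1 - f))
    if (n_case_want < 1) stop("infeasible target case fraction")
    keep <- c(sample(idx_case, n_case_want), idx_ctrl)
  }
  out <- phenotypes[sort(keep), , drop = FALSE]
  attr(out, "population_case_fraction") <- mean(phenotypes$case)
  out
}

#' Simulate a complete cohort
#'
#' Seed-managed end-to-end generation: SNP panel, ancestry assignments,
#' genotypes, and survival phenotypes. Fully deterministic given
#' `cfg$seed`; the caller's RNG state is restored on exit.
#'
#' @param cfg a [sim_config()].
#' @return list of class `sim_cohort` with `genotypes`, `weights` (true),
#'   `phenotypes`, `panel`, `config`.
#' @export
simulate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(cfg$seed)
  panel <- simulate_snp_panel(cfg)
  assignments <- sample(names(cfg$ancestry_props), cfg$n_individuals,
                        replace = TRUE, prob = cfg$ancestry_props)
  genotypes <- simulate_genotypes(panel, assignments, cfg)
  phenotypes <- simulate_survival_phenotypes(genotypes, panel$weights,
                                             assignments, cfg)
  structure(list(genotypes = genotypes, weights = panel$weights,
                 phenotypes = phenotypes, panel = panel, config = cfg),
            class = "sim_cohort")
}

#' Empirical population incidence curve from simulated latent onsets
#'
#' Builds the cumulative age-specific incidence of the simulated
#' population from the latent onset ages the generator retains, for use as
#' the baseline curve in sample-weight computation.
#'
#' @param phenotypes a phenotype table with an `onset_age` column.
#' @param ages evaluation grid (default 40-100 years).
#' @return an [incidence_curve()].
#' @export
population_incidence <- function(phenotypes, ages = 40:100) {
  stopifnot("onset_age" %in% names(phenotypes))
  ci <- vapply(ages, function(a) mean(phenotypes$onset_age <= a), numeric(1))
  incidence_curve(ages, cummax(pmin(ci, 1)))
}
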