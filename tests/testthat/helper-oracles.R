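# Independent oracles: deliberately naive implementations, kept separate
# from the package code paths they check.

# brute-force PHS: element-by-element double loop
oracle_phs <- function(dosage, weights) {
  out <- numeric(nrow(dosage))
  for (j in seq_len(nrow(dosage))) {
    s <- 0
    for (i in seq_len(nrow(weights))) {
      s <- s + dosage[j, weights$snp_id[i]] * weights$weight[i]
    }
    out[j] <- s
  }
  out
}

# hand-written weighted Cox partial log-likelihood (Breslow and Efron),
# single covariate, written straight from the definition
oracle_partial_loglik <- function(beta, time, event, x, w, ties = "efron") {
  ll <- 0
  for (t in sort(unique(time[event == 1]))) {
    D <- which(event == 1 & time == t)       # deaths at t
    R <- which(time >= t)                    # risk set
    wr <- w[R] * exp(beta * x[R])
    wd <- w[D] * exp(beta * x[D])
    ll <- ll + sum(w[D] * beta * x[D])
    d <- length(D)
    if (ties == "breslow" || d == 1) {
      ll <- ll - sum(w[D]) * log(sum(wr))
    } else {
      # Efron: average removal of the tied deaths' risk mass
      wbar <- mean(w[D])
      for (k in seq_len(d) - 1) {
        ll <- ll - wbar * log(sum(wr) - (k / d) * sum(wd))
      }
    }
  }
  ll
}

# maximize the oracle likelihood by golden-section search
oracle_cox_beta <- function(time, event, x, w, ties = "efron",
                            interval = c(-10, 10)) {
  stats::optimize(function(b) oracle_partial_loglik(b, time, event, x, w,
                                                    ties = ties),
                  interval = interval, maximum = TRUE,
                  tol = 1e-10)$maximum
}

# hand-coded ancestry rules, scalar form
oracle_oncoarray_label <- function(eur, asi, afr) {
  if (eur > 0.80) return("European")
  if (asi > 0.40) return("Asian")
  if (afr > 0.20) return("African")
  "other"
}

oracle_cluster_label <- function(p, threshold = 0.8) {
  m <- max(p)
  if (m >= threshold) paste0("cluster", which(p == m)[1]) else "admixed"
}

# hand-coded aggressive-disease rule, scalar form
oracle_classify <- function(gleason, psa, t_stage, n_stage, m_stage) {
  met <- c(!is.na(gleason) && gleason >= 7,
           !is.na(psa) && psa >= 10,
           !is.na(t_stage) && t_stage %in% c("T3", "T4"),
           !is.na(n_stage) && n_stage == "N1",
           !is.na(m_stage) && m_stage == "M1")
  if (any(met)) return("aggressive")
  if (anyNA(c(gleason, psa, t_stage, n_stage, m_stage))) return("unevaluable")
  "non_aggressive"
}

# small genotype fixture with explicit dosages
make_genotypes <- function(dosage, counted = NULL, other = NULL) {
  genotype_matrix(dosage, counted_allele = counted, other_allele = other)
}

# platform-adaptation fixture: n_targets score SNPs of which n_direct are
# genotyped on the platform, n_proxy of the rest have an LD twin at
# allele-copy fidelity sqrt(r2), and the remainder have no correlated
# candidate. Returns the pieces find_proxies()/adapt_score() need.
make_adaptation_fixture <- function(n_targets = 54, n_direct = 24,
                                    n_proxy = 22, r2 = 0.97, n_ref = 4000,
                                    seed = 7) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  tgt_ids <- sprintf("t%02d", seq_len(n_targets))
  f <- runif(n_targets, 0.1, 0.9)
  prox_idx <- seq(n_direct + 1, n_direct + n_proxy)
  prox_ids <- sprintf("p%02d", prox_idx)
  eps <- 1 - sqrt(r2)
  ref <- matrix(NA_real_, n_ref, n_targets + n_proxy)
  colnames(ref) <- c(tgt_ids, prox_ids)
  for (j in seq_len(n_targets)) {
    a1 <- rbinom(n_ref, 1, f[j])
    a2 <- rbinom(n_ref, 1, f[j])
    ref[, j] <- a1 + a2
    if (j %in% prox_idx) {
      b1 <- ifelse(runif(n_ref) < eps, rbinom(n_ref, 1, f[j]), a1)
      b2 <- ifelse(runif(n_ref) < eps, rbinom(n_ref, 1, f[j]), a2)
      ref[, sprintf("p%02d", j)] <- b1 + b2
    }
  }
  extra_ids <- sprintf("x%02d", 1:8)
  extra <- sapply(runif(8, 0.1, 0.9), function(p) rbinom(n_ref, 2, p))
  colnames(extra) <- extra_ids
  reference <- genotype_matrix(cbind(ref, extra))
  platform_cols <- c(tgt_ids[seq_len(n_direct)], prox_ids, extra_ids)
  platform <- genotype_matrix(reference$dosage[, platform_cols])
  targets <- snp_weight_table(tgt_ids, rep("A", n_targets),
                              rep("G", n_targets),
                              rnorm(n_targets, 0, 0.1))
  list(targets = targets, platform = platform, reference = reference)
}

# quick simulated analysis cohort shared across tests
make_analysis_cohort <- function(n = 4000, seed = 42, ...) {
  cfg <- sim_config(n_individuals = n, seed = seed, ...)
  coh <- simulate_cohort(cfg)
  scores <- compute_phs(coh$genotypes, coh$weights)
  ph <- coh$phenotypes
  ref <- build_percentile_reference(
    scores[ph$case == 0 & ph$age_followup < 70])
  list(cohort = coh, scores = scores, phenotypes = ph, ref = ref,
       incidence = population_incidence(ph))
}
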