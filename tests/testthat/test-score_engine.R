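test_that("compute_phs matches the double-loop oracle and trivial cases", {
  # all-zero dosages -> all-zero scores
  w <- snp_weight_table(c("a", "b"), c("A", "T"), c("G", "C"), c(0.5, -0.2))
  g0 <- make_genotypes(matrix(0, 3, 2, dimnames = list(NULL, c("a", "b"))))
  expect_equal(unname(compute_phs(g0, w)), rep(0, 3))

  # one SNP, dosage 2, weight 0.3 -> 0.6
  w1 <- snp_weight_table("s", "A", "G", 0.3)
  g1 <- make_genotypes(matrix(2, 1, 1, dimnames = list("i1", "s")))
  expect_equal(unname(compute_phs(g1, w1)), 0.6)

  # random 5 x 3 vs brute-force loop
  set.seed(1)
  d <- matrix(sample(seq(0, 2, 0.5), 15, replace = TRUE), 5, 3,
              dimnames = list(NULL, c("s1", "s2", "s3")))
  wr <- snp_weight_table(c("s2", "s1", "s3"), c("A", "C", "T"),
                         c("G", "T", "G"), rnorm(3))
  g <- make_genotypes(d)
  expect_equal(unname(compute_phs(g, wr)), oracle_phs(d, wr),
               tolerance = 1e-12)
})

test_that("compute_phs is linear in dosages and weights", {
  set.seed(2)
  d <- matrix(runif(40, 0, 2), 10, 4,
              dimnames = list(NULL, paste0("s", 1:4)))
  wa <- rnorm(4); wb <- rnorm(4)
  tab <- function(w) snp_weight_table(paste0("s", 1:4), rep("A", 4),
                                      rep("G", 4), w)
  g <- make_genotypes(d)
  expect_equal(compute_phs(g, tab(wa + wb)),
               compute_phs(g, tab(wa)) + compute_phs(g, tab(wb)),
               tolerance = 1e-12)
  # shifting one SNP's dosages by c shifts every score by c * beta_i
  d2 <- d; d2[, "s2"] <- pmin(d2[, "s2"] + 0.25, 2)
  shift <- d2[, "s2"] - d[, "s2"]
  expect_equal(compute_phs(make_genotypes(d2), tab(wa)),
               compute_phs(g, tab(wa)) + shift * wa[2], tolerance = 1e-12)
})

test_that("missing-dosage policies behave as documented", {
  d <- matrix(c(0, 1, 2, NA, 2, 0), 3, 2,
              dimnames = list(NULL, c("s1", "s2")))
  w <- snp_weight_table(c("s1", "s2"), c("A", "A"), c("G", "G"), c(1, 1))
  g <- make_genotypes(d)
  # mean imputation: missing s2 value replaced by mean of (2, 0) = 1
  expect_equal(unname(compute_phs(g, w, "mean_impute")), c(0 + 1, 1 + 2, 2 + 0))
  expect_equal(unname(compute_phs(g, w, "zero")), c(0, 3, 2))
  expect_error(compute_phs(g, w, "error"), "missing")
})

test_that("compute_phs validates inputs", {
  w <- snp_weight_table(c("s1", "zz"), c("A", "A"), c("G", "G"), c(1, 1))
  g <- make_genotypes(matrix(1, 2, 1, dimnames = list(NULL, "s1")))
  expect_error(compute_phs(g, w), "zz")
  expect_error(genotype_matrix(matrix(3, 1, 1, dimnames = list(NULL, "s"))),
               "\\[0, 2\\]")
  expect_error(snp_weight_table("a", "A", "A", 1), "differ")
  expect_error(snp_weight_table(c("a", "a"), c("A", "A"), c("G", "G"),
                                c(1, 1)), "duplicate")
})

test_that("harmonize_alleles flips, is an involution, and rejects ambiguity", {
  d <- matrix(c(2, 0, 1, 1, 2, 0), 3, 2,
              dimnames = list(NULL, c("s1", "s2")))
  w <- snp_weight_table(c("s1", "s2"), c("A", "C"), c("G", "T"), c(1, 1))
  # s1 counts the effect allele already; s2 counts the other allele
  g <- make_genotypes(d, counted = c(s1 = "A", s2 = "T"),
                      other = c(s1 = "G", s2 = "C"))
  h <- harmonize_alleles(g, w)
  expect_equal(h$dosage[, "s1"], d[, "s1"], ignore_attr = TRUE)
  expect_equal(h$dosage[, "s2"], 2 - d[, "s2"], ignore_attr = TRUE)
  expect_equal(unname(h$counted_allele["s2"]), "C")
  # flipping twice restores the original orientation
  set.seed(3)
  d2 <- matrix(runif(20, 0, 2), 5, 4, dimnames = list(NULL, paste0("s", 1:4)))
  w2 <- snp_weight_table(paste0("s", 1:4), c("A", "C", "T", "G"),
                         c("G", "T", "C", "A"), rnorm(4))
  g2 <- make_genotypes(d2,
                       counted = setNames(c("G", "T", "C", "A"), paste0("s", 1:4)),
                       other = setNames(c("A", "C", "T", "G"), paste0("s", 1:4)))
  once <- harmonize_alleles(g2, w2)
  flipped_back <- once
  # re-orient to a table whose effect alleles are the original counted ones
  w_back <- snp_weight_table(paste0("s", 1:4), c("G", "T", "C", "A"),
                             c("A", "C", "T", "G"), rnorm(4))
  twice <- harmonize_alleles(once, w_back)
  expect_equal(twice$dosage, d2, tolerance = 1e-12, ignore_attr = TRUE)

  # strand-ambiguous pair rejected by default, tolerated with "keep"
  wamb <- snp_weight_table("s1", "A", "T", 1)
  gamb <- make_genotypes(matrix(1, 2, 1, dimnames = list(NULL, "s1")),
                         counted = c(s1 = "A"), other = c(s1 = "T"))
  expect_error(harmonize_alleles(gamb, wamb), "ambiguous")
  expect_silent(harmonize_alleles(gamb, wamb, ambiguous = "keep"))
  # allele pair matching neither orientation
  wbad <- snp_weight_table("s1", "C", "G", 1)
  gbad <- make_genotypes(matrix(1, 2, 1, dimnames = list(NULL, "s1")),
                         counted = c(s1 = "A"), other = c(s1 = "T"))
  expect_error(harmonize_alleles(gbad, wbad, ambiguous = "keep"), "mismatch")
})

test_that("compute_ld: r-squared of dosage correlation", {
  set.seed(4)
  a <- rbinom(500, 2, 0.4)
  expect_equal(compute_ld(a, a), 1)
  expect_equal(compute_ld(a, 2 - a), 1)        # sign-invariant
  b <- rbinom(1e4, 2, 0.5)
  c <- rbinom(1e4, 2, 0.5)
  expect_lt(compute_ld(b, c), 0.01)            # independent columns
  expect_error(compute_ld(rep(1, 10), rbinom(10, 2, .5)), "variance")
  # pairwise-complete handling
  a2 <- a; a2[1:10] <- NA
  expect_equal(compute_ld(a2, a2), 1)
})

test_that("find_proxies maps on-platform targets to themselves and applies the floor", {
  fx <- make_adaptation_fixture(n_targets = 6, n_direct = 3, n_proxy = 2,
                                n_ref = 2000, seed = 11)
  pm <- find_proxies(fx$targets, fx$platform, fx$reference, min_r2 = 0.94)
  direct <- pm$target_snp %in% sprintf("t%02d", 1:3)
  expect_true(all(pm$proxy_snp[direct] == pm$target_snp[direct]))
  expect_true(all(pm$ld_r2[direct] == 1))
  expect_true(all(!is.na(pm$proxy_snp[pm$target_snp %in% c("t04", "t05")])))
  expect_true(is.na(pm$proxy_snp[pm$target_snp == "t06"]))
  # raising the floor is monotone non-increasing in the number mapped
  n_mapped <- sapply(c(0, 0.5, 0.94, 0.999), function(r2)
    sum(!is.na(find_proxies(fx$targets, fx$platform, fx$reference,
                            min_r2 = r2)$proxy_snp)))
  expect_true(all(diff(n_mapped) <= 0))
  # min_r2 = 0 maps every target with any candidate
  pm0 <- find_proxies(fx$targets, fx$platform, fx$reference, min_r2 = 0)
  expect_true(all(!is.na(pm0$proxy_snp)))
  # candidate below the floor is not used
  expect_true(is.na(find_proxies(fx$targets, fx$platform, fx$reference,
                                 min_r2 = 0.9999)$proxy_snp[6]))
})

test_that("perfect proxy substitution leaves PHS unchanged", {
  set.seed(5)
  d <- matrix(rbinom(300, 2, 0.4), 100, 3,
              dimnames = list(NULL, c("s1", "s2", "s3")))
  d <- cbind(d, s2_twin = d[, "s2"])  # r2 = 1, same orientation
  w <- snp_weight_table(c("s1", "s2", "s3"), rep("A", 3), rep("G", 3),
                        c(0.2, -0.4, 0.1))
  w_sub <- snp_weight_table(c("s1", "s2_twin", "s3"), rep("A", 3),
                            rep("G", 3), c(0.2, -0.4, 0.1))
  g <- make_genotypes(d)
  expect_equal(compute_phs(g, w), compute_phs(g, w_sub), tolerance = 1e-12)
})

test_that("adapt_weights recovers generative weights and is duplication-invariant", {
  cfg <- sim_config(n_individuals = 20000, n_snps = 10, sigma_beta = 0.2,
                    seed = 9)
  coh <- simulate_cohort(cfg)
  st <- build_survival_table(coh$phenotypes,
                             compute_phs(coh$genotypes, coh$weights), "any")
  tr <- data.frame(time = st$time, event = st$event)
  w_hat <- adapt_weights(coh$genotypes, tr)
  fit <- fit_weighted_cox(cbind(tr, as.data.frame(coh$genotypes$dosage)),
                          covariates = colnames(coh$genotypes$dosage))
  expect_true(all(abs(w_hat$weight - coh$weights$weight) < 3 * fit$se))
  expect_equal(w_hat$effect_allele, coh$weights$effect_allele)

  # zero-effect SNPs give |z| < 4 in the recovery fit
  cfg0 <- sim_config(n_individuals = 20000, n_snps = 10, sigma_beta = 0,
                     seed = 10)
  coh0 <- simulate_cohort(cfg0)
  st0 <- build_survival_table(coh0$phenotypes,
                              compute_phs(coh0$genotypes, coh0$weights),
                              "any")
  f0 <- fit_weighted_cox(
    cbind(st0[c("time", "event")], as.data.frame(coh0$genotypes$dosage)),
    covariates = colnames(coh0$genotypes$dosage))
  expect_true(all(abs(f0$z) < 4))

  # duplicating the training cohort leaves coefficients unchanged
  # (Breslow ties: duplication creates exact ties)
  small_cfg <- sim_config(n_individuals = 800, n_snps = 4, seed = 21)
  sm <- simulate_cohort(small_cfg)
  sst <- build_survival_table(sm$phenotypes,
                              compute_phs(sm$genotypes, sm$weights), "any")
  str <- data.frame(time = sst$time, event = sst$event)
  w1 <- adapt_weights(sm$genotypes, str, ties = "breslow")
  gdup <- sm$genotypes
  gdup$dosage <- rbind(gdup$dosage,
                       `rownames<-`(gdup$dosage,
                                    paste0(rownames(gdup$dosage), "_b")))
  w2 <- adapt_weights(gdup, rbind(str, str), ties = "breslow")
  expect_equal(w1$weight, w2$weight, tolerance = 1e-6)
})
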