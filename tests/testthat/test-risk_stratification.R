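test_that("percentile reference thresholds follow order statistics", {
  ref <- build_percentile_reference(1:100)
  expect_gte(ref$thresholds[["p20"]], 20)
  expect_lte(ref$thresholds[["p20"]], 21)
  expect_true(!is.unsorted(ref$thresholds))
  # degenerate: identical scores
  refc <- build_percentile_reference(rep(2.5, 200))
  expect_true(all(refc$thresholds == 2.5))
  # large normal sample: 98th percentile near qnorm(0.98) = 2.054
  set.seed(41)
  refn <- build_percentile_reference(rnorm(1e5))
  expect_equal(refn$thresholds[["p98"]], qnorm(0.98), tolerance = 0.02)
  # fraction strictly below each threshold is within 1/n of the target
  x <- rnorm(5000)
  refx <- build_percentile_reference(x)
  for (q in c(0.2, 0.3, 0.7, 0.8, 0.98)) {
    th <- refx$thresholds[[paste0("p", q * 100)]]
    expect_lt(abs(mean(x < th) - q), 1 / 5000 + 1e-12)
  }
  expect_error(build_percentile_reference(rnorm(50)), "at least 100")
})

test_that("percentile bins use inclusive boundaries and leave gaps unassigned", {
  ref <- build_percentile_reference(1:1000)
  t <- ref$thresholds
  b <- assign_percentile_bins(c(t[["p20"]] - 1, t[["p98"]],
                                (t[["p20"]] + t[["p30"]]) / 2,
                                (t[["p70"]] + t[["p80"]]) / 2), ref)
  expect_true(b$low[1] && !b$mid[1] && !b$high[1])
  expect_true(b$high[2] && b$top[2])     # score == t98 is in both groups
  expect_false(any(unlist(b[3, ])))      # 20th-30th gap: no group
  expect_false(any(unlist(b[4, ])))      # 70th-80th gap: no group
  # top is always a subset of high
  set.seed(42)
  s <- rnorm(2000)
  bb <- assign_percentile_bins(s, ref <- build_percentile_reference(rnorm(5000)))
  expect_true(all(!bb$top | bb$high))
  # occupancy when scores are drawn from the reference distribution
  expect_lt(abs(mean(bb$low) - 0.20), 0.03)
  expect_lt(abs(mean(bb$mid) - 0.40), 0.04)
  expect_lt(abs(mean(bb$high) - 0.20), 0.03)
  expect_lt(abs(mean(bb$top) - 0.02), 0.01)
})

test_that("group hazard ratios follow the closed form and the ratio identity", {
  fake_fit <- structure(list(coefficients = c(phs = log(2))),
                        class = "phs_coxfit")
  scores <- c(1, 1, 2, 2, 3, 3)
  bins <- data.frame(low = c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE),
                     mid = c(FALSE, FALSE, TRUE, TRUE, FALSE, FALSE),
                     high = c(FALSE, FALSE, FALSE, FALSE, TRUE, TRUE),
                     top = FALSE)
  # equal group means -> HR 1
  bins_eq <- bins; bins_eq$mid <- bins_eq$low
  expect_equal(hazard_ratio_between_groups(fake_fit, scores, bins_eq,
                                           c("20", "50")), 1)
  # beta = ln 2, mean difference 1 -> HR 2
  expect_equal(hazard_ratio_between_groups(fake_fit, scores, bins,
                                           c("50", "20")), 2)
  expect_error(hazard_ratio_between_groups(fake_fit, scores,
                                           data.frame(low = FALSE, mid = TRUE,
                                                      high = TRUE, top = TRUE),
                                           c("20", "50")), "empty")
  # single-fit ratio identity on a simulated report
  env <- make_analysis_cohort(n = 3000, seed = 12)
  st <- build_survival_table(env$phenotypes, env$scores, "any")
  rep <- hr_report(st, env$ref)
  expect_equal(rep$hr_80_20, rep$hr_80_50 / rep$hr_20_50, tolerance = 1e-9)
  # monotone ordering when the fitted effect is positive
  expect_true(rep$hr_20_50 < 1 && 1 < rep$hr_80_50 &&
                rep$hr_80_50 < rep$hr_98_50)
})

test_that("hazard-ratio contrasts are invariant to affine rescaling of the score", {
  env <- make_analysis_cohort(n = 3000, seed = 12)
  ph <- env$phenotypes
  st <- build_survival_table(ph, env$scores, "any")
  r1 <- hr_report(st, env$ref)
  st2 <- st; st2$phs <- 3 * st$phs + 5
  ref2 <- build_percentile_reference(
    3 * env$scores[ph$case == 0 & ph$age_followup < 70] + 5)
  r2 <- hr_report(st2, ref2)
  for (cn in c("hr_20_50", "hr_80_50", "hr_98_50", "hr_80_20"))
    expect_equal(r2[[cn]], r1[[cn]], tolerance = 1e-6)
})

test_that("stratified bootstrap is reproducible and degenerates to zero width", {
  env <- make_analysis_cohort(n = 1500, seed = 13)
  st <- build_survival_table(env$phenotypes, env$scores, "any")
  b1 <- bootstrap_hr_ci(st, env$ref, c("80", "20"), n_boot = 100, seed = 99)
  b2 <- bootstrap_hr_ci(st, env$ref, c("80", "20"), n_boot = 100, seed = 99)
  expect_identical(b1$replicates, b2$replicates)   # bit-reproducible
  b3 <- bootstrap_hr_ci(st, env$ref, c("80", "20"), n_boot = 100, seed = 100)
  expect_false(identical(b1$replicates, b3$replicates))
  expect_true(b1$ci[1] <= b1$ci[2])
  # point estimate typically inside its own bootstrap CI
  fit <- fit_weighted_cox(st, "phs")
  hr <- hazard_ratio_between_groups(fit, st$phs,
                                    assign_percentile_bins(st$phs, env$ref),
                                    c("80", "20"))
  expect_true(hr >= b1$ci[1] && hr <= b1$ci[2])

  # identical case rows + identical control rows: every resample is the
  # same dataset (case/control counts preserved), so the CI has zero width
  dd <- data.frame(time = rep(c(60, 70), each = 30),
                   event = rep(c(1, 0), each = 30),
                   phs = rep(c(1, -1), each = 30))
  refd <- build_percentile_reference(c(rep(-1, 60), rep(1, 60)))
  bd <- suppressWarnings(
    bootstrap_hr_ci(dd, refd, c("80", "20"), n_boot = 100, seed = 1))
  expect_equal(bd$ci[1], bd$ci[2], tolerance = 1e-12)
  expect_error(bootstrap_hr_ci(dd, refd, c("80", "20"), n_boot = 10, seed = 1),
               "n_boot")
})
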