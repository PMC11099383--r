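test_that("median stratification follows the tie-to-low rule", {
  g <- median_stratify(c(1, 2, 3, 4))
  expect_equal(as.character(g), c("low", "low", "high", "high"))
  g2 <- median_stratify(c(1, 2, 2, 4))
  expect_equal(as.character(g2), c("low", "low", "low", "high"))
  expect_equal(levels(g), c("low", "high"))
  expect_error(median_stratify(rep(3, 5)), "constant")
})

test_that("combined stratification intersects the two median splits", {
  g <- combined_stratify(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(as.character(g), c("low", "low", "high", "high"))
  # perfectly anti-ranked genes leave no both-high patient
  expect_null(combined_stratify(c(1, 2, 3, 4), c(4, 3, 2, 1)))
  # group sizes match brute-force set intersection on random input
  set.seed(17)
  vr <- rnorm(200); vp <- rnorm(200)
  g3 <- combined_stratify(vr, vp)
  expect_equal(sum(g3 == "high"),
               sum(vr > median(vr) & vp > median(vp)))
  expect_equal(sum(g3 == "low"),
               sum(vr <= median(vr) & vp <= median(vp)))
  expect_equal(sum(g3 == "excluded"),
               200 - sum(g3 == "high") - sum(g3 == "low"))
})

test_that("log-rank matches a hand-worked small example and symmetry", {
  # identical survival experience in both groups -> statistic 0, p 1
  time <- c(1, 2, 3, 1, 2, 3)
  event <- c(1, 1, 0, 1, 1, 0)
  grp <- factor(rep(c("low", "high"), each = 3), levels = c("low", "high"))
  out <- km_logrank(time, event, grp)
  expect_equal(out$statistic, 0, tolerance = 1e-12)
  expect_equal(out$p, 1, tolerance = 1e-12)

  # 6-patient example, hand-computed hypergeometric O-E / V form:
  # times 1,2,4 are events in A; 3,5 events in B; 6 censored in B
  time2 <- c(1, 2, 4, 3, 5, 6)
  event2 <- c(1, 1, 1, 1, 1, 0)
  grp2 <- factor(rep(c("A", "B"), each = 3))
  # at t=1: n=6, nA=3, O=1, E=0.5, V=0.25
  # at t=2: n=5, nA=2, O=1, E=0.4, V=0.24
  # at t=3: n=4, nA=1, O=0, E=0.25, V=0.1875
  # at t=4: n=3, nA=1, O=1, E=1/3, V=2/9
  # at t=5: n=2, nA=0, O=0, E=0,   V=0
  oe <- (1 - 0.5) + (1 - 0.4) + (0 - 0.25) + (1 - 1 / 3) + 0
  v <- 0.25 + 0.24 + 0.1875 + 2 / 9 + 0
  out2 <- km_logrank(time2, event2, grp2)
  expect_equal(out2$statistic, oe^2 / v, tolerance = 1e-10)
  # KM table covers both groups with survival in [0, 1]
  expect_setequal(unique(out2$km$group), c("A", "B"))
  expect_true(all(out2$km$survival >= 0 & out2$km$survival <= 1))
  expect_error(km_logrank(time2, event2, factor(rep("A", 6))), "two")
})

test_that("log-rank detects a strong planted hazard ratio", {
  hits <- 0
  for (s in 1:20) {
    d <- sim_two_group(1000, hr = 3, seed = 400 + s)
    p <- km_logrank(d$time, d$event, d$group)$p
    hits <- hits + (p < 0.001)
  }
  expect_gte(hits, 19)
})

test_that("Cox recovers a planted log-hazard and is null-calibrated", {
  d <- sim_two_group(2000, hr = 2, seed = 5)
  fit <- cox_univariate(d$time, d$event, d$group)
  expect_lt(abs(fit$beta - log(2)), 0.1)
  expect_equal(fit$hr, exp(fit$beta))

  # covariate independent of hazard
  set.seed(6)
  d0 <- sim_two_group(2000, hr = 1, seed = 6)
  fit0 <- cox_univariate(d0$time, d0$event, d0$group)
  expect_lt(abs(fit0$beta), 0.1)

  expect_error(cox_univariate(d$time, d$event, rep(1, 2000)), "constant")
})

test_that("relabeling high and low inverts the Cox coefficient", {
  d <- sim_two_group(300, hr = 2, seed = 8)
  flipped <- factor(ifelse(d$group == "high", "low", "high"),
                    levels = c("low", "high"))
  b1 <- cox_univariate(d$time, d$event, d$group)$beta
  b2 <- cox_univariate(d$time, d$event, flipped)$beta
  expect_lt(abs(b1 + b2), 1e-8)
})

test_that("axis screen applies the HR-fold and log-rank filter", {
  # deterministic filter logic on a constructed record set
  rec <- tibble::tibble(
    hr_axis = c(3.0, 1.8, 3.0), hr_r = c(1.2, 1.2, 1.2),
    hr_p = c(1.3, 1.3, 1.3),
    logrank_p_axis = c(0.01, 0.01, 0.06),
    logrank_p_r = c(0.03, 0.03, 0.3), logrank_p_p = c(0.04, 0.04, 0.4))
  pass <- with(rec, (hr_axis / hr_r < 0.5 | hr_axis / hr_r > 2) &
                 (hr_axis / hr_p < 0.5 | hr_axis / hr_p > 2) &
                 logrank_p_axis < pmin(logrank_p_r, logrank_p_p) &
                 logrank_p_axis < 0.05)
  expect_equal(pass, c(TRUE, FALSE, FALSE))

  # end-to-end on a synthetic cohort with one synergistic axis
  cfg <- sim_config(seed = 41, n_genes = 80, n_subtypes = 1,
                    n_samples_tumor = 300, n_samples_normal = 4,
                    planted_axes = default_planted_axes(1),
                    n_decoy_axes = 5,
                    survival = list(axis_multiplier = 4,
                                    individual_multiplier = 1.2))
  net <- generate_network_fixture(cfg)
  cnt <- generate_counts(cfg)
  surv <- generate_survival(cfg, cnt$counts)
  ds <- survival_dataset(surv$clinical, surv$expression[[1]], "c1")
  axes <- dplyr::transmute(net$truth, receptor, partner,
                           partner_kind = kind)
  scr <- axis_screen(ds, axes)
  expect_s3_class(scr, "axis_screen")
  planted <- scr[scr$receptor == "RCP01", ]
  expect_gt(planted$hr_axis, planted$hr_r)
  expect_true(all(scr$q >= scr$logrank_p_axis, na.rm = TRUE))
  # screens are deterministic
  scr2 <- axis_screen(ds, axes)
  expect_equal(tibble::as_tibble(scr), tibble::as_tibble(scr2))
})

test_that("the combinatorial predictor follows the linear form", {
  # beta_r = 0.5, beta_p = -0.2, indicators (1, 0) -> predictor 0.5
  expect_equal(0.5 * 1 + (-0.2) * 0, 0.5)
  cfg <- sim_config(seed = 43, n_genes = 60, n_subtypes = 1,
                    n_samples_tumor = 200, n_samples_normal = 4,
                    planted_axes = default_planted_axes(1), n_decoy_axes = 2,
                    survival = list(axis_multiplier = 1,
                                    individual_multiplier = 2))
  net <- generate_network_fixture(cfg)
  cnt <- generate_counts(cfg)
  surv <- generate_survival(cfg, cnt$counts)
  ds <- survival_dataset(surv$clinical, surv$expression[[1]], "c1")
  out <- combinatorial_cox(ds, "RCP01", "LIG01")
  expect_s3_class(out, "combinatorial_cox")
  expect_false(is.na(out$beta_c))
  # additive log-hazards: combined HR should exceed both individual HRs
  expect_gt(out$hr_c, max(out$hr_r, out$hr_p) * 0.8)
})

test_that("coefficient regression recovers an exact linear relation", {
  set.seed(19)
  res <- tibble::tibble(beta_r = rnorm(20), beta_p = rnorm(20),
                        selected = TRUE)
  res$beta_c <- 1.0 * res$beta_r + 1.0 * res$beta_p
  fit <- coefficient_regression(res)
  est <- tidy(fit)
  expect_equal(est$estimate[est$term == "beta_r"], 1, tolerance = 1e-10)
  expect_equal(est$estimate[est$term == "beta_p"], 1, tolerance = 1e-10)
  expect_equal(glance(fit)$r_squared, 1, tolerance = 1e-10)
  # independent response: slopes within 2 standard errors of zero
  res0 <- res
  set.seed(20)
  res0$beta_c <- rnorm(20)
  t0 <- tidy(coefficient_regression(res0))
  expect_true(all(abs(t0$estimate[-1]) < 2.5 * t0$std_error[-1]))
  expect_error(coefficient_regression(res[1:2, ]), ">= 3")
})

test_that("Cox score test and log-rank p agree on two-group data", {
  d <- sim_two_group(1000, hr = 1.25, censor_frac = 0.2, seed = 23)
  cox_p <- cox_univariate(d$time, d$event, d$group)$score_p
  lr_p <- km_logrank(d$time, d$event, d$group)$p
  expect_lt(abs(cox_p - lr_p) / lr_p, 0.1)
})
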