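test_that("mixed model recovers a null design and shifts only its intercept under translation", {
  spec <- scenario_spec(seed = 2,
                        donors = c(YD = 0, OD = 0, RS = 0),
                        inducers = c(C10 = 0, C1 = 0, Doxo = 0, Cis = 0,
                                     Eto = 0, Bleo = 0),
                        peak_slope = 0)
  obs <- generate_peak_observations(spec, n_curves = 60)
  fit <- fit_peak_lmm(obs)
  fe <- fit$fixed_effects
  nonint <- fe[fe$term != "(Intercept)", ]
  expect_true(all(abs(nonint$estimate) < 3 * nonint$se))
  expect_true(all(fe$ci_low <= fe$estimate & fe$estimate <= fe$ci_high))
  expect_gte(fit$random_intercept_variance, 0)

  obs2 <- obs
  obs2$log10_xpeak <- obs2$log10_xpeak + 1
  fit2 <- fit_peak_lmm(obs2)
  expect_equal(fit2$fixed_effects$estimate[1],
               fe$estimate[1] + 1, tolerance = 1e-6)
  expect_equal(fit2$fixed_effects$estimate[-1], fe$estimate[-1],
               tolerance = 1e-6)
})

test_that("inducer coefficients are offsets relative to the chosen reference", {
  spec <- scenario_spec(seed = 9)
  obs <- generate_peak_observations(spec, n_curves = 54)
  fit_c10 <- fit_peak_lmm(obs, inducer_ref = "C10")
  fit_c1 <- fit_peak_lmm(obs, inducer_ref = "C1")
  expect_true("inducerC1" %in% fit_c10$fixed_effects$term)
  expect_true("inducerC10" %in% fit_c1$fixed_effects$term)
  # re-expressing against the other reference flips the sign of the offset
  b_c1 <- fit_c10$fixed_effects$estimate[
    fit_c10$fixed_effects$term == "inducerC1"]
  b_c10 <- fit_c1$fixed_effects$estimate[
    fit_c1$fixed_effects$term == "inducerC10"]
  expect_equal(b_c1, -b_c10, tolerance = 1e-5)
})

test_that("a perfectly confounded design raises an estimability error", {
  d <- data.frame(
    log10_xpeak = rnorm(8),
    donor = rep(c("YD", "OD"), each = 4),
    inducer = rep(c("C10", "Doxo"), each = 4), # aliased with donor
    peak_id = rep(1:2, 4),
    curve_id = rep(c("a", "b", "c", "d"), each = 2)
  )
  expect_error(fit_peak_lmm(d), "aliased|estimable")
})

test_that("residual diagnostics flag bimodality and reject tiny samples", {
  set.seed(31)
  bimodal <- c(rnorm(20, -1, 0.05), rnorm(20, 1, 0.05))
  expect_lt(residual_normality(bimodal)$p, 0.01)
  expect_error(residual_normality(c(0.1, -0.1)), "3 residuals")
})

test_that("variance homogeneity detects a 10x spread and handles constants", {
  set.seed(32)
  vals <- c(rnorm(30, 0, 1), rnorm(30, 0, 1), rnorm(30, 0, sqrt(10)))
  grp <- rep(c("YD", "OD", "RS"), each = 30)
  expect_lt(variance_homogeneity(vals, grp)$p, 0.01)

  const <- variance_homogeneity(rep(c(1, 1, 2, 2), each = 3),
                                rep(c("a", "b", "c", "d"), each = 3))
  expect_equal(const$F, 0)
  expect_equal(const$p, 1)
  expect_error(variance_homogeneity(1:4, c("a", "a", "a", "b")), "two values")
})

test_that("k-sample Anderson-Darling statistic matches an independent reference", {
  # expected values frozen from an independent implementation of the
  # Scholz-Stephens midrank statistic and its tabulated p interpolation
  r <- ad_ksample(list(c(1.2, 2.3, 3.1, 4.0, 5.5), c(1.9, 2.8, 3.3, 4.4),
                       c(0.7, 1.1, 2.0, 2.9, 3.8, 6.0)))
  expect_equal(r$A2, -1.2414315204409567, tolerance = 1e-12)
  expect_equal(r$p, 0.25)
  expect_true(r$p_clamped)

  r_ties <- ad_ksample(list(c(1, 2, 2, 3, 5), c(2, 3, 3, 4, 6),
                            c(1, 1, 2, 5, 7)))
  expect_equal(r_ties$A2, -0.2923643990414222, tolerance = 1e-12)

  r_shift <- ad_ksample(list(c(1.1, 1.5, 2.0, 2.2, 2.9, 3.3, 1.8),
                             c(4.1, 4.5, 5.0, 5.2, 5.9, 6.3, 4.8),
                             c(1.0, 2.5, 3.0, 4.2, 5.1, 6.0, 2.2)))
  expect_equal(r_shift$A2, 4.150437192256262, tolerance = 1e-12)
  expect_equal(r_shift$p, 0.004577082466209442, tolerance = 1e-12)

  r_mid <- ad_ksample(list(c(1, 2, 3, 4, 5, 6, 7, 8),
                           c(1.5, 2.5, 3.5, 4.5, 5.5, 6.5, 7.5, 8.5),
                           c(5, 6, 7, 8, 9, 10, 11, 12)))
  expect_equal(r_mid$A2, 2.7537741146125674, tolerance = 1e-12)
  expect_equal(r_mid$p, 0.02068200976857641, tolerance = 1e-12)

  r_two <- ad_ksample(list(c(1.0, 2, 3, 4, 5, 6),
                           c(2.5, 3.5, 4.5, 5.5, 6.5, 7.5)))
  expect_equal(r_two$A2, 0.1572493330780069, tolerance = 1e-12)
})

test_that("the shape statistic is rank-based: invariant to a common location shift", {
  set.seed(33)
  g <- lapply(1:3, function(i) rnorm(15, i / 2))
  r0 <- ad_ksample(g)
  r1 <- ad_ksample(lapply(g, function(v) v + 2.71828))
  expect_equal(r1$A2, r0$A2, tolerance = 1e-12)
})

test_that("shape comparison keeps its size under the null and detects a shifted donor", {
  set.seed(34)
  null_high <- 0
  shift_low <- 0
  for (r in 1:100) {
    nullg <- lapply(1:3, function(i) rlnorm(20, 1, 0.4))
    if (ad_ksample(nullg)$p > 0.05) null_high <- null_high + 1
    sh <- list(rnorm(20, 1, 0.3), rnorm(20, 1, 0.3), rnorm(20, 2, 0.3))
    if (ad_ksample(sh)$p < 0.05) shift_low <- shift_low + 1
  }
  expect_gte(null_high, 90)
  expect_gte(shift_low, 90)
})

test_that("inducers with fewer than two peaks per donor subgroup are excluded", {
  input <- list(
    Bleo = list(YD = c(1.1, 1.6), OD = c(1.3, 1.9), RS = c(1.5, 2.2, 2.8)),
    Doxo = list(YD = c(1.2), OD = c(1.4, 2.0), RS = c(1.6, 2.1))
  )
  out <- shape_compare(input, min_peaks = 2)
  expect_true(out$included[out$inducer == "Bleo"])
  expect_false(out$included[out$inducer == "Doxo"])
  expect_identical(out$exclusion_reason[out$inducer == "Doxo"], "min_peaks")
  expect_true(is.na(out$A2[out$inducer == "Doxo"]))
  expect_false(is.na(out$p_adjusted[out$inducer == "Bleo"]))
  expect_match(attr(out, "caveat"), "random")
})

test_that("BH adjustment reproduces the step-up rule and its FDR readings", {
  p <- c(0.017, 0.075, 0.25, 0.25, 0.25)
  adj <- bh_adjust(p)
  expect_equal(min(adj), 0.085)
  expect_true(min(adj) < 0.10)  # significant under FDR control at 0.10
  expect_false(min(adj) < 0.05) # but not at 0.05
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(0.03, 4)), rep(0.03, 4))
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")

  set.seed(35)
  for (i in 1:20) {
    pr <- runif(sample(1:12, 1))
    adj <- bh_adjust(pr)
    expect_equal(adj, oracle_bh(pr))
    expect_true(all(adj >= pr))
    # BH rejects a superset of Bonferroni at the same level
    q <- 0.1
    expect_true(all(which(pmin(pr * length(pr), 1) <= q) %in% which(adj <= q)))
  }
})

test_that("group comparison picks Welch for two groups and Dunn flags the shifted group", {
  set.seed(36)
  hits <- 0
  for (r in 1:20) {
    g2 <- list(a = rnorm(30, 0), b = rnorm(30, 2))
    if (group_compare(g2)$p < 0.001) hits <- hits + 1
  }
  expect_gte(hits, 19)

  flagged_ok <- 0
  for (r in 1:20) {
    g3 <- list(a = rnorm(25, 0), b = rnorm(25, 0), c = rnorm(25, 1.5))
    gc <- group_compare(g3)
    expect_identical(gc$design, "multi-group")
    ph <- gc$posthoc
    involved <- ph$group1 == "c" | ph$group2 == "c"
    if (all(ph$p_adjusted[involved] < 0.05) && all(ph$p_adjusted[!involved] > 0.05)) {
      flagged_ok <- flagged_ok + 1
    }
  }
  expect_gte(flagged_ok, 18)

  ident <- group_compare(list(a = c(1, 2, 3, 4), b = c(1, 2, 3, 4)))
  expect_gt(ident$p, 0.9)
})
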