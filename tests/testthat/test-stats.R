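test_that("Hotelling T2 has its closed-form behaviour", {
  set.seed(40)
  X <- matrix(stats::rnorm(40 * 3), 40, 3)
  # identical groups: T2 = 0, p = 1
  ht0 <- hotelling_two_sample(X, X)
  expect_equal(ht0$T2, 0, tolerance = 1e-12)
  expect_equal(ht0$p, 1)
  # p = 1 reduces to the squared pooled-variance t statistic
  a <- matrix(stats::rnorm(25, 1), 25, 1)
  b <- matrix(stats::rnorm(30), 30, 1)
  ht1 <- hotelling_two_sample(a, b)
  tt <- stats::t.test(a, b, var.equal = TRUE)
  expect_equal(ht1$T2, unname(tt$statistic^2), tolerance = 1e-10)
  expect_equal(ht1$p, tt$p.value, tolerance = 1e-10)
  # dimension and size guards
  expect_error(hotelling_two_sample(a, matrix(0, 5, 2)), "dimension")
  expect_error(hotelling_two_sample(matrix(0, 2, 3), matrix(0, 2, 3)),
               "exceed")
})

test_that("singular pooled covariance fails informatively unless ridged", {
  set.seed(41)
  base <- stats::rnorm(20)
  # perfectly collinear columns make the pooled covariance singular
  expect_error(hotelling_two_sample(cbind(base, base),
                                    cbind(base, base) + 1),
               "ridge")
  ht <- hotelling_two_sample(cbind(base, base), cbind(base, base) + 1,
                             ridge = TRUE)
  expect_true(ht$ridged && is.finite(ht$p))
})

test_that("multivariate GLM terms reduce to the two-sample T2", {
  set.seed(42)
  Y <- matrix(stats::rnorm(70 * 3), 70, 3)
  grp <- factor(rep(c("autism", "NAI"), c(30, 40)))
  ht <- hotelling_two_sample(Y[grp == "autism", ], Y[grp == "NAI", ])
  mg <- mglm_terms(Y, data.frame(group = grp), ~ group)
  expect_equal(mg$p, ht$p, tolerance = 1e-8)
  expect_equal(mg$F, ht$F, tolerance = 1e-8)
  # aliased designs are reported
  d <- data.frame(group = grp, dup = as.integer(grp == "autism"))
  expect_error(mglm_terms(Y, d, ~ group + dup), "aliased")
})

test_that("post-hoc t tests match the standard oracle and threshold
           arithmetic", {
  set.seed(43)
  Y <- matrix(stats::rnorm(60 * 3), 60, 3)
  grp <- factor(rep(c("autism", "NAI"), each = 30))
  ph <- posthoc_t(Y, grp, reference = "NAI")
  for (g in 1:3) {
    tt <- stats::t.test(Y[grp == "NAI", g], Y[grp == "autism", g],
                        var.equal = TRUE)
    expect_equal(ph$t[g], unname(tt$statistic), tolerance = 1e-10)
    expect_equal(ph$p[g], tt$p.value, tolerance = 1e-10)
  }
  # a mirrored gradient (same values in both groups) gives t = 0
  Ym <- Y
  Ym[grp == "NAI", 2] <- Ym[grp == "autism", 2]
  expect_equal(posthoc_t(Ym, grp)$t[2], 0, tolerance = 1e-12)
  # the /k correction: a p around 0.03 clears 0.05 but not 0.05/3,
  # constructed with exact sample moments so the t value is deterministic
  a <- as.numeric(scale(stats::rnorm(30)))       # mean 0, sd 1 exactly
  b <- as.numeric(scale(stats::rnorm(30)))
  delta <- 2.2 * sqrt(2 / 30)                    # t = 2.2 on 58 df
  ph2 <- posthoc_t(cbind(c(a + delta, b)), factor(rep(c("x", "y"),
                                                      each = 30)),
                   reference = "x")
  expect_equal(ph2$t, 2.2, tolerance = 1e-10)
  expect_true(ph2$p > 0.05 / 3 && ph2$p < 0.05)
  expect_false(ph2$significant)
})

test_that("BH and Bonferroni flags agree with exhaustive oracles", {
  # worked example: all four rejected by step-up
  flags <- p_adjust_flags(c(0.01, 0.02, 0.03, 0.04), "bh_fdr", 0.05)
  expect_true(all(flags$significant))
  # degenerate families
  expect_false(any(p_adjust_flags(rep(1, 6), "bh_fdr", 0.05)$significant))
  expect_false(any(p_adjust_flags(rep(1, 6), "bonferroni", 0.05)$significant))
  expect_true(p_adjust_flags(0.04, "bh_fdr", 0.05)$significant)
  expect_true(p_adjust_flags(0.04, "bonferroni", 0.05)$significant)
  expect_error(p_adjust_flags(c(0.5, 1.2)), "\\[0, 1\\]")

  set.seed(44)
  for (i in 1:50) {
    m <- sample(1:20, 1)
    p <- stats::runif(m)^sample(1:3, 1)
    q <- stats::runif(1, 0.01, 0.2)
    expect_equal(p_adjust_flags(p, "bh_fdr", q)$significant,
                 oracle_bh(p, q))
    expect_equal(p_adjust_flags(p, "bonferroni", q)$significant,
                 oracle_bonferroni(p, q))
  }
})

test_that("detection power is monotone in the planted effect size", {
  mean_abs_t <- sapply(c(0.3, 0.8, 1.5), function(es) {
    vals <- sapply(1:3, function(r) {
      synth <- simulate_study("group-effect", n_per_group = 40,
                              seed = 400 + r, group_effect_size = es)
      X <- synth$observed$intra
      adj <- combat_fit_transform(X, synth$cohort$site,
                                  covariates = cbind(age = synth$cohort$age),
                                  protect = synth$cohort$group)$adjusted
      cols <- synth$truth$group_effect_pairs
      ph <- posthoc_t(adj[, cols, drop = FALSE], synth$cohort$group)
      mean(abs(ph$t))
    })
    mean(vals)
  })
  expect_true(all(diff(mean_abs_t) > 0))
})

test_that("the group workflow flags planted language-network pairs and is
           deterministic", {
  synth <- simulate_study("group-effect", n_per_group = 70, seed = 45)
  harm <- lapply(synth$observed, function(X)
    combat_fit_transform(X, synth$cohort$site,
                         covariates = cbind(age = synth$cohort$age),
                         protect = synth$cohort$group)$adjusted)
  st <- group_pipeline(harm, synth$cohort, synth$scheme, grad_config(),
                       contrast = "group")
  pa <- st$parcel[st$parcel$pattern == "intra", ]
  planted <- synth$truth$group_effect_pairs
  # most planted pairs pass the multivariate FDR gate and the G1 post-hoc
  expect_gte(mean(pa$significant[planted] & pa$sig_G1[planted]), 0.7)
  # the planted network is flagged at the network level on G1
  nw <- st$network[st$network$pattern == "intra" &
                     st$network$unit == "Lan", ]
  expect_true(nw$significant && nw$sig_G1)
  # direction: lower leftward asymmetry in the clinical group -> positive t
  expect_gt(nw$t_G1, 0)
  # re-running is hash-identical
  st2 <- group_pipeline(harm, synth$cohort, synth$scheme, grad_config(),
                        contrast = "group")
  expect_identical(st, st2)
})

test_that("within-group age contrasts use the three-pair Bonferroni
           family", {
  synth <- simulate_study("interaction", n_per_group = 45, seed = 46)
  harm <- list(intra = combat_fit_transform(
    synth$observed$intra, synth$cohort$site,
    protect = synth$cohort$group)$adjusted)
  st <- group_pipeline(harm, synth$cohort, synth$scheme, grad_config(),
                       contrast = "age")
  expect_true(all(st$parcel$contrast %in%
                    c("child vs adolescent", "child vs adult",
                      "adolescent vs adult")))
  expect_equal(st$parcel$significant, st$parcel$p < 0.05 / 3)
  # planted NAI age slope: child-vs-adult contrasts detected in NAI far
  # more often than in the flat autism group
  planted <- synth$truth$age_effect_pairs
  sub <- st$parcel[st$parcel$unit %in% as.character(planted) &
                     st$parcel$contrast == "child vs adult", ]
  expect_gt(mean(sub$significant[sub$group == "NAI"]),
            mean(sub$significant[sub$group == "autism"]))
})
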