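test_that("parcellation generation is mirrored, balanced and
           deterministic", {
  scheme <- make_parcellation(180, 12, seed = 1)
  expect_equal(nrow(scheme), 360)
  nets <- pair_networks(scheme)
  # homologs share networks by construction
  right_nets <- scheme$network[parcel_rows(scheme, "right")]
  expect_identical(nets, right_nets)
  expect_true(all(table(nets) >= 180 %/% 12))
  expect_identical(make_parcellation(4, 2, seed = 1),
                   make_parcellation(4, 2, seed = 1))
  expect_error(make_parcellation(2, 3), "more networks")
})

test_that("cohort simulation is deterministic with planted demographic
           offsets", {
  c1 <- simulate_cohort(70, 5, c(5, 40), seed = 7)
  c2 <- simulate_cohort(70, 5, c(5, 40), seed = 7)
  expect_identical(c1, c2)
  expect_equal(nrow(c1), 140)
  expect_equal(length(unique(c1$site)), 5)
  expect_true(all(table(c1$group, c1$site) > 0))
  expect_true(all(c1$age >= 5 & c1$age <= 40))
  expect_error(simulate_cohort(10, 2, c(40, 5)), "age range")

  # FIQ offset is detectable at n = 500 per group
  big <- simulate_cohort(500, 5, seed = 8, fiq_offset = -8)
  tt <- stats::t.test(fiq ~ group, data = big)
  expect_lt(tt$p.value, 0.05)
  expect_lt(mean(big$fiq[big$group == "autism"]),
            mean(big$fiq[big$group == "NAI"]))
})

test_that("AI feature generation is deterministic and respects the null", {
  scheme <- make_parcellation(60, 12, seed = 2)
  cohort <- simulate_cohort(30, 3, seed = 3)
  truth <- ground_truth(scheme, n_sites = 3, seed = 4,
                        group_effect_size = 0,
                        age_slope_by_group = list(NAI = 0, autism = 0),
                        site_shift_sd = 0, site_scale_sd = 0)
  # zero out the per-feature site effect realisations for a clean null
  truth$site_gamma[] <- 0
  truth$site_delta[] <- 1
  s1 <- simulate_ai_features(cohort, truth, seed = 5)
  s2 <- simulate_ai_features(cohort, truth, seed = 5)
  expect_identical(s1$observed, s2$observed)
  # conservation of symmetry: per-parcel mean AI is 0 within MC error
  mu <- colMeans(s1$observed$intra)
  se <- apply(s1$observed$intra, 2, stats::sd) / sqrt(nrow(cohort))
  expect_lt(mean(abs(mu) > 3 * se), 0.02)
})

test_that("planted group effects shift the designated pairs in the right
           direction", {
  synth <- simulate_study("group-effect", n_per_group = 200, seed = 9)
  truth <- synth$truth
  cols <- truth$group_effect_pairs
  bio <- synth$biological$intra
  d <- colMeans(bio[synth$cohort$group == "NAI", cols, drop = FALSE]) -
    colMeans(bio[synth$cohort$group == "autism", cols, drop = FALSE])
  # autism lower leftward: NAI minus autism positive, near the planted size
  expect_true(all(d > 0))
  expect_equal(mean(d), truth$group_effect_shift,
               tolerance = 0.15)
  # untouched pairs carry no effect
  other <- setdiff(seq_len(truth$n_pairs), cols)
  d0 <- colMeans(bio[synth$cohort$group == "NAI", other, drop = FALSE]) -
    colMeans(bio[synth$cohort$group == "autism", other, drop = FALSE])
  expect_lt(max(abs(d0)), 4 * truth$ai_noise_sd / sqrt(200))
})

test_that("noise-free symmetric construction yields identical hemispheric
           blocks and zero AI", {
  scheme <- make_parcellation(40, 12, seed = 10)
  cohort <- simulate_cohort(2, 1, seed = 11)
  truth <- ground_truth(scheme, n_sites = 1, seed = 12,
                        group_effect_size = 0,
                        age_slope_by_group = list(NAI = 0, autism = 0),
                        ai_noise_sd = 0, fc_noise_sd = 0)
  blocks <- simulate_connectomes(cohort, scheme, truth, seed = 13,
                                 subject_sd = 0)
  for (s in seq_along(blocks)) {
    expect_equal(blocks[[s]]$LL, blocks[[s]]$RR, tolerance = 1e-14)
    expect_equal(blocks[[s]]$LR, t(blocks[[s]]$RL))
  }
  expect_lt(max(abs(attr(blocks, "latent_ai"))), 1e-14)
  # planted left shift: left-minus-right latent score is negative for the
  # clinical group on effect pairs (lower leftward asymmetry)
  truth2 <- ground_truth(scheme, n_sites = 1, seed = 12,
                         age_slope_by_group = list(NAI = 0, autism = 0),
                         fc_noise_sd = 0)
  truth2$ai_noise_sd <- 0  # shift frozen at construction stays planted
  blocks2 <- simulate_connectomes(cohort, scheme, truth2, seed = 13,
                                  subject_sd = 0)
  lat <- attr(blocks2, "latent_ai")
  aut <- which(cohort$group == "autism")[1]
  cols <- truth2$group_effect_pairs
  expect_true(all(lat[aut, cols] < 0))
  expect_error(
    ground_truth(scheme, group_effect_pairs = c(1, 1000)),
    "out of range")
})

test_that("connectome generation is bit-reproducible and the time-series
           route carries the same structure", {
  scheme <- make_parcellation(30, 12, seed = 14)
  cohort <- simulate_cohort(2, 1, seed = 15)
  truth <- ground_truth(scheme, n_sites = 1, seed = 16)
  b1 <- simulate_connectomes(cohort, scheme, truth, seed = 17)
  b2 <- simulate_connectomes(cohort, scheme, truth, seed = 17)
  expect_identical(b1, b2)
  ts <- simulate_connectomes(cohort, scheme, truth, seed = 18,
                             emit = "timeseries", timepoints = 150)
  expect_equal(dim(ts[[1]]), c(150, 60))
  fc <- pearson_fc(ts[[1]])
  blocks <- split_blocks(fc, scheme)
  # within-hemisphere connectivity reflects the latent ring: neighbouring
  # parcels correlate more than antipodal ones
  near <- mean(blocks$LL[cbind(1:29, 2:30)])
  far <- mean(blocks$LL[cbind(1:15, 16:30)])
  expect_gt(near, far)
})

test_that("trait generation hits its design R2 and decouples RRB", {
  synth <- simulate_study("trait", n_per_group = 250, seed = 19,
                          trait_r2 = 0.3)
  cohort <- synth$cohort
  feats <- synth$biological$intra[, synth$truth$trait_features, drop = FALSE]
  fit <- stats::lm(cohort$ados_total ~ feats)
  expect_gt(summary(fit)$r.squared, 0.25)
  expect_lt(summary(fit)$r.squared, 0.35)
  # RRB is decoupled from the asymmetry features
  fit_rrb <- stats::lm(cohort$ados_rrb ~ feats)
  expect_lt(summary(fit_rrb)$r.squared, 0.05)
  expect_true(all(cohort$ados_total >= 0))
  expect_true(all(cohort$ados_total == round(cohort$ados_total)))

  # zero weights: trait independent of features
  null <- simulate_study("null", n_per_group = 250, seed = 20)
  nf <- null$biological$intra[, synth$truth$trait_features, drop = FALSE]
  fit0 <- stats::lm(null$cohort$ados_total ~ nf)
  expect_lt(summary(fit0)$r.squared, 0.05)
})

test_that("a single unit-weight noise-free trait is rank-identical to its
           feature", {
  scheme <- make_parcellation(30, 12, seed = 21)
  cohort <- simulate_cohort(50, 2, seed = 22)
  truth <- ground_truth(scheme, n_sites = 2, seed = 23,
                        n_trait_features = 1L, trait_r2 = 1)
  truth$trait_weights[] <- 1
  synth <- simulate_ai_features(cohort, truth, seed = 24)
  synth <- attach_trait_scores(synth, seed = 25, trait_mean = 500,
                               trait_sd = 40)
  feat <- synth$biological$intra[, truth$trait_features]
  # integerization aside, ranks coincide
  expect_gt(stats::cor(synth$cohort$ados_total, feat,
                       method = "spearman"), 0.999)
})

test_that("term map simulation is deterministic with a verbatim planted
           term", {
  m1 <- simulate_term_maps(24, 180, seed = 26)
  m2 <- simulate_term_maps(24, 180, seed = 26)
  expect_identical(m1, m2)
  expect_equal(ncol(m1), 24)
  expect_true(all(is.finite(m1)))
  planted <- stats::rnorm(180)
  m3 <- simulate_term_maps(10, 180, planted = planted, seed = 27)
  expect_identical(m3[, "planted"], planted)
  expect_error(simulate_term_maps(0), "n_terms")
})
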