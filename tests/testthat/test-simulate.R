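test_that("feature simulation is deterministic and respects space structure", {
  cfg <- simulation_config(n_timepoints = 200, seed = 9)
  f1 <- simulate_features(cfg, "audio-low")
  f2 <- simulate_features(cfg, "audio-low")
  expect_identical(f1$values, f2$values)
  expect_equal(ncol(f1$values), 6)
  expect_equal(ncol(simulate_features(cfg, "audio-high")$values), 8)
  expect_equal(ncol(simulate_features(cfg, "visual-low")$values), 2)
  h <- simulate_features(cfg, "visual-high")$values
  expect_true(all(h %in% c(0, 1)))
  expect_error(simulate_features(cfg, "tactile"), "audio-low")
})

test_that("zero sparsity yields an all-zero high-level matrix", {
  cfg <- simulation_config(n_timepoints = 100, sparsity = 0, seed = 2)
  expect_true(all(simulate_features(cfg, "audio-high")$values == 0))
})

test_that("low-level lag-1 autocorrelation matches the generative coefficient", {
  cfg <- simulation_config(n_timepoints = 10000, ar1_coef = 0.5, seed = 3)
  x <- simulate_features(cfg, "visual-low")$values[, 1]
  ac <- stats::cor(x[-1], x[-length(x)])
  expect_equal(ac, 0.5, tolerance = 0.03)
})

test_that("noiseless responses are recovered with R^2 near 1", {
  cfg <- simulation_config(n_timepoints = 400, n_grayordinates = 8,
                           snr = Inf, site_sd = 0, seed = 21)
  des <- simulate_design_set(cfg)
  coh <- simulate_cohort(cfg)
  bold <- cohort_bold(coh, des, 3)
  # oracle refit: all features jointly, near-zero penalty
  Xall <- do.call(cbind, lapply(des, function(d) d$values))
  oracle <- fit_ridge_cv(Xall, bold[1, ], penalty_grid = 1e-6)
  expect_gte(oracle$r2, 0.999)
  # full stacked pipeline also approaches the ceiling
  fit <- fit_encoding(des, bold)
  expect_gt(mean(fit$r2_stacked), 0.9)
})

test_that("a pure single-space mixture is uncorrelated with other spaces", {
  cfg <- simulation_config(n_timepoints = 2000, n_grayordinates = 1,
                           snr = Inf, site_sd = 0, seed = 8)
  des <- simulate_design_set(cfg)
  coefs <- lapply(cfg$feature_dims, function(p) matrix(rnorm(p), p, 1))
  names(coefs) <- names(cfg$feature_dims)
  w <- matrix(c(1, 0, 0, 0), 1, 4,
              dimnames = list(NULL, names(cfg$feature_dims)))
  bold <- simulate_bold(cfg, des, list(weights = w, coefs = coefs))
  for (k in c("audio-high", "visual-low", "visual-high")) {
    pred <- des[[k]]$values %*% coefs[[k]]
    expect_lt(abs(stats::cor(drop(bold), drop(pred))), 0.1)
  }
})

test_that("mismatched time axes are rejected", {
  cfg <- simulation_config(n_timepoints = 100, seed = 1)
  cfg2 <- simulation_config(n_timepoints = 80, seed = 1)
  des_short <- simulate_design_set(cfg2)
  coh <- simulate_cohort(cfg)
  truth <- list(weights = coh$truth$subject_weights[[1]],
                coefs = coh$truth$coefs)
  expect_error(simulate_bold(cfg, des_short, truth), "time axis")
})

test_that("stacked R^2 matches the snr variance-ratio identity", {
  cfg <- simulation_config(n_timepoints = 5000, n_grayordinates = 20,
                           snr = 1, seed = 7)
  des <- simulate_design_set(cfg)
  coh <- simulate_cohort(cfg)
  fit <- fit_encoding(des, cohort_bold(coh, des, 5))
  expect_equal(mean(fit$r2_stacked), 0.5, tolerance = 0.05)
})

test_that("a zero preference shift leaves the groups identical in truth", {
  cfg <- simulation_config(n_subjects_per_group = 5, n_grayordinates = 24,
                           n_parcels = 6, n_timepoints = 100,
                           group_pref_shift = 0, seed = 13)
  coh <- simulate_cohort(cfg)
  diffs <- vapply(coh$truth$subject_weights,
                  function(w) max(abs(w - coh$truth$weights_base)),
                  numeric(1))
  expect_true(all(diffs == 0))
})

test_that("the injected shift is confined to designated parcels and recovered", {
  cfg <- simulation_config(n_subjects_per_group = 6, n_grayordinates = 24,
                           n_parcels = 6, n_timepoints = 600,
                           group_pref_shift = 0.3, snr = Inf, site_sd = 0,
                           seed = 31)
  des <- simulate_design_set(cfg)
  coh <- simulate_cohort(cfg)
  in_des <- coh$truth$parcel %in% coh$truth$designated
  # locality in truth: non-designated grayordinates never shifted
  for (w in coh$truth$subject_weights) {
    expect_equal(w[!in_des, ], coh$truth$weights_base[!in_des, ])
  }
  # pipeline recovery of the group difference in W_H - W_L (visual)
  pref <- vapply(seq_len(nrow(coh$phenotype)), function(i) {
    fit <- fit_encoding(des, cohort_bold(coh, des, i))
    mean(preference_index(fit, "high_vs_low_visual")[in_des])
  }, numeric(1))
  grp <- coh$phenotype$group
  recovered <- mean(pref[grp == "nonASD"]) - mean(pref[grp == "ASD"])
  expect_lt(abs(recovered - 0.3), 0.05)
})

test_that("weights pushed outside the simplex are re-projected with a warning", {
  cfg <- simulation_config(n_subjects_per_group = 4, n_grayordinates = 12,
                           n_parcels = 4, n_timepoints = 50,
                           group_pref_shift = 0.95, seed = 17)
  expect_warning(coh <- simulate_cohort(cfg), "simplex")
  for (w in coh$truth$subject_weights) {
    expect_true(all(w >= 0))
    expect_equal(rowSums(w), rep(1, nrow(w)), tolerance = 1e-10)
  }
})

test_that("simulated motion is nonnegative with the configured age trend", {
  cfg0 <- simulation_config(n_timepoints = 100, motion_age_slope = 0,
                            seed = 23)
  ages <- runif(500, 5, 21)
  fd0 <- simulate_motion(cfg0, ages)
  expect_true(all(unlist(fd0) >= 0))
  frac0 <- vapply(fd0, function(f) mean(f > 0.2), numeric(1))
  expect_lt(abs(stats::cor(frac0, ages, method = "spearman")), 0.15)
  cfgn <- simulation_config(n_timepoints = 100, motion_age_slope = -0.05,
                            seed = 23)
  fracn <- vapply(simulate_motion(cfgn, ages), function(f) mean(f > 0.2),
                  numeric(1))
  expect_lt(stats::cor(fracn, ages, method = "spearman"), -0.3)
  expect_error(simulate_motion(cfg0, c(10, -1)), "nonnegative")
})
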