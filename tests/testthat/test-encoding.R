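test_that("folds are contiguous, balanced, and partition the time axis", {
  f <- make_folds(10, 5)
  expect_equal(lengths(f), rep(2L, 5))
  f11 <- make_folds(11, 5)
  expect_equal(lengths(f11), c(3L, 2L, 2L, 2L, 2L))
  expect_equal(sort(unlist(f11)), 1:11)
  expect_equal(sum(duplicated(unlist(f11))), 0)
  expect_error(make_folds(3, 5), "exceeds")
})

test_that("R^2 follows the variance-about-the-mean definition", {
  expect_equal(score_r2(c(1, 2, 3), c(1, 2, 3)), 1)
  obs <- c(1, 2, 3, 4)
  expect_equal(score_r2(rep(mean(obs), 4), obs), 0)
  expect_equal(score_r2(c(2, 2, 3, 3), obs), 0.6)
  expect_warning(r <- score_r2(c(1, 2), c(5, 5)), "constant")
  expect_true(is.na(r))
})

test_that("cross-validated ridge recovers noiseless signal and not noise", {
  set.seed(10)
  X <- matrix(rnorm(400 * 5), 400)
  beta <- rnorm(5)
  y <- drop(X %*% beta)
  fit <- fit_ridge_cv(X, y)
  expect_gte(fit$r2, 0.999)
  expect_false(any(is.na(fit$heldout)))
  # null: responses independent of the design
  noise <- matrix(rnorm(100 * 500), 100, 500)
  nf <- fit_encoding(list(space = matrix(rnorm(500 * 5), 500)), noise)
  expect_lte(mean(nf$r2_space[, "space"]), 0.02)
  # infinite shrinkage: predictions collapse to training means
  big <- fit_ridge_cv(X, y, penalty_grid = 1e12)
  expect_lte(big$r2, 1e-6)
  expect_warning(flat <- fit_ridge_cv(X, rep(1, 400)), "zero-variance")
  expect_true(flat$flagged)
})

test_that("stacking finds the dominant model and breaks ties uniformly", {
  set.seed(11)
  y <- rnorm(300)
  noise <- rnorm(300)
  st <- stack_models(list(good = y, bad = noise), y,
                     scale_predictions = FALSE)
  expect_equal(unname(st$alpha), c(1, 0), tolerance = 0.01)
  st_sc <- stack_models(list(good = y / sd(y), bad = noise), y)
  expect_gt(st_sc$alpha[["good"]], 0.97)
  tie <- stack_models(list(a = y, b = y), y)
  expect_equal(unname(tie$alpha), c(0.5, 0.5), tolerance = 1e-3)
})

test_that("the QP solution matches the simplex grid-search oracle", {
  set.seed(12)
  for (i in 1:5) {
    P <- matrix(rnorm(200 * 3), 200)
    y <- drop(P %*% c(0.5, 0.3, 0.2)) + rnorm(200, sd = 0.5)
    st <- stack_models(P, y, scale_predictions = FALSE)
    Pc <- sweep(P, 2, colMeans(P))
    oracle <- simplex_grid_search(Pc, y - mean(y), step = 0.005)
    expect_lt(max(abs(st$alpha - oracle)), 0.01)
  }
})

test_that("stacking weights always lie on the simplex and dominate vertices", {
  set.seed(13)
  for (K in 2:4) {
    for (i in 1:5) {
      P <- matrix(rnorm(150 * K), 150)
      y <- rnorm(150)
      st <- stack_models(P, y)
      expect_gte(min(st$alpha), -1e-10)
      expect_lte(abs(sum(st$alpha) - 1), 1e-8)
      # convex-combination optimality against each vertex
      Pc <- sweep(P, 2, colMeans(P))
      Pc <- sweep(Pc, 2, apply(Pc, 2, sd), "/")
      yc <- y - mean(y)
      sse_stack <- sum((yc - Pc %*% st$alpha)^2)
      for (k in seq_len(K)) {
        expect_lte(sse_stack, sum((yc - Pc[, k])^2) + 1e-10)
      }
    }
  }
})

test_that("unique R^2 clipping covers all three branches exactly", {
  expect_equal(partition_unique_r2(0.3, -0.1), 0.3)  # negative clipped to 0
  expect_equal(partition_unique_r2(0.3, 0.5), 0.0)   # ceiling at stacked
  expect_equal(partition_unique_r2(0.3, 0.2), 0.1)   # plain subtraction
  # partition consistency: unique + clipped component = stacked, all branches
  s <- c(0.3, 0.3, 0.3, 0.0, -0.1)
  comp <- c(-0.1, 0.5, 0.2, 0.1, -0.2)
  u <- partition_unique_r2(s, comp)
  expect_equal(u + pmin(pmax(comp, 0), s), s)
})

test_that("preference indices are signed weight differences in [-1, 1]", {
  w <- c("visual-high" = 1, "visual-low" = 0, "audio-high" = 0.5,
         "audio-low" = 0.5)
  expect_equal(preference_index(w, "high_vs_low_visual"), 1)
  expect_equal(preference_index(w, "high_vs_low_audio"), 0)
  w2 <- c("visual-high" = 0.25, "visual-low" = 0.75)
  expect_equal(preference_index(w2, "high_vs_low_visual"), -0.5)
  expect_error(preference_index(w2, "visual_vs_audio"), "lacks")
})

test_that("the engine reports simplex weights and sensible R^2 per space", {
  cfg <- simulation_config(n_timepoints = 400, n_grayordinates = 10,
                           seed = 19)
  des <- simulate_design_set(cfg)
  coh <- simulate_cohort(cfg)
  fit <- fit_encoding(des, cohort_bold(coh, des, 2))
  expect_gte(min(fit$alpha), -1e-10)
  expect_equal(rowSums(fit$alpha), rep(1, 10), tolerance = 1e-8)
  expect_equal(dim(fit$r2_space), c(10L, 4L))
  expect_true(all(is.finite(fit$r2_stacked)))
})
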