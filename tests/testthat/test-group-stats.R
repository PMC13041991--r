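# small synthetic parcel-summary + phenotype pair
make_group_data <- function(n_per = 20, n_parcel = 3, site_sd = 0,
                            effect = 0, noise_sd = 0.05, seed = 1) {
  set.seed(seed)
  n <- 2 * n_per
  ph <- data.frame(
    subject_id = sprintf("s%02d", 1:n),
    group = rep(c("nonASD", "ASD"), each = n_per),
    age = runif(n, 6, 20),
    sex = sample(c("M", "F"), n, replace = TRUE),
    ses = rnorm(n, 50, 8),
    site = paste0("site", rep_len(1:3, n)),
    srs_total = rnorm(n, 60, 10))
  ph$sss <- round(pmin(pmax(rnorm(n, 4, 2), 0), 12))
  site_off <- rnorm(3, 0, site_sd)[rep_len(1:3, n)]
  rows <- lapply(seq_len(n_parcel), function(pc) {
    data.frame(subject_id = ph$subject_id, parcel = paste0("p", pc),
               metric = "m",
               value = 0.4 + effect * (ph$group == "ASD") + site_off +
                 rnorm(n, sd = noise_sd))
  })
  list(summaries = do.call(rbind, rows), phenotype = ph)
}

test_that("with no site variance the mixed fit matches ordinary least squares", {
  d <- make_group_data(site_sd = 0, effect = -0.1, seed = 5)
  res <- suppressMessages(fit_group_model(d$summaries, d$phenotype, "m",
                                          focal = "group"))
  one <- merge(d$summaries[d$summaries$parcel == "p1", ], d$phenotype,
               by = "subject_id")
  one$group01 <- as.numeric(one$group == "ASD")
  one$sex01 <- as.numeric(one$sex == "M")
  ref <- lm(value ~ group01 + age + sex01 + ses, data = one)
  expect_equal(res$estimate[res$parcel == "p1"],
               unname(coef(ref)["group01"]), tolerance = 1e-6)
  expect_true(all(res$converged))
})

test_that("a noiseless linear severity effect is recovered exactly", {
  d <- make_group_data(seed = 6)
  slope <- 0.01
  d$summaries$value <- 0.2 + slope *
    d$phenotype$srs_total[match(d$summaries$subject_id,
                                d$phenotype$subject_id)]
  # a zero-residual fit trips lme4's gradient checks; only the recovered
  # coefficient matters for the deterministic limit
  res <- suppressWarnings(
    fit_severity_model(d$summaries, d$phenotype, "m", focal = "srs"))
  expect_equal(res$estimate, rep(slope, 3), tolerance = 1e-8)
  # standardizing the severity input rescales the coefficient by its SD
  ph2 <- d$phenotype
  s <- sd(ph2$srs_total)
  ph2$srs_total <- as.numeric(scale(ph2$srs_total))
  res2 <- suppressWarnings(
    fit_severity_model(d$summaries, ph2, "m", focal = "srs"))
  expect_equal(res2$estimate, res$estimate * s, tolerance = 1e-6)
})

test_that("null severity coefficients are small and rarely significant", {
  hits <- 0
  for (r in 1:15) {
    d <- make_group_data(n_per = 25, noise_sd = 0.05, seed = 100 + r)
    res <- fit_severity_model(d$summaries, d$phenotype, "m", focal = "sss")
    hits <- hits + sum(abs(res$estimate / res$se) > 2)
  }
  expect_lte(hits / (15 * 3), 0.07)
})

test_that("the logit link maps outcomes before the linear fit", {
  d <- make_group_data(effect = -0.1, seed = 7)
  res <- suppressMessages(fit_group_model(d$summaries, d$phenotype, "m",
                                          focal = "group", link = "logit",
                                          logit_map = "r2"))
  expect_true(all(res$converged))
  expect_true(all(res$significant[1:3] ==
                    (res$q[1:3] <= 0.05)))
})

test_that("single-site data fall back to a fixed-effects fit with a warning", {
  d <- make_group_data(seed = 8)
  d$phenotype$site <- "site1"
  expect_warning(
    res <- fit_group_model(d$summaries, d$phenotype, "m", focal = "group"),
    "single site")
  expect_true(all(res$converged))
  expect_equal(res$site_sd, rep(0, 3))
})

test_that("the D'Agostino K-squared statistic matches its reference values", {
  # oracle values computed independently with scipy.stats.normaltest
  out <- dagostino_k2(dagostino_fixture())
  expect_equal(out$statistic, 0.3778637354472685, tolerance = 1e-10)
  expect_equal(out$z_skew, 0.5799623907366259, tolerance = 1e-10)
  expect_equal(out$z_kurt, -0.20373355339345975, tolerance = 1e-10)
  expect_equal(out$p.value, 0.8278429075951186, tolerance = 1e-10)
})

test_that("the demographic cascade routes by normality and variance", {
  set.seed(41)
  n <- 100
  ph <- data.frame(
    group = rep(c("ASD", "nonASD"), each = n),
    eqvar = c(rnorm(n, 0, 1), rnorm(n, 0.1, 1)),
    uneqvar = c(rnorm(n, 0, 1), rnorm(n, 0, 3)),
    skewed = c(rexp(n), rexp(n)),
    sex = "M")
  out <- demographic_tests(ph, c("eqvar", "uneqvar", "skewed"),
                           sex_col = NULL)
  expect_equal(out$test[out$measure == "eqvar"], "student_t")
  expect_equal(out$test[out$measure == "uneqvar"], "welch_t")
  expect_equal(out$test[out$measure == "skewed"], "mann_whitney_u")
  # identical non-normal samples: location test lands in the p = 1 region
  ph$same <- rep(rexp(n), 2)
  out2 <- demographic_tests(ph, "same", sex_col = NULL)
  expect_gt(out2$p[out2$measure == "same"], 0.9)
})

test_that("sex contrasts use Yates chi-squared or Fisher as appropriate", {
  big <- data.frame(group = rep(c("ASD", "nonASD"), c(108, 63)),
                    sex = c(rep("M", 90), rep("F", 18),
                            rep("M", 35), rep("F", 28)))
  out <- demographic_tests(big, character(0), sex_col = "sex")
  expect_equal(out$test, "chisq_yates")
  expect_equal(out$statistic, 14.23, tolerance = 0.005)
  small <- data.frame(group = rep(c("ASD", "nonASD"), c(10, 10)),
                      sex = c(rep("M", 9), "F", rep("M", 4), rep("F", 6)))
  out2 <- demographic_tests(small, character(0), sex_col = "sex")
  expect_equal(out2$test, "fisher_exact")
})
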