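#' Parcel-wise mixed-effects group model
#'
#' For each parcel, fits a linear mixed model of a pooled encoding metric on
#' a focal predictor plus the age/sex/SES covariates with a random intercept
#' for site, and FDR-corrects the focal p values across parcels
#' (Benjamini-Hochberg, one family per call). Group is coded 0 = nonASD,
#' 1 = ASD and sex 0 = F, 1 = M, so a negative group coefficient means the
#' metric is larger in the ASD group. With `link = "logit"` the outcome is
#' first mapped affinely into `(eps, 1 - eps)` (R^2-type metrics are clipped
#' to `[0, 1]`; preference indices are mapped by `(x + 1) / 2`) and
#' logit-transformed before the linear fit. Single-site data are refit
#' without the random term with a warning; non-converging parcels are
#' flagged and excluded from the FDR family.
#'
#' @param summaries Long parcel-summary table from [pool_parcels()] with a
#'   `subject_id` column (stack per-subject outputs with `rbind` after adding
#'   ids), or any data frame with columns `subject_id`, `parcel`, `metric`,
#'   `value`.
#' @param phenotypes Phenotype table with columns `subject_id`, `group`,
#'   `age`, `sex`, `ses`, `site`, and (for severity models) `srs_total` /
#'   `sss`.
#' @param metric Name of the metric to model.
#' @param focal One of `"group"`, `"srs"`, `"sss"`, `"age"`, `"age:group"`,
#'   `"age:srs"`.
#' @param link `"identity"` (default) or `"logit"`.
#' @param logit_map `"r2"` or `"preference"`: the affine map used under the
#'   logit link.
#' @param eps Squeeze margin for the logit map.
#' @param q_level FDR level for the `significant` flags.
#' @param min_n Minimum subjects with the outcome per parcel (default 10).
#' @return Data frame, one row per parcel: `parcel`, `estimate`, `se`, `p`,
#'   `q`, `significant`, `site_sd` (random-intercept SD), `n`, `converged`.
#' @export
fit_group_model <- function(summaries, phenotypes, metric,
                            focal = c("group", "srs", "sss", "age",
                                      "age:group", "age:srs"),
                            link = c("identity", "logit"),
                            logit_map = c("r2", "preference"),
                            eps = 1e-3, q_level = 0.05, min_n = 10) {
  focal <- match.arg(focal)
  link <- match.arg(link)
  logit_map <- match.arg(logit_map)
  dat <- summaries[summaries$metric == metric, , drop = FALSE]
  if (nrow(dat) == 0) stop("metric '", metric, "' not present in summaries")
  dat <- merge(dat, phenotypes, by = "subject_id")
  dat$group01 <- as.numeric(dat$group == "ASD")
  dat$sex01 <- as.numeric(dat$sex == "M")
  focal_var <- switch(focal, group = "group01", srs = "srs_total",
                      sss = "sss", age = "age",
                      "age:group" = "age:group01", "age:srs" = "age:srs_total")
  rhs <- switch(focal,
    group = "group01 + age + sex01 + ses",
    srs = "srs_total + age + sex01 + ses",
    sss = "sss + age + sex01 + ses",
    age = "age + sex01 + ses",
    "age:group" = "age * group01 + sex01 + ses",
    "age:srs" = "age * srs_total + sex01 + ses")

  parcels <- unique(dat$parcel)
  rows <- lapply(parcels, function(pc) {
    d <- dat[dat$parcel == pc & !is.na(dat$value), , drop = FALSE]
    res <- data.frame(parcel = pc, estimate = NA_real_, se = NA_real_,
                      p = NA_real_, site_sd = NA_real_, n = nrow(d),
                      converged = FALSE)
    if (nrow(d) < min_n) return(res)
    y <- d$value
    if (link == "logit") {
      y <- if (logit_map == "r2") pmin(pmax(y, 0), 1) else (y + 1) / 2
      y <- stats::qlogis(pmin(pmax(y, eps), 1 - eps))
    }
    d$y <- y
    multi_site <- length(unique(d$site)) > 1
    fit <- tryCatch({
      if (multi_site) {
        # singular fits (site variance estimated at 0) are legitimate here:
        # the site SD is reported, so the boundary message is suppressed
        m <- lmerTest::lmer(stats::as.formula(
          paste("y ~", rhs, "+ (1 | site)")), data = d,
          control = lme4::lmerControl(check.conv.singular = "ignore"))
        co <- stats::coef(summary(m))
        vc <- as.data.frame(lme4::VarCorr(m))
        list(co = co, site_sd = vc$sdcor[vc$grp == "site"])
      } else {
        warning("single site for parcel ", pc,
                "; refitting without the random intercept")
        m <- stats::lm(stats::as.formula(paste("y ~", rhs)), data = d)
        co <- stats::coef(summary(m))
        list(co = co, site_sd = 0)
      }
    }, error = function(e) NULL)
    if (is.null(fit)) return(res)
    co <- fit$co
    row_name <- intersect(c(focal_var, sub(":", ":", focal_var),
                            paste(rev(strsplit(focal_var, ":")[[1]]),
                                  collapse = ":")), rownames(co))[1]
    if (is.na(row_name)) return(res)
    res$estimate <- co[row_name, "Estimate"]
    res$se <- co[row_name, "Std. Error"]
    pcol <- grep("^Pr", colnames(co), value = TRUE)[1]
    res$p <- co[row_name, pcol]
    res$site_sd <- fit$site_sd
    res$converged <- TRUE
    res
  })
  out <- do.call(rbind, rows)
  out$q <- NA_real_
  out$significant <- FALSE
  fam <- which(out$converged & !is.na(out$p))
  if (length(fam)) {
    adj <- fdr_bh(out$p[fam], q_level)
    out$q[fam] <- adj$q
    out$significant[fam] <- adj$significant
  }
  n_dropped <- sum(!out$converged)
  if (n_dropped > 0) {
    message(n_dropped, " parcel(s) not fit (too few subjects or ",
            "non-convergence); excluded from the FDR family")
  }
  out[, c("parcel", "estimate", "se", "p", "q", "significant",
          "site_sd", "n", "converged")]
}

#' Parcel-wise severity model
#'
#' [fit_group_model()] with a continuous severity measure (SRS total or the
#' sensory subset score) as the focal predictor in place of diagnostic group.
#'
#' @inheritParams fit_group_model
#' @param focal `"srs"` or `"sss"`.
#' @return As [fit_group_model()].
#' @export
fit_severity_model <- function(summaries, phenotypes, metric,
                               focal = c("srs", "sss"), ...) {
  focal <- match.arg(focal)
  fit_group_model(summaries, phenotypes, metric, focal = focal, ...)
}

#' D'Agostino's K-squared normality test
#'
#' Omnibus normality test combining the transformed skewness and kurtosis
#' z statistics: `K^2 = Z_skew^2 + Z_kurt^2`, referred to a chi-squared
#' distribution with 2 degrees of freedom.
#'
#' @param x Numeric vector (n >= 20 recommended; n >= 8 required for the
#'   kurtosis component).
#' @return List with `statistic`, `p.value`, `z_skew`, `z_kurt`.
#' @export
dagostino_k2 <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 8) stop("need at least 8 observations")
  m <- mean(x)
  m2 <- mean((x - m)^2)
  m3 <- mean((x - m)^3)
  m4 <- mean((x - m)^4)
  g1 <- m3 / m2^1.5
  b2 <- m4 / m2^2
  # skewness: D'Agostino (1970) transformation
  y <- g1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  beta2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  W2 <- -1 + sqrt(2 * (beta2 - 1))
  delta <- 1 / sqrt(0.5 * log(W2))
  alpha <- sqrt(2 / (W2 - 1))
  if (y == 0) y <- 1
  z_skew <- delta * log(y / alpha + sqrt((y / alpha)^2 + 1))
  # kurtosis: Anscombe & Glynn (1983) transformation
  Eb2 <- 3 * (n - 1) / (n + 1)
  var_b2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xs <- (b2 - Eb2) / sqrt(var_b2)
  sqrt_beta1 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  A <- 6 + 8 / sqrt_beta1 * (2 / sqrt_beta1 + sqrt(1 + 4 / sqrt_beta1^2))
  term1 <- 1 - 2 / (9 * A)
  denom <- 1 + xs * sqrt(2 / (A - 4))
  term2 <- sign(denom) * abs((1 - 2 / A) / abs(denom))^(1 / 3)
  z_kurt <- (term1 - term2) / sqrt(2 / (9 * A))
  k2 <- z_skew^2 + z_kurt^2
  list(statistic = k2, p.value = stats::pchisq(k2, 2, lower.tail = FALSE),
       z_skew = z_skew, z_kurt = z_kurt)
}

#' Demographic comparisons with test-selection cascade
#'
#' For each continuous measure: within-group normality is assessed with
#' Shapiro-Wilk (n < 50) or D'Agostino's K-squared (n >= 50); if both groups
#' are normal, variance homogeneity is assessed with Levene's test, routing
#' to Student's t (equal variances), Welch's t (unequal variances), or a
#' two-sided Mann-Whitney U test (non-normal). The sex contingency table is
#' tested with a continuity-corrected chi-squared test, substituting
#' Fisher's exact test when any expected cell count falls below five. All
#' p values are Benjamini-Hochberg adjusted over the comparison family.
#'
#' @param phenotypes Data frame with a two-level `group` column.
#' @param measures Character vector of continuous measure columns.
#' @param sex_col Name of the sex column (`"sex"`), or `NULL` to skip it.
#' @param groups The two group labels to compare (default `ASD`, `nonASD`).
#' @param normality_alpha,levene_alpha Cascade decision levels (default 0.05).
#' @return Data frame: `measure`, `test`, `statistic`, `p`, `p_adj`.
#' @export
demographic_tests <- function(phenotypes, measures, sex_col = "sex",
                              groups = c("ASD", "nonASD"),
                              normality_alpha = 0.05, levene_alpha = 0.05) {
  g <- phenotypes[[if ("group" %in% names(phenotypes)) "group" else
    stop("phenotypes must have a 'group' column")]]
  keep <- g %in% groups
  dat <- phenotypes[keep, , drop = FALSE]
  g <- factor(dat$group, levels = groups)
  rows <- list()
  for (meas in measures) {
    x <- dat[[meas]]
    x1 <- x[g == groups[1] & !is.na(x)]
    x2 <- x[g == groups[2] & !is.na(x)]
    if (length(x1) < 3 || length(x2) < 3) {
      message("skipping '", meas, "': fewer than 3 observations in a group")
      next
    }
    norm_p <- vapply(list(x1, x2), function(v) {
      if (length(v) < 50) stats::shapiro.test(v)$p.value
      else dagostino_k2(v)$p.value
    }, numeric(1))
    if (all(norm_p > normality_alpha)) {
      lev <- car::leveneTest(x[!is.na(x)] ~ droplevels(g[!is.na(x)]),
                             center = mean)
      if (lev[1, "Pr(>F)"] > levene_alpha) {
        tt <- stats::t.test(x1, x2, var.equal = TRUE)
        rows[[meas]] <- data.frame(measure = meas, test = "student_t",
                                   statistic = unname(tt$statistic),
                                   p = tt$p.value)
      } else {
        tt <- stats::t.test(x1, x2, var.equal = FALSE)
        rows[[meas]] <- data.frame(measure = meas, test = "welch_t",
                                   statistic = unname(tt$statistic),
                                   p = tt$p.value)
      }
    } else {
      wt <- suppressWarnings(stats::wilcox.test(x1, x2,
                                                alternative = "two.sided"))
      rows[[meas]] <- data.frame(measure = meas, test = "mann_whitney_u",
                                 statistic = unname(wt$statistic),
                                 p = wt$p.value)
    }
  }
  if (!is.null(sex_col) && sex_col %in% names(dat)) {
    tab <- table(g, dat[[sex_col]])
    expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    if (any(expected < 5)) {
      ft <- stats::fisher.test(tab)
      rows[["sex"]] <- data.frame(measure = sex_col, test = "fisher_exact",
                                  statistic = unname(ft$estimate), p = ft$p.value)
    } else {
      ct <- stats::chisq.test(tab, correct = TRUE)
      rows[["sex"]] <- data.frame(measure = sex_col, test = "chisq_yates",
                                  statistic = unname(ct$statistic),
                                  p = ct$p.value)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out
}
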