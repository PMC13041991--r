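#' Configuration for the synthetic study generator
#'
#' Bundles and validates the parameters of the synthetic cohort: cohort and
#' grid sizes, acquisition timing, signal-to-noise ratio, noise
#' autocorrelation, the group shift of high- vs low-level visual mixing in
#' designated parcels, site structure, and the age-motion slope. Defaults are
#' the generator's reference study conditions: 30 subjects per group across 3
#' sites, TR 0.8 s, 2000 timepoints, snr 1, AR(1) noise with coefficient 0.5,
#' and a group preference shift of 0.3 confined to two designated
#' "pSTS-like" parcels.
#'
#' @param n_subjects_per_group Subjects per diagnostic group (>= 1).
#' @param n_grayordinates,n_parcels Spatial grid size; grayordinates are
#'   split evenly over parcels.
#' @param n_timepoints Number of TRs per simulated run.
#' @param tr_seconds Repetition time in seconds (> 0).
#' @param snr Ratio of signal SD to noise SD (may be `Inf` for noiseless).
#' @param ar1_coef AR(1) coefficient of noise and low-level features, in
#'   `[0, 1)`.
#' @param group_pref_shift Group difference injected into the high-minus-low
#'   visual mixing weight of designated parcels, in `[-1, 1]`.
#' @param site_count,site_sd Number of sites and SD of their response offsets.
#' @param motion_age_slope Slope of mean framewise displacement per year of
#'   age (negative: older children move less).
#' @param sparsity Stationary on-probability of high-level binary features.
#' @param block_len_trs Mean on-block length of high-level features, in TRs.
#' @param n_designated Number of designated parcels carrying the group shift.
#' @param feature_dims Named feature counts per space.
#' @param seed Master integer seed.
#' @return Validated list of class `sim_config`.
#' @export
simulation_config <- function(n_subjects_per_group = 30,
                              n_grayordinates = 120,
                              n_parcels = 12,
                              n_timepoints = 2000,
                              tr_seconds = 0.8,
                              snr = 1,
                              ar1_coef = 0.5,
                              group_pref_shift = 0.3,
                              site_count = 3,
                              site_sd = 0.1,
                              motion_age_slope = -0.03,
                              sparsity = 0.3,
                              block_len_trs = 8,
                              n_designated = 2,
                              feature_dims = c("audio-low" = 6,
                                               "audio-high" = 8,
                                               "visual-low" = 2,
                                               "visual-high" = 2),
                              seed = 1) {
  cfg <- as.list(environment())
  counts <- c(n_subjects_per_group, n_grayordinates, n_parcels, n_timepoints,
              site_count, n_designated)
  if (any(counts < 1)) stop("all counts must be >= 1")
  stopifnot(tr_seconds > 0, ar1_coef >= 0, ar1_coef < 1,
            abs(group_pref_shift) <= 1, snr > 0,
            sparsity >= 0, sparsity <= 1, n_designated <= n_parcels)
  structure(cfg, class = "sim_config")
}

ar1_series <- function(n, phi, innov_sd = 1) {
  if (phi == 0) return(stats::rnorm(n, sd = innov_sd))
  as.numeric(stats::filter(stats::rnorm(n, sd = innov_sd), phi,
                           method = "recursive"))
}

#' Simulate a feature matrix for one feature space
#'
#' Low-level spaces are smooth, temporally autocorrelated Gaussian AR(1)
#' processes (lag-1 autocorrelation `ar1_coef`) scaled to unit SD; high-level
#' spaces are blockwise binary indicators from a two-state Markov chain with
#' stationary on-probability `sparsity` and mean on-block length
#' `block_len_trs`. Deterministic given the config seed and space tag.
#'
#' @param config A [simulation_config()].
#' @param space One of `"audio-low"`, `"audio-high"`, `"visual-low"`,
#'   `"visual-high"`.
#' @return A [feature_matrix()] with `n_timepoints` rows.
#' @export
simulate_features <- function(config, space) {
  stopifnot(inherits(config, "sim_config"))
  if (!space %in% FEATURE_SPACES) {
    stop("unknown feature space '", space, "'; valid tags: ",
         paste(FEATURE_SPACES, collapse = ", "))
  }
  set.seed(config$seed + 17L * match(space, FEATURE_SPACES))
  Tn <- config$n_timepoints
  p <- config$feature_dims[[space]]
  high <- grepl("-high$", space)
  vals <- if (!high) {
    m <- vapply(seq_len(p), function(i) ar1_series(Tn, config$ar1_coef),
                numeric(Tn))
    m <- matrix(m, nrow = Tn)
    sweep(m, 2, apply(m, 2, stats::sd), "/")
  } else {
    s <- config$sparsity
    if (s == 0) {
      matrix(0, Tn, p)
    } else {
      p_off <- 1 / config$block_len_trs
      p_on <- min(1, s * p_off / (1 - s))
      vapply(seq_len(p), function(i) {
        x <- integer(Tn)
        x[1] <- stats::rbinom(1, 1, s)
        for (t in seq_len(Tn)[-1]) {
          x[t] <- if (x[t - 1] == 1) stats::rbinom(1, 1, 1 - p_off)
                  else stats::rbinom(1, 1, p_on)
        }
        as.numeric(x)
      }, numeric(Tn))
    }
  }
  colnames(vals) <- paste0(gsub("-", "_", space), "_", seq_len(p))
  feature_matrix(vals, space, config$tr_seconds)
}

#' Simulate all four feature spaces
#' @param config A [simulation_config()].
#' @return Named list of four [feature_matrix()] objects (the shared movie
#'   stimulus of the cohort).
#' @export
simulate_design_set <- function(config) {
  stats::setNames(lapply(FEATURE_SPACES, simulate_features, config = config),
                  FEATURE_SPACES)
}

#' Simulate grayordinate responses from known mixing weights
#'
#' Each grayordinate's response is the convex mixture (by its ground-truth
#' weights) of the standardized per-space predictions `X_k beta_k`, plus a
#' site offset and AR(1) Gaussian noise scaled so that signal SD / noise SD
#' equals the configured snr. Under this construction the population stacked
#' R^2 equals `snr^2 / (1 + snr^2)`.
#'
#' @param config A [simulation_config()].
#' @param designs Named list of [feature_matrix()] objects covering the
#'   spaces of `truth$coefs`, all with `n_timepoints` rows.
#' @param truth Per-subject ground truth: `weights` (grayordinate-by-space
#'   simplex matrix), `coefs` (named list of feature-by-grayordinate
#'   coefficient matrices), and optionally `site_offset` (scalar).
#' @param seed Seed for the noise stream (default: config seed).
#' @return Grayordinate-by-time response matrix with attribute `tr_seconds`.
#' @export
simulate_bold <- function(config, designs, truth, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  spaces <- colnames(truth$weights)
  stopifnot(!is.null(spaces), all(spaces %in% names(designs)))
  Tn <- config$n_timepoints
  lens <- vapply(designs[spaces], function(d) nrow(d$values), integer(1))
  if (any(lens != Tn)) {
    stop("designs do not share the configured time axis (n_timepoints)")
  }
  G <- nrow(truth$weights)
  set.seed(seed)
  signal <- matrix(0, Tn, G)
  for (k in spaces) {
    pred <- designs[[k]]$values %*% truth$coefs[[k]]      # T x G
    psd <- apply(pred, 2, stats::sd)
    psd[psd < 1e-12] <- 1
    pred <- sweep(sweep(pred, 2, colMeans(pred)), 2, psd, "/")
    signal <- signal + sweep(pred, 2, truth$weights[, k], "*")
  }
  sig_sd <- apply(signal, 2, stats::sd)
  noise_sd <- if (is.infinite(config$snr)) rep(0, G) else sig_sd / config$snr
  noise <- vapply(seq_len(G), function(g) {
    if (noise_sd[g] == 0) return(numeric(Tn))
    e <- ar1_series(Tn, config$ar1_coef)
    e / stats::sd(e) * noise_sd[g]
  }, numeric(Tn))
  offset <- if (is.null(truth$site_offset)) 0 else truth$site_offset
  out <- t(signal + matrix(noise, nrow = Tn) + offset)
  attr(out, "tr_seconds") <- config$tr_seconds
  out
}

#' Simulate a phenotyped cohort with known ground truth
#'
#' Builds the spatial ground truth (parcel assignment, baseline simplex
#' mixing weights, per-space tuning coefficients) and a phenotype table for
#' two groups. In the designated "pSTS-like" parcels, simulated-ASD subjects
#' have their visual-high weight shifted toward visual-low so that the group
#' mean difference in the high-minus-low visual preference equals
#' `group_pref_shift`; the per-subject shift magnitude covaries with the
#' subject's severity score. Weights pushed outside the simplex are clipped
#' to zero and renormalized with a warning. Sites are assigned round-robin
#' and carry Gaussian response offsets.
#'
#' @param config A [simulation_config()].
#' @return List with `phenotype` (data frame), `truth` (baseline weights,
#'   per-subject weights, coefficients, parcel labels, designated parcels,
#'   site offsets), and `config`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  G <- config$n_grayordinates
  K <- length(FEATURE_SPACES)
  per <- ceiling(G / config$n_parcels)
  parcel_names <- c(paste0("STS_like_", seq_len(config$n_designated)),
                    sprintf("parcel_%02d",
                            seq_len(config$n_parcels - config$n_designated)))
  parcel <- rep(parcel_names, each = per, length.out = G)
  designated <- parcel_names[seq_len(config$n_designated)]

  # baseline simplex weights: designated parcels keep headroom on the
  # visual-high coordinate so the default shift stays inside the simplex
  weights <- matrix(NA_real_, G, K, dimnames = list(NULL, FEATURE_SPACES))
  in_des <- parcel %in% designated
  n_des <- sum(in_des)
  if (n_des > 0) {
    vl <- stats::runif(n_des, 0.15, 0.25)
    vh <- stats::runif(n_des, 0.30, 0.40)
    a_split <- stats::runif(n_des, 0.3, 0.7)
    weights[in_des, "visual-low"] <- vl
    weights[in_des, "visual-high"] <- vh
    weights[in_des, "audio-low"] <- (1 - vl - vh) * a_split
    weights[in_des, "audio-high"] <- (1 - vl - vh) * (1 - a_split)
  }
  if (any(!in_des)) {
    raw <- matrix(stats::rgamma(sum(!in_des) * K, shape = 2), ncol = K)
    weights[!in_des, ] <- raw / rowSums(raw)
  }

  coefs <- lapply(FEATURE_SPACES, function(k) {
    matrix(stats::rnorm(config$feature_dims[[k]] * G),
           nrow = config$feature_dims[[k]])
  })
  names(coefs) <- FEATURE_SPACES

  n_per <- config$n_subjects_per_group
  n <- 2L * n_per
  group <- rep(c("nonASD", "ASD"), each = n_per)
  subject_id <- sprintf("sub-%03d", seq_len(n))

  # severity-linked shift multiplier, standardized so the ASD group mean
  # shift equals group_pref_shift exactly
  z <- stats::rnorm(n_per)
  z <- if (n_per > 1) (z - mean(z)) / stats::sd(z) else 0
  m <- pmin(pmax(1 + 0.25 * z, 0.3), 1.7)
  delta <- numeric(n)
  delta[group == "ASD"] <- config$group_pref_shift / 2 * m

  subject_weights <- vector("list", n)
  clipped_any <- FALSE
  for (i in seq_len(n)) {
    w <- weights
    if (delta[i] != 0 && n_des > 0) {
      w[in_des, "visual-high"] <- w[in_des, "visual-high"] - delta[i]
      w[in_des, "visual-low"] <- w[in_des, "visual-low"] + delta[i]
      if (any(w < 0)) {
        clipped_any <- TRUE
        w[w < 0] <- 0
        w <- w / rowSums(w)
      }
    }
    subject_weights[[i]] <- w
  }
  if (clipped_any) {
    warning("shifted weights left the simplex; clipped to zero and renormalized")
  }

  age <- stats::runif(n, 5.3, 21)
  p_male <- ifelse(group == "ASD", 90 / 108, 35 / 63)
  sex <- ifelse(stats::rbinom(n, 1, p_male) == 1, "M", "F")
  ses <- round(pmin(pmax(stats::rnorm(
    n, mean = ifelse(group == "ASD", 49.3, 54.4), sd = 10), 9), 66), 1)
  site <- paste0("site", rep_len(seq_len(config$site_count), n))
  srs <- numeric(n)
  srs[group == "ASD"] <- round(pmin(pmax(
    68 + 8 * z + stats::rnorm(n_per, sd = 3), 44), 90))
  srs[group == "nonASD"] <- round(pmin(pmax(
    stats::rnorm(n_per, 49, 7), 38), 73))
  lam <- ifelse(group == "ASD", 1.3, 0.35)
  items <- vapply(seq_len(3), function(j) pmin(stats::rpois(n, lam), 3),
                  numeric(n))
  scq <- 3 * stats::rbinom(n, 1, ifelse(group == "ASD", 0.5, 0.1))
  adhd <- group == "ASD" & stats::rbinom(n, 1, 483 / 659) == 1
  site_offsets <- stats::rnorm(config$site_count, 0, config$site_sd)

  phenotype <- data.frame(
    subject_id = subject_id,
    consensus_label = ifelse(group == "ASD", "Autism Spectrum Disorder",
                             "No Diagnosis Given"),
    group = group, adhd = adhd, age = age, sex = sex, ses = ses,
    site = site, srs_total = srs,
    srs_item20 = items[, 1], srs_item42 = items[, 2],
    srs_item58 = items[, 3], scq_item14 = scq)
  phenotype$sss <- sensory_subset_score(phenotype$srs_item20,
                                        phenotype$srs_item42,
                                        phenotype$srs_item58,
                                        phenotype$scq_item14)
  phenotype$adhd_stratum <- ifelse(group == "nonASD", "nonASD",
                                   ifelse(adhd, "ASD+ADHD", "ASD-ADHD"))

  list(phenotype = phenotype,
       truth = list(weights_base = weights,
                    subject_weights = subject_weights,
                    coefs = coefs, parcel = parcel,
                    designated = designated,
                    site_offsets = stats::setNames(
                      site_offsets, paste0("site", seq_len(config$site_count))),
                    severity_multiplier = stats::setNames(
                      delta * 2 / max(config$group_pref_shift, 1e-12),
                      subject_id)),
       config = config)
}

#' Simulated BOLD for one cohort subject
#'
#' Convenience wrapper: assembles the subject's ground truth (weights, shared
#' tuning, site offset) and calls [simulate_bold()] with a subject-specific
#' seed derived from the master seed.
#'
#' @param cohort Output of [simulate_cohort()].
#' @param designs Shared design set from [simulate_design_set()].
#' @param subject Subject index or id.
#' @return Grayordinate-by-time response matrix.
#' @export
cohort_bold <- function(cohort, designs, subject) {
  i <- if (is.character(subject)) {
    match(subject, cohort$phenotype$subject_id)
  } else subject
  stopifnot(!is.na(i), i >= 1, i <= nrow(cohort$phenotype))
  truth <- list(weights = cohort$truth$subject_weights[[i]],
                coefs = cohort$truth$coefs,
                site_offset = cohort$truth$site_offsets[[
                  cohort$phenotype$site[i]]])
  simulate_bold(cohort$config, designs, truth,
                seed = cohort$config$seed + 1000L + i)
}

#' Simulate per-subject framewise-displacement series
#'
#' Per-volume FD is drawn from a Gamma distribution whose mean decreases
#' with age at `motion_age_slope` (plus subject-level jitter), so the
#' expected fraction of volumes over the 0.2 mm cut decreases monotonically
#' in age when the slope is negative, and is age-independent at slope zero.
#'
#' @param config A [simulation_config()].
#' @param ages Nonnegative ages in years (one per subject, nonempty).
#' @param seed Seed (default derived from the config seed).
#' @return Named list of nonnegative FD series of length `n_timepoints`.
#' @export
simulate_motion <- function(config, ages, seed = config$seed + 5L) {
  stopifnot(inherits(config, "sim_config"), length(ages) > 0)
  if (any(ages < 0)) stop("ages must be nonnegative")
  set.seed(seed)
  out <- lapply(seq_along(ages), function(i) {
    mu <- max(0.03, 0.18 + config$motion_age_slope * (ages[i] - 12) +
                stats::rnorm(1, sd = 0.08))
    stats::rgamma(config$n_timepoints, shape = 2, scale = mu / 2)
  })
  names(out) <- sprintf("sub-%03d", seq_along(ages))
  out
}
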