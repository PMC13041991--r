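#' Temporal-permutation null for one grayordinate
#'
#' Repeatedly permutes the temporal order of the response, re-runs the full
#' fit procedure, and compares the observed statistic against the null
#' distribution with the add-one estimator
#' `p = (1 + #\{null >= observed\}) / (1 + n_perm)`. The default scheme is a
#' full random reordering; a block scheme (circular rotation of contiguous
#' blocks) is available for autocorrelation-aware nulls. Full shuffles are
#' anticonservative when the noise is autocorrelated.
#'
#' @param response Observed response vector.
#' @param fit_stat Function taking a response vector and returning the scalar
#'   statistic (e.g. stacked held-out R^2 from the full fit procedure).
#' @param n_perm Number of permutations (>= 1).
#' @param scheme `"full"` (default) or `"block"`.
#' @param block_len Block length for the block scheme.
#' @param seed Integer seed for the permutation stream.
#' @return List with `observed`, `null` (length `n_perm`), and `p`.
#' @export
permutation_null <- function(response, fit_stat, n_perm = 1000,
                             scheme = c("full", "block"), block_len = 10,
                             seed = 1) {
  scheme <- match.arg(scheme)
  stopifnot(n_perm >= 1)
  observed <- fit_stat(response)
  Tn <- length(response)
  set.seed(seed)
  null_stats <- vapply(seq_len(n_perm), function(i) {
    fit_stat(response[permute_time(Tn, scheme, block_len)])
  }, numeric(1))
  p <- (1 + sum(null_stats >= observed)) / (1 + n_perm)
  list(observed = observed, null = null_stats, p = p)
}

permute_time <- function(Tn, scheme, block_len) {
  if (scheme == "full") return(sample.int(Tn))
  n_blocks <- ceiling(Tn / block_len)
  blocks <- split(seq_len(Tn), rep(seq_len(n_blocks), each = block_len,
                                   length.out = Tn))
  unlist(blocks[sample.int(n_blocks)], use.names = FALSE)
}

#' Permutation significance for every grayordinate of a fit
#'
#' Batched version of [permutation_null()] with the stacked held-out R^2 as
#' the statistic: for each grayordinate the permuted response copies are laid
#' out as columns and pushed through the vectorized engine in chunks, which
#' is mathematically identical to refitting per permutation. Per-grayordinate
#' permutation streams are seeded as `seed + grayordinate index` so results
#' are reproducible under any parallel split.
#'
#' @param designs Named list of feature-space designs (see [fit_encoding()]).
#' @param bold Grayordinate-by-time response matrix.
#' @param n_perm Permutations per grayordinate.
#' @param scheme,block_len Permutation scheme, as in [permutation_null()].
#' @param seed Master integer seed.
#' @param q_level FDR level for the significance flags.
#' @param chunk_cols Max permuted columns per engine call (memory knob).
#' @param ... Passed to [fit_encoding()] (folds, penalty grid, ...).
#' @return Data frame with one row per grayordinate: `stat` (observed stacked
#'   R^2), `p`, `q` (Benjamini-Hochberg), `significant`.
#' @export
permutation_test <- function(designs, bold, n_perm = 1000,
                             scheme = c("full", "block"), block_len = 10,
                             seed = 1, q_level = 0.05, chunk_cols = 4000,
                             ...) {
  scheme <- match.arg(scheme)
  if (is.vector(bold)) bold <- matrix(bold, nrow = 1)
  G <- nrow(bold)
  Tn <- ncol(bold)
  fit <- fit_encoding(designs, bold, ...)
  observed <- fit$r2_stacked
  per_chunk <- max(1L, floor(chunk_cols / n_perm))
  p <- rep(NA_real_, G)
  for (start in seq(1L, G, by = per_chunk)) {
    gs <- seq(start, min(start + per_chunk - 1L, G))
    Yp <- matrix(NA_real_, length(gs) * n_perm, Tn)
    for (i in seq_along(gs)) {
      g <- gs[i]
      set.seed(seed + g)
      rows <- (i - 1L) * n_perm + seq_len(n_perm)
      for (j in seq_len(n_perm)) {
        Yp[rows[j], ] <- bold[g, permute_time(Tn, scheme, block_len)]
      }
    }
    nf <- fit_encoding(designs, Yp, ...)
    for (i in seq_along(gs)) {
      g <- gs[i]
      nulls <- nf$r2_stacked[(i - 1L) * n_perm + seq_len(n_perm)]
      p[g] <- (1 + sum(nulls >= observed[g])) / (1 + n_perm)
    }
  }
  adj <- fdr_bh(p, q_level)
  data.frame(grayordinate = seq_len(G), stat = observed, p = p,
             q = adj$q, significant = adj$significant)
}

#' Benjamini-Hochberg FDR adjustment with significance flags
#'
#' Step-up adjusted q values with enforced monotonicity (via
#' [stats::p.adjust()]) and flags at the requested level.
#'
#' @param p_values Numeric p values in (0, 1].
#' @param q_level FDR level (default 0.05).
#' @return List with `q` and logical `significant`; empty in, empty out.
#' @export
fdr_bh <- function(p_values, q_level = 0.05) {
  if (length(p_values) == 0) {
    return(list(q = numeric(0), significant = logical(0)))
  }
  ok <- !is.na(p_values)
  if (any(p_values[ok] <= 0 | p_values[ok] > 1)) {
    stop("p values must lie in (0, 1]")
  }
  q <- stats::p.adjust(p_values, method = "BH")
  list(q = q, significant = !is.na(q) & q <= q_level)
}

#' Pool grayordinate metrics into parcel summaries
#'
#' Per parcel and metric, the unweighted mean over grayordinates whose
#' significance flag is `TRUE`. Parcels with no significant grayordinate get
#' `NA` and `n_significant = 0`. Grayordinates missing from the atlas are
#' excluded and counted in the `"unlabeled"` attribute.
#'
#' @param metrics Grayordinate-by-metric numeric matrix or data frame (rows
#'   in atlas grayordinate order).
#' @param flags Logical significance flag per grayordinate.
#' @param atlas A `parcel_atlas` from [read_atlas()] or a data frame with
#'   columns `grayordinate`, `parcel`, `hemisphere`.
#' @return Long data frame: `parcel`, `hemisphere`, `metric`, `value`,
#'   `n_significant`, `n_total`.
#' @export
pool_parcels <- function(metrics, flags, atlas) {
  if (inherits(atlas, "parcel_atlas")) atlas <- atlas$table
  metrics <- as.matrix(metrics)
  G <- nrow(metrics)
  stopifnot(length(flags) == G)
  lab <- atlas$parcel[match(seq_len(G), atlas$grayordinate)]
  hemi <- atlas$hemisphere[match(seq_len(G), atlas$grayordinate)]
  unlabeled <- sum(is.na(lab))
  parcels <- unique(stats::na.omit(lab))
  rows <- lapply(parcels, function(pc) {
    in_pc <- !is.na(lab) & lab == pc
    sig <- in_pc & flags & !is.na(flags)
    vals <- if (any(sig)) colMeans(metrics[sig, , drop = FALSE])
            else rep(NA_real_, ncol(metrics))
    data.frame(parcel = pc, hemisphere = hemi[which(in_pc)[1]],
               metric = colnames(metrics), value = unname(vals),
               n_significant = sum(sig), n_total = sum(in_pc),
               row.names = NULL)
  })
  out <- do.call(rbind, rows)
  attr(out, "unlabeled") <- unlabeled
  out
}

#' Spearman-Brown corrected split-half noise ceiling per parcel
#'
#' Subjects are repeatedly split into random halves; per parcel, the Pearson
#' correlation between the two half-mean time series is averaged over splits,
#' then extrapolated to the full sample with the Spearman-Brown formula
#' `r_sb = 2 r / (1 + r)`. The ceiling on explainable R^2 is reported as
#' `r_sb^2`, the standard reliability-to-variance conversion.
#'
#' @param responses List (one element per subject, >= 4) of parcel-by-time
#'   matrices on a shared time axis, with identical parcel ordering.
#' @param n_splits Number of random splits to average (default 50).
#' @param seed Integer seed.
#' @return Data frame: `parcel`, `r` (mean split-half correlation), `r_sb`,
#'   `ceiling_r2`.
#' @export
split_half_noise_ceiling <- function(responses, n_splits = 50, seed = 1) {
  n_sub <- length(responses)
  if (n_sub < 4) stop("need at least 4 subjects for split-half reliability")
  dims <- vapply(responses, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop("all subjects must share parcel and time dimensions")
  }
  n_parcel <- dims[1, 1]
  set.seed(seed)
  r_acc <- matrix(NA_real_, n_splits, n_parcel)
  for (s in seq_len(n_splits)) {
    half <- sample.int(n_sub, n_sub %/% 2)
    m1 <- Reduce(`+`, responses[half]) / length(half)
    m2 <- Reduce(`+`, responses[-half]) / (n_sub - length(half))
    r_acc[s, ] <- vapply(seq_len(n_parcel), function(pc) {
      stats::cor(m1[pc, ], m2[pc, ])
    }, numeric(1))
  }
  r <- colMeans(r_acc)
  r_sb <- 2 * r / (1 + r)
  labels <- rownames(responses[[1]])
  if (is.null(labels)) labels <- paste0("parcel_", seq_len(n_parcel))
  data.frame(parcel = labels, r = r, r_sb = r_sb, ceiling_r2 = r_sb^2,
             row.names = NULL)
}

#' Spearman-Brown correction
#'
#' Extrapolates a split-half correlation to full test length:
#' `r_sb = 2 r / (1 + r)`.
#'
#' @param r Split-half correlation(s) in `[-1, 1]`.
#' @return Corrected reliability.
#' @export
spearman_brown <- function(r) {
  stopifnot(all(abs(r) <= 1, na.rm = TRUE))
  2 * r / (1 + r)
}
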