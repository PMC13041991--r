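#' @keywords internal
FEATURE_SPACES <- c("audio-low", "audio-high", "visual-low", "visual-high")

#' Construct a feature-matrix object
#'
#' Light container for a time-by-feature design matrix belonging to one
#' feature space, carrying its sampling interval and provenance flags.
#'
#' @param values Numeric time-by-feature matrix (no missing values).
#' @param space_tag One of `"audio-low"`, `"audio-high"`, `"visual-low"`,
#'   `"visual-high"` (or another descriptive tag, e.g. `"audio"` for a
#'   modality-combined space).
#' @param tr_seconds Sampling interval in seconds.
#' @param convolved,standardized Logical provenance flags.
#' @return An object of class `feature_matrix`.
#' @export
feature_matrix <- function(values, space_tag, tr_seconds,
                           convolved = FALSE, standardized = FALSE) {
  values <- as.matrix(values)
  if (anyNA(values)) stop("feature matrix must not contain missing values")
  if (is.null(colnames(values))) {
    colnames(values) <- paste0("f", seq_len(ncol(values)))
  }
  structure(
    list(values = values, space_tag = space_tag, tr_seconds = tr_seconds,
         column_names = colnames(values), convolved = convolved,
         standardized = standardized),
    class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %s: %d TRs x %d features (TR = %gs)%s%s\n",
              x$space_tag, nrow(x$values), ncol(x$values), x$tr_seconds,
              if (x$convolved) ", HRF-convolved" else "",
              if (x$standardized) ", z-scored" else ""))
  invisible(x)
}

#' Build an HRF-convolved, TR-locked, z-scored design matrix
#'
#' Convolves each raw feature column with the canonical double-gamma HRF at
#' the native sampling rate, downsamples to the scan TR by averaging within
#' TR bins, drops the initial volumes that are also discarded from the BOLD
#' series, and z-scores each column. Constant columns (zero variance after
#' convolution) are dropped with a warning naming them.
#'
#' @param raw Numeric time-by-feature matrix sampled uniformly at
#'   `native_rate` (sample i is at time `(i-1)/native_rate` seconds).
#' @param native_rate Sampling rate of `raw`, in Hz.
#' @param tr_seconds Scan repetition time in seconds.
#' @param n_trs Number of TRs covered by the stimulus (before discarding).
#' @param discard_initial Leading TRs to drop (default 10, matching the BOLD
#'   discard).
#' @param space_tag Feature-space tag stored on the result.
#' @param standardize If `FALSE`, skip the z-scoring step (useful for testing
#'   the linearity of convolution + binning).
#' @param hrf Optional pre-sampled HRF kernel at the native rate; defaults to
#'   [canonical_hrf()] with standard parameters.
#' @return A [feature_matrix()] with `n_trs - discard_initial` rows.
#' @export
build_design <- function(raw, native_rate, tr_seconds, n_trs,
                         discard_initial = 10, space_tag = "feature",
                         standardize = TRUE, hrf = NULL) {
  raw <- as.matrix(raw)
  if (is.null(colnames(raw))) colnames(raw) <- paste0("f", seq_len(ncol(raw)))
  needed <- ceiling(n_trs * tr_seconds * native_rate)
  if (nrow(raw) < needed) {
    stop(sprintf(
      "raw features cover %d samples but %d are needed (%d TRs x %gs at %g Hz); short by %d",
      nrow(raw), needed, n_trs, tr_seconds, native_rate, needed - nrow(raw)))
  }
  raw_sds <- apply(raw[seq_len(needed), , drop = FALSE], 2, stats::sd)
  if (any(raw_sds < 1e-12)) {
    warning("dropping constant feature column(s): ",
            paste(colnames(raw)[raw_sds < 1e-12], collapse = ", "))
    raw <- raw[, raw_sds >= 1e-12, drop = FALSE]
  }
  if (is.null(hrf)) hrf <- canonical_hrf(1 / native_rate)
  conv <- apply(raw, 2, function(col) {
    full <- stats::convolve(col, rev(hrf), type = "open")
    full[seq_len(nrow(raw))]
  })
  # TR binning: sample i (time (i-1)/rate) falls in bin floor(t/tr) + 1
  t_sample <- (seq_len(nrow(conv)) - 1) / native_rate
  bin <- floor(t_sample / tr_seconds) + 1L
  keep <- bin <= n_trs
  binned <- rowsum(conv[keep, , drop = FALSE], bin[keep]) /
    as.vector(table(bin[keep]))
  binned <- binned[seq_len(n_trs), , drop = FALSE]
  rownames(binned) <- NULL
  if (discard_initial > 0) {
    binned <- binned[-seq_len(discard_initial), , drop = FALSE]
  }
  sds <- apply(binned, 2, stats::sd)
  const <- sds < 1e-12
  if (any(const)) {
    warning("dropping constant feature column(s): ",
            paste(colnames(binned)[const], collapse = ", "))
    binned <- binned[, !const, drop = FALSE]
  }
  if (standardize && ncol(binned) > 0) binned <- scale(binned)
  feature_matrix(unclass(binned)[, , drop = FALSE], space_tag, tr_seconds,
                 convolved = TRUE, standardized = standardize)
}

#' Mean perceptual brightness of video frames
#'
#' Per frame, the mean over pixels of the luminance combination
#' 0.299 R + 0.587 G + 0.114 B, normalized to `[0, 1]`. Channel scale
#' (`[0, 1]` vs `[0, 255]`) is auto-detected from the maximum value.
#'
#' @param frames A list of height-by-width-by-3 RGB arrays, or a single such
#'   array.
#' @return Numeric vector of per-frame brightness values in `[0, 1]`.
#' @export
compute_brightness <- function(frames) {
  if (!is.list(frames)) frames <- list(frames)
  if (length(frames) == 0) stop("frames must be nonempty")
  mx <- max(vapply(frames, max, numeric(1)))
  denom <- if (mx > 1) 255 else 1
  vapply(frames, function(fr) {
    if (length(fr) == 0) stop("empty frame")
    fr <- fr / denom
    if (length(dim(fr)) != 3 || dim(fr)[3] != 3) {
      stop("each frame must be a height x width x 3 RGB array")
    }
    mean(0.299 * fr[, , 1] + 0.587 * fr[, , 2] + 0.114 * fr[, , 3])
  }, numeric(1))
}

#' The eight top-level audio ontology categories
#'
#' Category names, in output order, used when collapsing fine-grained audio
#' tagger classes to the highest ontology level.
#'
#' @return Character vector of length 8.
#' @export
audioset_categories <- function() {
  c("Human Sounds, Speech", "Human Sounds, NonSpeech", "Animal Sounds",
    "Music", "Natural Sounds", "Sounds of Things",
    "Source Ambiguous Sounds", "Channel, Environment, Background")
}

#' Collapse fine-grained audio class scores to the eight top-level categories
#'
#' Each output column is the within-window aggregate (maximum by default,
#' preserving the detection semantics of tagger scores; sum optionally) over
#' the member fine classes of one top-level category. Categories with no
#' member class in the input are zero.
#'
#' @param frame_scores Numeric window-by-class score matrix with fine class
#'   names as column names.
#' @param map Named character vector mapping each fine class name to one of
#'   the eight category names from [audioset_categories()].
#' @param agg Aggregation rule within category: `"max"` (default) or `"sum"`.
#' @return Window-by-8 matrix, columns ordered as [audioset_categories()].
#' @export
collapse_audioset <- function(frame_scores, map, agg = c("max", "sum")) {
  agg <- match.arg(agg)
  frame_scores <- as.matrix(frame_scores)
  cats <- audioset_categories()
  fine <- colnames(frame_scores)
  if (is.null(fine)) stop("frame_scores must have fine class names as colnames")
  unmapped <- setdiff(fine, names(map))
  if (length(unmapped)) {
    stop("unmapped audio class name(s): ", paste(unmapped, collapse = ", "))
  }
  bad <- setdiff(unname(map[fine]), cats)
  if (length(bad)) {
    stop("map targets outside the eight categories: ",
         paste(unique(bad), collapse = ", "))
  }
  out <- matrix(0, nrow(frame_scores), length(cats),
                dimnames = list(NULL, cats))
  for (k in cats) {
    members <- fine[map[fine] == k]
    if (length(members) == 0) next
    block <- frame_scores[, members, drop = FALSE]
    out[, k] <- if (agg == "max") apply(block, 1, max) else rowSums(block)
  }
  out
}

#' Principal-component reduction of a multichannel series
#'
#' Column-centers the input and returns the first `n_components` principal
#' component scores, ordered by descending explained variance. The sign of
#' each component is fixed so that its largest-magnitude loading is positive,
#' for reproducibility across platforms.
#'
#' @param series Numeric time-by-channel matrix.
#' @param n_components Number of components to keep (<= channel count).
#' @return Time-by-`n_components` score matrix with an
#'   `"explained_variance_ratio"` attribute.
#' @export
reduce_components <- function(series, n_components) {
  series <- as.matrix(series)
  if (n_components > ncol(series)) {
    stop(sprintf("n_components (%d) exceeds channel count (%d)",
                 n_components, ncol(series)))
  }
  pc <- stats::prcomp(series, center = TRUE, scale. = FALSE)
  rot <- pc$rotation[, seq_len(n_components), drop = FALSE]
  flip <- vapply(seq_len(n_components), function(i) {
    j <- which.max(abs(rot[, i]))
    if (rot[j, i] < 0) -1 else 1
  }, numeric(1))
  scores <- sweep(pc$x[, seq_len(n_components), drop = FALSE], 2, flip, "*")
  vars <- pc$sdev^2
  attr(scores, "explained_variance_ratio") <-
    vars[seq_len(n_components)] / sum(vars)
  scores
}
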