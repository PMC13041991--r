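#' Framewise displacement from rigid-body motion parameters
#'
#' Power-style FD: the sum of absolute backward differences of the three
#' translations (mm) plus the three rotations (radians) converted to arc
#' length on a sphere of `rotation_radius_mm`. The first volume has FD 0.
#'
#' @param trace Numeric volumes-by-6 matrix: translations x/y/z in mm then
#'   rotations x/y/z in radians (>= 2 volumes).
#' @param rotation_radius_mm Conversion radius in mm (default 50).
#' @return Nonnegative FD series, one value per volume.
#' @export
framewise_displacement <- function(trace, rotation_radius_mm = 50) {
  trace <- as.matrix(trace)
  if (nrow(trace) < 2) stop("need at least 2 volumes to compute FD")
  if (ncol(trace) != 6) stop("trace must have 6 columns (3 trans, 3 rot)")
  stopifnot(rotation_radius_mm > 0)
  d <- abs(diff(trace))
  fd <- rowSums(d[, 1:3, drop = FALSE]) +
    rotation_radius_mm * rowSums(d[, 4:6, drop = FALSE])
  c(0, fd)
}

#' Fraction-based run exclusion at a sweep of FD thresholds
#'
#' A run's `fraction_over` is the proportion of volumes with FD above
#' `fd_cut_mm`; the run fails a fraction threshold iff `fraction_over`
#' strictly exceeds it ("greater than" semantics, so a run sitting exactly at
#' a threshold passes). With the default sweep `(0.4, 0.6, 0.8)` the pass
#' flags are nested: pass at 40% implies pass at 60% implies pass at 80%.
#'
#' @param fd Nonnegative per-volume FD series (nonempty).
#' @param fd_cut_mm Per-volume FD cut in mm (default 0.2).
#' @param fraction_thresholds Proportions in (0, 1] to sweep.
#' @param subject_id,run_id Optional identifiers carried into the record.
#' @return One-row data frame: ids, `fraction_over`, and a logical `pass_X`
#'   column per threshold (X = percentage).
#' @export
fd_exclusion <- function(fd, fd_cut_mm = 0.2,
                         fraction_thresholds = c(0.4, 0.6, 0.8),
                         subject_id = NA_character_, run_id = NA_character_) {
  if (length(fd) == 0) stop("fd series is empty")
  if (any(fd < 0)) stop("fd values must be nonnegative")
  if (any(fraction_thresholds <= 0 | fraction_thresholds > 1)) {
    stop("fraction thresholds must lie in (0, 1]")
  }
  fraction_over <- mean(fd > fd_cut_mm)
  out <- data.frame(subject_id = subject_id, run_id = run_id,
                    fraction_over = fraction_over)
  for (th in fraction_thresholds) {
    out[[sprintf("pass_%d", round(100 * th))]] <- fraction_over <= th
  }
  out
}

#' QC table for a set of subject runs
#'
#' Applies [fd_exclusion()] to each run and returns one row per subject-run.
#'
#' @param fd_list Named list of per-run FD series (names = subject ids, or
#'   "subject.run").
#' @param ... Passed to [fd_exclusion()].
#' @return Data frame, one row per run.
#' @export
qc_table <- function(fd_list, ...) {
  rows <- lapply(names(fd_list), function(id) {
    fd_exclusion(fd_list[[id]], subject_id = id, ...)
  })
  do.call(rbind, rows)
}
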