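#' Canonical double-gamma haemodynamic response function
#'
#' Samples the canonical double-gamma HRF (difference of two gamma densities)
#' on a regular grid. With the default parameters the response gamma has shape
#' `peak_delay / peak_disp` = 6 and unit scale, so the kernel mode falls at
#' 5 s after onset; the undershoot peaks near 16 s and is scaled down by
#' `ratio`. The kernel is rescaled to unit peak so convolution preserves the
#' amplitude of an impulse.
#'
#' @param tr_seconds Sampling interval in seconds (> 0).
#' @param length_seconds Kernel support in seconds (>= 20).
#' @param peak_delay,peak_disp Delay and dispersion of the response gamma, in
#'   seconds.
#' @param undershoot_delay,undershoot_disp Delay and dispersion of the
#'   undershoot gamma, in seconds.
#' @param ratio Peak-to-undershoot amplitude ratio.
#' @return Numeric vector: the kernel sampled at `0, tr, 2 tr, ...` up to
#'   `length_seconds`, scaled to unit maximum.
#' @examples
#' h <- canonical_hrf(0.8)
#' plot(seq(0, by = 0.8, length.out = length(h)), h, type = "l")
#' @export
canonical_hrf <- function(tr_seconds, length_seconds = 32,
                          peak_delay = 6, peak_disp = 1,
                          undershoot_delay = 16, undershoot_disp = 1,
                          ratio = 6) {
  stopifnot(is.numeric(tr_seconds), length(tr_seconds) == 1, tr_seconds > 0)
  if (length_seconds < 20) {
    stop("length_seconds must be >= 20 to cover the undershoot")
  }
  t <- seq(0, length_seconds, by = tr_seconds)
  h <- stats::dgamma(t, shape = peak_delay / peak_disp, scale = peak_disp) -
    stats::dgamma(t, shape = undershoot_delay / undershoot_disp,
                  scale = undershoot_disp) / ratio
  h / max(h)
}
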