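#' Parameters for the heuristic signal-quality estimator
#'
#' The estimator is a documented rule-based stand-in for learned PPG quality
#' models: it flags samples by the union of three sliding-window rules and
#' reports the flagged fraction as the artifact-percentage estimate.
#'
#' @param window_s Window length for the flatline and amplitude rules,
#'   seconds.
#' @param hop_s Hop between windows, seconds.
#' @param flat_range_frac A window is a flatline if its range is below this
#'   fraction of the whole-segment range.
#' @param excursion_mult A window is an amplitude excursion if its range
#'   exceeds this multiple of the median window range.
#' @param spectral_window_s Window length for the spectral-plausibility rule,
#'   seconds (longer, for frequency resolution).
#' @param hr_band_hz Plausible heart-rate band in Hz; windows whose dominant
#'   frequency falls outside are flagged.  The default 0.5--3.7 Hz covers
#'   30--222 beats/min.
#' @param anchor_threshold Segments with estimated y at or below this value
#'   are labelled high quality.
#' @return A list with class \code{quality_params}.
#' @export
quality_params <- function(window_s = 2, hop_s = 1,
                           flat_range_frac = 0.04,
                           excursion_mult = 1.8,
                           spectral_window_s = 4,
                           hr_band_hz = c(0.5, 3.7),
                           anchor_threshold = 0) {
  structure(list(window_s = window_s, hop_s = hop_s,
                 flat_range_frac = flat_range_frac,
                 excursion_mult = excursion_mult,
                 spectral_window_s = spectral_window_s,
                 hr_band_hz = hr_band_hz,
                 anchor_threshold = anchor_threshold),
            class = "quality_params")
}

sliding_windows <- function(n, win, hop) {
  starts <- seq(1L, max(1L, n - win + 1L), by = hop)
  # make sure the tail is covered
  if (tail(starts, 1) + win - 1L < n) starts <- c(starts, n - win + 1L)
  starts
}

#' Estimate a per-sample artifact mask for a PPG segment
#'
#' Union of three rules evaluated over sliding windows and expanded to
#' sample resolution: (a) flatline -- window range below a fraction of the
#' segment range; (b) amplitude excursion -- window range above a multiple of
#' the median window range; (c) spectral implausibility -- dominant window
#' frequency outside the plausible heart-rate band.  An all-constant segment
#' is flagged entirely.
#'
#' @param segment Numeric vector, at least 2 s of samples.
#' @param fs Sampling rate, Hz.
#' @param params A \code{\link{quality_params}}.
#' @return Logical vector the length of \code{segment}.
#' @export
estimate_artifact_mask <- function(segment, fs, params = quality_params()) {
  if (is.null(params)) params <- quality_params()
  n <- length(segment)
  if (n < 2 * fs) stopf("segment too short: need >= 2 s (%d samples), got %d",
                        2 * fs, n)
  seg_range <- diff(range(segment))
  if (seg_range == 0) return(rep(TRUE, n))

  mask <- logical(n)
  win <- round(params$window_s * fs)
  hop <- round(params$hop_s * fs)
  starts <- sliding_windows(n, win, hop)
  ranges <- vapply(starts, function(s) {
    w <- segment[s:(s + win - 1L)]
    diff(range(w))
  }, 0)
  flat <- ranges < params$flat_range_frac * seg_range
  # reference amplitude from the low quartile of non-flat windows: robust to
  # segments where artifact bursts dominate and would inflate a median
  ref_range <- if (any(!flat)) quantile(ranges[!flat], 0.25, names = FALSE)
               else Inf
  exc <- ranges > params$excursion_mult * ref_range
  for (i in seq_along(starts)) {
    if (flat[i] || exc[i])
      mask[starts[i]:(starts[i] + win - 1L)] <- TRUE
  }

  swin <- round(params$spectral_window_s * fs)
  if (swin <= n) {
    sstarts <- sliding_windows(n, swin, swin %/% 2)
    for (s in sstarts) {
      idx <- s:(s + swin - 1L)
      # windows dominated by already-flagged (flatline/excursion) samples are
      # rule (a)/(b) territory; their spectra are step-artifacts, not rhythm
      if (mean(mask[idx]) > 0.25) next
      w <- segment[idx]
      if (diff(range(w)) == 0) { mask[idx] <- TRUE; next }
      f <- dominant_frequency(w, fs)
      if (f < params$hr_band_hz[1] || f > params$hr_band_hz[2])
        mask[idx] <- TRUE
    }
  }
  mask
}

#' Assess the quality of a PPG segment
#'
#' Runs \code{\link{estimate_artifact_mask}} and summarizes it: the estimated
#' artifact fraction \code{y_estimate} is the flagged-sample fraction, and
#' the binary label is \code{"high"} iff \code{y_estimate} is at or below the
#' anchor threshold.
#'
#' @inheritParams estimate_artifact_mask
#' @return A list of class \code{quality_assessment} with
#'   \code{binary_label} (\code{"high"}/\code{"low"}), \code{mask_estimate}
#'   and \code{y_estimate}.
#' @examples
#' x <- minmax_normalize(simulate_clean_ppg(60, 30, 40))
#' assess_quality(x, 40)$binary_label  # "high"
#' @export
assess_quality <- function(segment, fs, params = quality_params()) {
  if (is.null(params)) params <- quality_params()
  mask <- estimate_artifact_mask(segment, fs, params)
  y <- mean(mask)
  structure(list(binary_label = if (y <= params$anchor_threshold) "high" else "low",
                 mask_estimate = mask, y_estimate = y),
            class = "quality_assessment")
}
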