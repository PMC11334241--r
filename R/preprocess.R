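#' @rdname preprocess_recording
#' @export
new_ppg_segment <- function(samples, y, t, patient_id, segment_id, fs,
                            meta = list()) {
  assert_fraction(y, "y")
  structure(list(samples = as.numeric(samples), y = y, t = t,
                 patient_id = as.character(patient_id),
                 segment_id = as.character(segment_id), fs = fs, meta = meta),
            class = "ppg_segment")
}

new_ppg_segments <- function(segments) {
  structure(segments, class = "ppg_segments")
}

#' @export
print.ppg_segments <- function(x, ...) {
  df <- as.data.frame(x)
  cat(sprintf("<ppg_segments> %d segments from %d patient(s); mean y = %.3f\n",
              nrow(df), length(unique(df$patient_id)), mean(df$y)))
  invisible(x)
}

#' @export
`[.ppg_segments` <- function(x, i) new_ppg_segments(unclass(x)[i])

#' @export
as.data.frame.ppg_segments <- function(x, ...) {
  data.frame(segment_id = vapply(x, `[[`, "", "segment_id"),
             patient_id = vapply(x, `[[`, "", "patient_id"),
             t = vapply(x, `[[`, 0, "t"),
             y = vapply(x, `[[`, 0, "y"),
             n_samples = vapply(x, function(s) length(s$samples), 0L),
             stringsAsFactors = FALSE)
}

# stack segment samples into a (n_samples x n_segments) matrix
segment_matrix <- function(segments) {
  vapply(segments, `[[`, numeric(length(segments[[1]]$samples)), "samples")
}

#' Cut a recording into non-overlapping fixed-length windows
#'
#' Consecutive, non-overlapping windows of \code{segment_seconds}; a trailing
#' remainder shorter than one window is dropped.  Window k (0-based) starts
#' at \code{start_time + k * segment_seconds}.
#'
#' @param rec A \code{ppg_recording}.
#' @param segment_seconds Window length in seconds (> 0).
#' @return A list of raw windows, each a list with \code{samples},
#'   \code{mask}, \code{t} (start time, seconds) and \code{first} (1-based
#'   index of the window's first sample in the recording).
#' @export
segment_recording <- function(rec, segment_seconds = 30) {
  stopifnot(inherits(rec, "ppg_recording"))
  if (!is.numeric(segment_seconds) || segment_seconds <= 0)
    stopf("`segment_seconds` must be positive")
  win <- round(segment_seconds * rec$fs)
  n <- length(rec$samples)
  n_seg <- n %/% win
  if (n_seg == 0) return(list())
  lapply(seq_len(n_seg), function(k) {
    idx <- seq((k - 1L) * win + 1L, k * win)
    list(samples = rec$samples[idx], mask = rec$artifact_mask[idx],
         t = rec$start_time + (k - 1) * segment_seconds, first = idx[1])
  })
}

#' Downsample a signal with anti-alias filtering
#'
#' Zero-phase low-pass filtering (4th-order Butterworth, cutoff
#' \code{0.45 * fs_out}, applied forwards and backwards via
#' \code{signal::filtfilt}) followed by decimation.  The integer-ratio path
#' is the only one supported: \code{fs_in} must be a multiple of
#' \code{fs_out}.  With \code{fs_in == fs_out} the input is returned
#' unchanged.
#'
#' @param samples Numeric vector.
#' @param fs_in Input sampling rate, Hz.
#' @param fs_out Output sampling rate, Hz (<= \code{fs_in}).
#' @return Numeric vector of length \code{round(length(samples) * fs_out / fs_in)}.
#' @export
downsample <- function(samples, fs_in, fs_out) {
  if (!is.numeric(fs_in) || !is.numeric(fs_out) || fs_out <= 0)
    stopf("sampling rates must be positive")
  if (fs_out > fs_in) stopf("`fs_out` (%g) must not exceed `fs_in` (%g)",
                            fs_out, fs_in)
  if (fs_in == fs_out) return(samples)
  r <- fs_in / fs_out
  if (abs(r - round(r)) > 1e-9)
    stopf("`fs_in` must be an integer multiple of `fs_out` (got ratio %g)", r)
  r <- round(r)
  bf <- signal::butter(4, 0.45 * fs_out / (fs_in / 2))
  filtered <- signal::filtfilt(bf, samples)
  filtered[seq(1, length(samples), by = r)]
}

#' Min-max normalize a signal to [0, 1]
#'
#' \code{(x - min) / (max - min)}; a constant input maps to all zeros rather
#' than erroring, since flatline artifact segments occur in practice and must
#' not crash the pipeline.
#'
#' @param samples Non-empty numeric vector.
#' @return Numeric vector with minimum 0 and maximum 1 (non-constant input).
#' @export
minmax_normalize <- function(samples) {
  if (!length(samples)) stopf("`samples` must be non-empty")
  lo <- min(samples)
  hi <- max(samples)
  if (hi == lo) return(numeric(length(samples)))
  (samples - lo) / (hi - lo)
}

#' Attach artifact-fraction labels to raw windows
#'
#' Computes y for each window either from the recording's ground-truth mask
#' (the flagged-sample fraction) or from an externally supplied label table.
#'
#' @param raw_segments Output of \code{\link{segment_recording}}.
#' @param rec The source \code{ppg_recording} (for ground-truth labels), or
#'   \code{NULL} when \code{labels} is given.
#' @param labels Optional data.frame with columns \code{t} and \code{y}; must
#'   cover every window start time.
#' @return Numeric vector of y values, one per window.
#' @export
label_segments <- function(raw_segments, rec = NULL, labels = NULL) {
  if (!is.null(labels)) {
    idx <- match(vapply(raw_segments, `[[`, 0, "t"), labels$t)
    if (anyNA(idx)) {
      missing_t <- vapply(raw_segments, `[[`, 0, "t")[is.na(idx)]
      stopf("missing labels for segment(s) starting at t = %s",
            paste(missing_t, collapse = ", "))
    }
    return(labels$y[idx])
  }
  if (is.null(rec)) stopf("either `rec` or `labels` must be supplied")
  vapply(raw_segments, function(s) mean(s$mask), 0)
}

#' Preprocess a recording into normalized, labelled 30 s segments
#'
#' The standard pipeline: non-overlapping segmentation, per-segment
#' anti-aliased downsampling to \code{target_fs}, per-segment min-max
#' normalization, and artifact-fraction labelling.  Labels come from the
#' ground-truth mask (\code{labels = "truth"}, computed at the original
#' sampling rate before decimation) or from the heuristic quality estimator
#' (\code{labels = "estimate"}).
#'
#' @param rec A \code{ppg_recording}.
#' @param segment_seconds Segment length, seconds (default 30).
#' @param target_fs Output sampling rate, Hz (default 40).
#' @param labels \code{"truth"} or \code{"estimate"}.
#' @param quality_params Parameters for the estimator when
#'   \code{labels = "estimate"}; see \code{\link{quality_params}}.
#' @return A \code{ppg_segments} collection of \code{ppg_segment} objects
#'   (fields \code{samples}, \code{y}, \code{t}, \code{patient_id},
#'   \code{segment_id}, \code{fs}).
#' @examples
#' rec <- make_corpus(1, 2, fs = 240, seed = 1)[[1]]
#' segs <- preprocess_recording(rec)
#' as.data.frame(segs)
#' @export
preprocess_recording <- function(rec, segment_seconds = 30, target_fs = 40,
                                 labels = c("truth", "estimate"),
                                 quality_params = NULL) {
  labels <- match.arg(labels)
  raw <- segment_recording(rec, segment_seconds)
  if (!length(raw)) return(new_ppg_segments(list()))
  ys <- if (labels == "truth") label_segments(raw, rec) else NA
  segs <- lapply(seq_along(raw), function(k) {
    s <- raw[[k]]
    x <- downsample(s$samples, rec$fs, target_fs)
    x <- minmax_normalize(x)
    y <- if (labels == "truth") ys[k] else {
      qa <- assess_quality(x, target_fs, params = quality_params)
      qa$y_estimate
    }
    new_ppg_segment(x, y, s$t, rec$patient_id,
                    sprintf("%s_%04d", rec$patient_id, k), target_fs,
                    meta = rec$meta["hr_bpm"])
  })
  new_ppg_segments(segs)
}

#' Preprocess a corpus of recordings
#'
#' Applies \code{\link{preprocess_recording}} to each recording and
#' concatenates the results.
#'
#' @inheritParams preprocess_recording
#' @param corpus List of \code{ppg_recording} objects.
#' @return A \code{ppg_segments} collection.
#' @export
preprocess_corpus <- function(corpus, segment_seconds = 30, target_fs = 40,
                              labels = "truth", quality_params = NULL) {
  out <- lapply(corpus, preprocess_recording, segment_seconds = segment_seconds,
                target_fs = target_fs, labels = labels,
                quality_params = quality_params)
  new_ppg_segments(do.call(c, lapply(out, unclass)))
}
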