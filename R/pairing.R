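#' Configuration for temporal-quality pairing
#'
#' @param window_seconds Width of the two-sided temporal search window around
#'   each anchor, seconds (default 300, i.e. 5 minutes).
#' @param low_quality_threshold Candidates must have artifact fraction
#'   strictly above this value (default 0.2).
#' @param anchor_threshold Anchors must have artifact fraction at or below
#'   this value (default 0: exactly clean).  A small positive value is useful
#'   when y is estimated rather than ground truth.
#' @param selection \code{"max_distance"} picks the candidate with the
#'   largest |t_candidate - t_anchor| (the stated intent of the pairing
#'   search); \code{"max_index"} picks the candidate with the largest
#'   timestamp (the literal max-index rule), which differs for mid-recording
#'   anchors because the window is two-sided.
#' @return A list of class \code{pairing_config}.
#' @export
pairing_config <- function(window_seconds = 300,
                           low_quality_threshold = 0.2,
                           anchor_threshold = 0,
                           selection = c("max_distance", "max_index")) {
  if (!is.numeric(window_seconds) || window_seconds <= 0)
    stopf("`window_seconds` must be positive")
  assert_fraction(low_quality_threshold, "low_quality_threshold")
  assert_fraction(anchor_threshold, "anchor_threshold")
  structure(list(window_seconds = window_seconds,
                 low_quality_threshold = low_quality_threshold,
                 anchor_threshold = anchor_threshold,
                 selection = match.arg(selection)),
            class = "pairing_config")
}

#' Curriculum measure: artifact-level difference of a pair
#'
#' \code{C(y1, y2) = |y1 - y2|}: the size of the artifact difference between
#' two segments, used to order training pairs from easy (similar quality) to
#' hard (very different quality).
#'
#' @param y1,y2 Artifact fractions in [0, 1] (vectorized).
#' @return \code{|y1 - y2|}, in [0, 1].
#' @examples
#' curriculum_measure(0, 0.5)  # 0.5
#' @export
curriculum_measure <- function(y1, y2) {
  if (any(!is.finite(y1)) || any(!is.finite(y2)) ||
      any(y1 < 0 | y1 > 1) || any(y2 < 0 | y2 > 1))
    stopf("artifact fractions must be finite and in [0, 1]")
  abs(y1 - y2)
}

#' Find temporal-quality training pairs
#'
#' For every anchor segment (y at or below the anchor threshold), searches
#' same-patient candidates with |t_candidate - t_anchor| strictly less than
#' the window and y strictly above the low-quality threshold, and selects the
#' one with the greatest temporal distance from the anchor (ties broken by
#' the later timestamp, then the higher y, for determinism).  Each anchor
#' yields at most one pair; anchors with no candidate yield none; one
#' low-quality segment may serve several anchors.
#'
#' @param segments A \code{ppg_segments} collection or a data.frame with
#'   columns \code{segment_id}, \code{patient_id}, \code{t}, \code{y}.
#' @param config A \code{\link{pairing_config}}.
#' @return A data.frame of class \code{quality_pairs} with columns
#'   \code{good_id}, \code{bad_id}, \code{good_idx}, \code{bad_idx}
#'   (row/element indices into \code{segments}), \code{patient_id} and
#'   \code{c} (the curriculum measure).
#' @examples
#' grid <- simulate_hr_noise_grid(hrs = 60, segments_per_patient = 6, seed = 1)
#' find_pairs(grid)
#' @export
find_pairs <- function(segments, config = pairing_config()) {
  stopifnot(inherits(config, "pairing_config"))
  df <- if (is.data.frame(segments)) segments else as.data.frame(segments)
  req <- c("segment_id", "patient_id", "t", "y")
  miss <- setdiff(req, names(df))
  if (length(miss)) stopf("segments missing field(s): %s",
                          paste(miss, collapse = ", "))
  if (anyNA(df$t) || anyNA(df$y)) stopf("segments have missing t or y values")

  out <- list()
  k <- 0L
  for (pid in unique(df$patient_id)) {
    rows <- which(df$patient_id == pid)
    anchors <- rows[df$y[rows] <= config$anchor_threshold]
    lows <- rows[df$y[rows] > config$low_quality_threshold]
    if (!length(anchors) || !length(lows)) next
    for (a in anchors) {
      dt <- abs(df$t[lows] - df$t[a])
      cand <- lows[dt < config$window_seconds & lows != a]
      if (!length(cand)) next
      if (config$selection == "max_distance") {
        d <- abs(df$t[cand] - df$t[a])
        # ties: later t, then higher y
        ord <- order(-d, -df$t[cand], -df$y[cand])
      } else {
        ord <- order(-df$t[cand], -df$y[cand])
      }
      j <- cand[ord[1]]
      k <- k + 1L
      out[[k]] <- data.frame(good_id = df$segment_id[a],
                             bad_id = df$segment_id[j],
                             good_idx = a, bad_idx = j,
                             patient_id = pid,
                             c = curriculum_measure(df$y[a], df$y[j]),
                             stringsAsFactors = FALSE)
    }
  }
  pairs <- if (k) do.call(rbind, out) else
    data.frame(good_id = character(), bad_id = character(),
               good_idx = integer(), bad_idx = integer(),
               patient_id = character(), c = numeric(),
               stringsAsFactors = FALSE)
  class(pairs) <- c("quality_pairs", "data.frame")
  attr(pairs, "config") <- config
  pairs
}

#' Order training pairs by curriculum difficulty
#'
#' \code{strict_sort} stably sorts pairs by ascending curriculum measure c.
#' \code{staged_buckets} partitions pairs into \code{n_buckets} equal-width
#' c-bins over [0, 1], consumes the bins in ascending order, and shuffles
#' within each bin (reproducibly, by \code{seed}) -- a compromise that keeps
#' the easy-to-hard schedule while preserving within-stage stochasticity for
#' gradient training.  In both modes the sequence of bucket-level mean c is
#' non-decreasing.
#'
#' @param pairs A \code{quality_pairs} data.frame (non-empty).
#' @param mode \code{"strict_sort"} or \code{"staged_buckets"}.
#' @param n_buckets Number of equal-width c-bins for the staged mode (>= 1).
#' @param seed Integer seed for within-bin shuffling.
#' @return The reordered \code{quality_pairs} data.frame.
#' @export
curriculum_order <- function(pairs, mode = c("staged_buckets", "strict_sort"),
                             n_buckets = 5, seed = 1L) {
  mode <- match.arg(mode)
  if (!nrow(pairs)) stopf("`pairs` must be non-empty")
  if (!is.numeric(n_buckets) || n_buckets < 1)
    stopf("`n_buckets` must be >= 1")
  if (mode == "strict_sort") {
    ord <- order(pairs$c)  # stable in R
  } else {
    bin <- pmin(floor(pairs$c * n_buckets) + 1L, as.integer(n_buckets))
    ord <- withr::with_seed(as.integer(seed), {
      unlist(lapply(sort(unique(bin)), function(b) {
        idx <- which(bin == b)
        if (length(idx) > 1L) sample(idx) else idx
      }))
    })
  }
  out <- pairs[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @export
print.quality_pairs <- function(x, ...) {
  cat(sprintf("<quality_pairs> %d pairs from %d patient(s); c in [%.3f, %.3f]\n",
              nrow(x), length(unique(x$patient_id)),
              if (nrow(x)) min(x$c) else NA, if (nrow(x)) max(x$c) else NA))
  if (nrow(x)) print.data.frame(head(as.data.frame(x), 5))
  invisible(x)
}
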