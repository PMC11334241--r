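#' Beat template parameters for the PPG waveform generator
#'
#' The simulator models each cardiac cycle as the sum of two Gaussian bumps:
#' a systolic peak and a delayed diastolic (dicrotic) bump.  The waveform is
#' the superposition of one such template per beat, which makes its
#' periodicity analytically checkable: with zero heart-rate jitter the signal
#' is periodic with period 60/HR seconds and its dominant non-DC spectral
#' component sits at HR/60 Hz.
#'
#' @param systolic_amplitude Peak amplitude of the systolic bump (arbitrary
#'   units, > 0).
#' @param systolic_width Gaussian sigma of the systolic bump, seconds.
#' @param diastolic_amplitude Peak amplitude of the diastolic bump (> 0).
#' @param diastolic_offset Delay of the diastolic bump after the systolic
#'   peak, seconds; must be positive and shorter than one beat period at the
#'   lowest supported heart rate (30 bpm, i.e. 2 s).
#' @param diastolic_width Gaussian sigma of the diastolic bump, seconds.
#' @return An object of class \code{beat_template}.
#' @examples
#' tpl <- beat_template()
#' x <- simulate_clean_ppg(60, 10, 40, template = tpl)
#' @export
beat_template <- function(systolic_amplitude = 1,
                          systolic_width = 0.08,
                          diastolic_amplitude = 0.4,
                          diastolic_offset = 0.28,
                          diastolic_width = 0.12) {
  assert_scalar_num(systolic_amplitude, "systolic_amplitude")
  assert_scalar_num(systolic_width, "systolic_width")
  assert_scalar_num(diastolic_amplitude, "diastolic_amplitude")
  assert_scalar_num(diastolic_offset, "diastolic_offset")
  assert_scalar_num(diastolic_width, "diastolic_width")
  if (systolic_amplitude <= 0 || diastolic_amplitude <= 0)
    stopf("amplitudes must be positive")
  if (systolic_width <= 0 || diastolic_width <= 0)
    stopf("widths must be positive")
  if (diastolic_offset <= 0 || diastolic_offset >= 2)
    stopf("diastolic_offset must be in (0, 2) seconds")
  structure(list(systolic_amplitude = systolic_amplitude,
                 systolic_width = systolic_width,
                 diastolic_amplitude = diastolic_amplitude,
                 diastolic_offset = diastolic_offset,
                 diastolic_width = diastolic_width),
            class = "beat_template")
}

#' Noise specification for artifact injection
#'
#' Three noise families are modelled.  Baseline drift (0.05--0.5 Hz) and
#' powerline interference (a sinusoid at the mains frequency) are global
#' confounders applied to the whole recording; localized motion-artifact
#' bursts distort the amplitude over contiguous windows and are the only
#' component that sets the ground-truth artifact mask (the artifact fraction
#' y of a segment must be a window-localizable quantity for temporal-quality
#' pairing to be meaningful).  Each level maps linearly to component
#' amplitude relative to the clean signal's peak-to-peak range.
#'
#' @param drift_level Drift amplitude as a fraction of the clean peak-to-peak
#'   range, in [0, 1].
#' @param motion_level Motion-burst amplitude fraction, in [0, 1].  Together
#'   with \code{motion_window_fraction} it also determines the fraction of
#'   samples covered by bursts: approximately
#'   \code{motion_window_fraction * motion_level}.
#' @param powerline_level Powerline amplitude fraction, in [0, 1].
#' @param mains_hz Mains frequency, typically 50 or 60 Hz.
#' @param motion_window_fraction Scales the burst coverage, in [0, 1].
#' @return An object of class \code{noise_spec}.
#' @export
noise_spec <- function(drift_level = 0, motion_level = 0, powerline_level = 0,
                       mains_hz = 60, motion_window_fraction = 0.5) {
  assert_fraction(drift_level, "drift_level")
  assert_fraction(motion_level, "motion_level")
  assert_fraction(powerline_level, "powerline_level")
  assert_fraction(motion_window_fraction, "motion_window_fraction")
  assert_scalar_num(mains_hz, "mains_hz", 1, 1000)
  structure(list(drift_level = drift_level, motion_level = motion_level,
                 powerline_level = powerline_level, mains_hz = mains_hz,
                 motion_window_fraction = motion_window_fraction),
            class = "noise_spec")
}

#' Simulate a clean PPG waveform
#'
#' Generates \code{round(duration_s * fs)} samples of an artifact-free PPG
#' signal at a given heart rate.  Beats are placed at inter-beat intervals of
#' 60/\code{hr_bpm} seconds, optionally jittered beat-to-beat, and each beat
#' contributes a systolic plus diastolic Gaussian bump.
#'
#' @param hr_bpm Heart rate in beats/min, in [30, 220].
#' @param duration_s Duration in seconds (> 0).
#' @param fs Sampling frequency in Hz (>= 20).
#' @param template A \code{\link{beat_template}}.
#' @param hr_jitter Fractional standard deviation of the inter-beat interval
#'   (0 = exactly periodic).
#' @param seed Optional integer seed controlling the jitter; the output is
#'   deterministic given the seed.
#' @return Numeric vector of length \code{round(duration_s * fs)}.
#' @examples
#' x <- simulate_clean_ppg(60, 30, 40)
#' length(x)  # 1200
#' @export
simulate_clean_ppg <- function(hr_bpm, duration_s, fs,
                               template = beat_template(),
                               hr_jitter = 0, seed = NULL) {
  assert_scalar_num(hr_bpm, "hr_bpm", 30, 220)
  if (!is.numeric(duration_s) || length(duration_s) != 1L || duration_s <= 0)
    stopf("`duration_s` must be a positive number")
  if (!is.numeric(fs) || length(fs) != 1L || fs < 20)
    stopf("`fs` must be a number >= 20 Hz")
  assert_fraction(hr_jitter, "hr_jitter")
  stopifnot(inherits(template, "beat_template"))

  gen <- function() {
    n <- round(duration_s * fs)
    t <- (seq_len(n) - 1) / fs
    ibi <- 60 / hr_bpm
    # beat times covering [ -margin, duration + margin ] so edges are complete
    margin <- 3 * ibi
    n_beats <- ceiling((duration_s + 2 * margin) / ibi) + 1L
    if (hr_jitter > 0) {
      ivals <- ibi * (1 + hr_jitter * rnorm(n_beats))
      ivals <- pmax(ivals, 0.25 * ibi)
      beats <- cumsum(c(-margin, ivals[-1]))
    } else {
      beats <- -margin + ibi * (seq_len(n_beats) - 1)
    }
    x <- numeric(n)
    # each beat only contributes within +/- 6 sigma of its bumps; evaluating
    # the Gaussians on that slice keeps long recordings fast
    wmax <- max(template$systolic_width, template$diastolic_width)
    reach_lo <- 6 * wmax
    reach_hi <- template$diastolic_offset + 6 * wmax
    for (tb in beats) {
      i0 <- max(1L, ceiling((tb - reach_lo) * fs) + 1L)
      i1 <- min(n, floor((tb + reach_hi) * fs) + 1L)
      if (i0 > i1) next
      idx <- i0:i1
      ts <- t[idx]
      x[idx] <- x[idx] + template$systolic_amplitude *
        exp(-(ts - tb)^2 / (2 * template$systolic_width^2)) +
        template$diastolic_amplitude *
        exp(-(ts - tb - template$diastolic_offset)^2 /
              (2 * template$diastolic_width^2))
    }
    x
  }
  if (is.null(seed)) gen() else withr::with_seed(as.integer(seed), gen())
}

# add motion bursts covering exactly `target_n` samples; returns list(x, mask)
add_motion_bursts <- function(x, fs, level, target_n) {
  n <- length(x)
  rng <- diff(range(x))
  if (rng == 0) rng <- 1
  mask <- logical(n)
  covered <- 0L
  attempts <- 0L
  while (covered < target_n && attempts < 10000L) {
    attempts <- attempts + 1L
    len <- min(round(runif(1, 0.5, 3) * fs), target_n - covered)
    if (len < 1L) len <- 1L
    start <- sample.int(n - len + 1L, 1L)
    idx <- seq(start, length.out = len)
    if (any(mask[idx])) next
    mask[idx] <- TRUE
    covered <- covered + len
    # band-limited amplitude distortion: smoothed white noise, unit sd
    w <- rnorm(len)
    if (len >= 5L) w <- as.numeric(stats::filter(w, rep(1 / 5, 5), sides = 2))
    w[is.na(w)] <- 0
    s <- sd(w)
    if (is.na(s) || s == 0) s <- 1
    x[idx] <- x[idx] + level * rng * w / s
  }
  list(x = x, mask = mask)
}

#' Inject labelled noise into a clean PPG signal
#'
#' Applies the three noise families of a \code{\link{noise_spec}}.  Drift and
#' powerline are global additive components and do not set the artifact mask;
#' motion bursts are localized and define the mask (and hence the
#' ground-truth artifact fraction y of any segment cut from the recording).
#' With all levels zero the input is returned bit-exactly with an all-false
#' mask.
#'
#' @param clean Numeric vector, the clean signal.
#' @param fs Sampling frequency in Hz.
#' @param spec A \code{\link{noise_spec}}.
#' @param seed Integer seed; output is deterministic given the seed.
#' @param patient_id Identifier stored on the returned recording.
#' @param start_time Recording start time in seconds.
#' @return A \code{ppg_recording}: list with \code{samples}, \code{fs},
#'   \code{start_time}, \code{artifact_mask}, \code{patient_id}, \code{meta}.
#' @export
inject_noise <- function(clean, fs, spec, seed = 1L,
                         patient_id = "sim", start_time = 0) {
  if (!length(clean)) stopf("`clean` must be non-empty")
  if (!is.numeric(fs) || fs <= 0) stopf("`fs` must be positive")
  stopifnot(inherits(spec, "noise_spec"))

  n <- length(clean)
  if (spec$drift_level == 0 && spec$motion_level == 0 &&
      spec$powerline_level == 0) {
    return(new_ppg_recording(clean, fs, start_time, logical(n),
                             patient_id, list(noise = spec)))
  }
  res <- withr::with_seed(as.integer(seed), {
    x <- clean
    rng <- diff(range(clean))
    if (rng == 0) rng <- 1
    t <- (seq_len(n) - 1) / fs
    if (spec$drift_level > 0) {
      # sum of three sinusoids with random frequencies in the drift band
      f <- runif(3, 0.05, 0.5)
      ph <- runif(3, 0, 2 * pi)
      d <- sin(2 * pi * f[1] * t + ph[1]) + sin(2 * pi * f[2] * t + ph[2]) +
        sin(2 * pi * f[3] * t + ph[3])
      x <- x + spec$drift_level * rng * d / max(abs(d))
    }
    if (spec$powerline_level > 0) {
      x <- x + spec$powerline_level * rng *
        sin(2 * pi * spec$mains_hz * t + runif(1, 0, 2 * pi))
    }
    mask <- logical(n)
    if (spec$motion_level > 0 && spec$motion_window_fraction > 0) {
      target_n <- round(spec$motion_window_fraction * spec$motion_level * n)
      if (target_n > 0) {
        mb <- add_motion_bursts(x, fs, spec$motion_level, target_n)
        x <- mb$x
        mask <- mb$mask
      }
    }
    list(x = x, mask = mask)
  })
  new_ppg_recording(res$x, fs, start_time, res$mask, patient_id,
                    list(noise = spec))
}

new_ppg_recording <- function(samples, fs, start_time, artifact_mask,
                              patient_id, meta = list()) {
  stopifnot(length(samples) == length(artifact_mask))
  structure(list(samples = as.numeric(samples), fs = fs,
                 start_time = start_time,
                 artifact_mask = as.logical(artifact_mask),
                 patient_id = as.character(patient_id), meta = meta),
            class = "ppg_recording")
}

#' @export
print.ppg_recording <- function(x, ...) {
  cat(sprintf("<ppg_recording> patient %s: %d samples @ %g Hz (%.1f s), %.1f%% artifact\n",
              x$patient_id, length(x$samples), x$fs,
              length(x$samples) / x$fs, 100 * mean(x$artifact_mask)))
  invisible(x)
}

#' Artifact schedule for the corpus simulator
#'
#' Controls how motion-artifact bursts are interleaved with clean stretches
#' in \code{\link{make_corpus}}.
#'
#' @param bursts_per_10min Expected number of bursts per 10 minutes of
#'   recording; 0 disables artifacts entirely.
#' @param min_s,max_s Burst duration range in seconds.
#' @param level_range Range of motion-burst amplitude levels drawn per burst.
#' @param drift_level,powerline_level Global confounder levels applied to the
#'   whole recording.
#' @return A list with class \code{artifact_schedule}.
#' @export
artifact_schedule <- function(bursts_per_10min = 8, min_s = 3, max_s = 12,
                              level_range = c(0.4, 0.9),
                              drift_level = 0.1, powerline_level = 0) {
  structure(list(bursts_per_10min = bursts_per_10min, min_s = min_s,
                 max_s = max_s, level_range = level_range,
                 drift_level = drift_level,
                 powerline_level = powerline_level),
            class = "artifact_schedule")
}

#' Simulate a corpus of continuous PPG recordings with ground truth
#'
#' One continuous recording per synthetic patient, each with a constant
#' (jittered) heart rate drawn from \code{hr_range}, interleaving clean
#' stretches with motion-artifact bursts placed by the
#' \code{\link{artifact_schedule}}.  When the schedule is non-empty the first
#' 30 s window of every patient is kept burst-free (a clean anchor) and at
#' least one burst covering more than 20\% of a 30 s window is forced within
#' the first 5 minutes, so every patient admits at least one
#' (anchor, low-quality neighbour) training pair.
#'
#' @param n_patients Number of synthetic patients (>= 1).
#' @param recording_minutes Length of each recording in minutes (>= 1).
#' @param fs Sampling frequency in Hz (default 240, typical of bedside
#'   monitor waveforms).
#' @param hr_range Heart-rate interval in beats/min to draw from.
#' @param schedule An \code{\link{artifact_schedule}}.
#' @param hr_jitter Beat-to-beat heart rate jitter fraction.
#' @param seed Integer seed; corpora are reproducible given the seed.
#' @return List of \code{ppg_recording} objects; each carries its generator
#'   heart rate in \code{meta$hr_bpm}.
#' @examples
#' corpus <- make_corpus(2, 10, fs = 240, seed = 7)
#' length(corpus[[1]]$samples)  # 144000
#' @export
make_corpus <- function(n_patients, recording_minutes, fs = 240,
                        hr_range = c(50, 130),
                        schedule = artifact_schedule(),
                        hr_jitter = 0.02, seed = 1L) {
  if (!is.numeric(n_patients) || n_patients < 1) stopf("`n_patients` must be >= 1")
  if (!is.numeric(recording_minutes) || recording_minutes < 1)
    stopf("`recording_minutes` must be >= 1")
  if (!length(hr_range) || any(!is.finite(hr_range)))
    stopf("`hr_range` must be a non-empty numeric interval")
  hr_range <- range(hr_range)
  stopifnot(inherits(schedule, "artifact_schedule"))

  duration_s <- recording_minutes * 60
  n <- round(duration_s * fs)
  lapply(seq_len(n_patients), function(p) {
    pseed <- derive_seed(seed, p)
    withr::with_seed(pseed, {
      hr <- runif(1, hr_range[1], hr_range[2])
      x <- simulate_clean_ppg(hr, duration_s, fs, hr_jitter = hr_jitter,
                              seed = derive_seed(pseed, 1L))
      rng <- diff(range(x))
      t <- (seq_len(n) - 1) / fs
      if (schedule$drift_level > 0) {
        f <- runif(3, 0.05, 0.5); ph <- runif(3, 0, 2 * pi)
        d <- sin(2 * pi * f[1] * t + ph[1]) + sin(2 * pi * f[2] * t + ph[2]) +
          sin(2 * pi * f[3] * t + ph[3])
        x <- x + schedule$drift_level * rng * d / max(abs(d))
      }
      if (schedule$powerline_level > 0 && fs > 100) {
        x <- x + schedule$powerline_level * rng *
          sin(2 * pi * 60 * t + runif(1, 0, 2 * pi))
      }
      mask <- logical(n)
      n_bursts <- round(schedule$bursts_per_10min * recording_minutes / 10)
      if (schedule$bursts_per_10min > 0 && n_bursts < 1) n_bursts <- 1L
      if (n_bursts > 0) {
        # forced burst: > 20% of one 30 s window, inside the first 5 minutes
        forced_len <- round(runif(1, 8, 12) * fs)
        forced_start <- round(runif(1, 35, min(240, duration_s - 15)) * fs) + 1L
        starts <- forced_start
        lens <- forced_len
        for (b in seq_len(max(0L, n_bursts - 1L))) {
          len <- round(runif(1, schedule$min_s, schedule$max_s) * fs)
          # keep the first 30 s burst-free so an anchor always exists
          st <- round(runif(1, 31, duration_s - schedule$max_s - 1) * fs) + 1L
          starts <- c(starts, st)
          lens <- c(lens, len)
        }
        for (b in seq_along(starts)) {
          idx <- seq(starts[b], length.out = min(lens[b], n - starts[b] + 1L))
          lvl <- runif(1, schedule$level_range[1], schedule$level_range[2])
          w <- rnorm(length(idx))
          if (length(idx) >= 5L)
            w <- as.numeric(stats::filter(w, rep(1 / 5, 5), sides = 2))
          w[is.na(w)] <- 0
          s <- sd(w); if (is.na(s) || s == 0) s <- 1
          x[idx] <- x[idx] + lvl * rng * w / s
          mask[idx] <- TRUE
        }
      }
      new_ppg_recording(x, fs, 0, mask, sprintf("P%03d", p),
                        list(hr_bpm = hr, schedule = schedule))
    })
  })
}

#' Simulate a grid of labelled 30 s segments over heart rates and noise levels
#'
#' Builds, for each heart rate, one synthetic patient whose timeline
#' alternates clean segments with noisy segments at the requested levels
#' (motion, drift and powerline all set to the level; the motion window
#' fraction is 1 so the ground-truth artifact fraction approximately equals
#' the level).  Segments are simulated directly at the target sampling rate,
#' min-max normalized, and returned as a \code{ppg_segments} collection ready
#' for pairing -- the layout used to probe representation robustness across
#' noise at fixed physiology.
#'
#' @param hrs Heart rates in beats/min, one synthetic patient each.
#' @param noise_levels Noise levels; the first is usually 0 (clean).
#'   Non-zero levels are cycled over the noisy positions of the timeline.
#' @param segments_per_patient Number of 30 s segments per patient (clean and
#'   noisy alternate).
#' @param fs Sampling rate of the segments, Hz.
#' @param segment_seconds Segment length, seconds.
#' @param hr_jitter Beat-to-beat jitter fraction.
#' @param seed Integer seed.
#' @return A \code{ppg_segments} collection; each segment's \code{meta}
#'   carries \code{hr_bpm} and \code{noise_level}.
#' @export
simulate_hr_noise_grid <- function(hrs = c(60, 90, 120),
                                   noise_levels = c(0, 0.3, 0.7),
                                   segments_per_patient = 20,
                                   fs = 40, segment_seconds = 30,
                                   hr_jitter = 0.02, seed = 1L) {
  noisy_levels <- setdiff(noise_levels, 0)
  segs <- list()
  k <- 0L
  for (pi in seq_along(hrs)) {
    hr <- hrs[pi]
    pid <- sprintf("HR%03d", round(hr))
    for (si in seq_len(segments_per_patient)) {
      k <- k + 1L
      sseed <- derive_seed(seed, k)
      lvl <- if (si %% 2 == 1 || !length(noisy_levels)) 0 else
        noisy_levels[((si %/% 2 - 1L) %% length(noisy_levels)) + 1L]
      clean <- simulate_clean_ppg(hr, segment_seconds, fs,
                                  hr_jitter = hr_jitter, seed = sseed)
      if (lvl > 0) {
        rec <- inject_noise(clean, fs,
                            noise_spec(drift_level = lvl, motion_level = lvl,
                                       powerline_level = if (fs > 100) lvl else 0,
                                       motion_window_fraction = 1),
                            seed = derive_seed(sseed, 2L), patient_id = pid)
        x <- rec$samples
        y <- mean(rec$artifact_mask)
      } else {
        x <- clean
        y <- 0
      }
      segs[[k]] <- new_ppg_segment(minmax_normalize(x), y,
                                   t = (si - 1) * segment_seconds,
                                   patient_id = pid,
                                   segment_id = sprintf("%s_%04d", pid, si),
                                   fs = fs,
                                   meta = list(hr_bpm = hr, noise_level = lvl))
    }
  }
  new_ppg_segments(segs)
}
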