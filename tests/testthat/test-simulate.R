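test_that("clean waveform has the requested length and heart-rate fundamental", {
  x <- simulate_clean_ppg(60, 30, 40)
  expect_length(x, 1200)
  spec <- Mod(fft(x - mean(x)))[2:600]
  freqs <- (1:599) * 40 / 1200
  expect_lt(abs(freqs[which.max(spec)] - 1.0), 0.1)

  # arbitrary durations round to the nearest sample count
  expect_length(simulate_clean_ppg(80, 12.34, 37), round(12.34 * 37))
})

test_that("zero-jitter waveform is periodic with period 60/HR", {
  x <- simulate_clean_ppg(120, 10, 40, hr_jitter = 0)
  a <- acf(x, lag.max = 40, plot = FALSE)$acf[-1]
  expect_equal(which.max(a), 20)
})

test_that("waveform generation is deterministic given a seed and rejects bad input", {
  expect_identical(simulate_clean_ppg(70, 10, 40, hr_jitter = 0.05, seed = 9),
                   simulate_clean_ppg(70, 10, 40, hr_jitter = 0.05, seed = 9))
  expect_error(simulate_clean_ppg(70, -1, 40), "duration")
  expect_error(simulate_clean_ppg(70, 10, 5), "fs")
  expect_error(simulate_clean_ppg(300, 10, 40), "hr_bpm")
})

test_that("zero-noise injection is the bit-exact identity with an empty mask", {
  clean <- simulate_clean_ppg(60, 10, 40)
  rec <- inject_noise(clean, 40, noise_spec(), seed = 1)
  expect_identical(rec$samples, clean)
  expect_false(any(rec$artifact_mask))
})

test_that("motion bursts cover the prescribed sample fraction", {
  fr <- vapply(1:20, function(s) {
    rec <- inject_noise(simulate_clean_ppg(70, 30, 40), 40,
                        noise_spec(motion_level = 0.5,
                                   motion_window_fraction = 0.5),
                        seed = s)
    mean(rec$artifact_mask)
  }, 0)
  expect_lt(abs(mean(fr) - 0.25), 0.05)
})

test_that("only motion bursts set the artifact mask; drift and powerline do not", {
  clean <- simulate_clean_ppg(60, 10, 240)
  rec <- inject_noise(clean, 240,
                      noise_spec(drift_level = 0.5, powerline_level = 0.3),
                      seed = 4)
  expect_false(any(rec$artifact_mask))
  expect_false(identical(rec$samples, clean))
})

test_that("powerline injection adds a mains-frequency spectral peak", {
  clean <- simulate_clean_ppg(60, 10, 240)
  rec <- inject_noise(clean, 240,
                      noise_spec(powerline_level = 0.3, mains_hz = 50),
                      seed = 2)
  added <- rec$samples - clean
  n <- length(added)
  spec <- Mod(fft(added - mean(added)))[seq_len(n %/% 2)]
  freqs <- (seq_len(n %/% 2) - 1) * 240 / n
  expect_lt(abs(freqs[which.max(spec)] - 50), 0.5)
})

test_that("noise levels outside [0,1] are rejected", {
  expect_error(noise_spec(drift_level = 1.2), "drift_level")
  expect_error(noise_spec(motion_level = -0.1), "motion_level")
})

test_that("corpus has the requested shape and seeded reproducibility", {
  corpus <- make_corpus(2, 10, fs = 240, seed = 7)
  expect_length(corpus, 2)
  expect_length(corpus[[1]]$samples, 144000)

  segs1 <- preprocess_corpus(make_corpus(2, 6, fs = 40, seed = 3))
  segs2 <- preprocess_corpus(make_corpus(2, 6, fs = 40, seed = 3))
  expect_identical(vapply(segs1, `[[`, 0, "y"), vapply(segs2, `[[`, 0, "y"))
  segs3 <- preprocess_corpus(make_corpus(2, 6, fs = 40, seed = 4))
  expect_false(identical(vapply(segs1, `[[`, 0, "y"),
                         vapply(segs3, `[[`, 0, "y")))
  expect_error(make_corpus(2, 10, hr_range = numeric()), "hr_range")
})

test_that("a burst-free schedule yields all-clean segments", {
  corpus <- make_corpus(1, 5, fs = 40,
                        schedule = artifact_schedule(bursts_per_10min = 0,
                                                     drift_level = 0),
                        seed = 1)
  segs <- preprocess_recording(corpus[[1]])
  expect_true(all(vapply(segs, `[[`, 0, "y") == 0))
})

test_that("every patient with artifacts admits at least one anchor/low-quality pair", {
  corpus <- make_corpus(4, 6, fs = 40, seed = 21)
  for (rec in corpus) {
    segs <- preprocess_recording(rec)
    expect_gte(nrow(find_pairs(segs)), 1)
  }
})

test_that("ground-truth y equals the flagged fraction of the segment mask", {
  rec <- make_corpus(1, 6, fs = 40, seed = 13)[[1]]
  raw <- segment_recording(rec, 30)
  ys <- label_segments(raw, rec)
  for (k in seq_along(raw))
    expect_identical(ys[k], mean(raw[[k]]$mask))
  expect_true(all(ys >= 0 & ys <= 1))
})

test_that("hr-noise grid labels segments with approximately the noise level", {
  grid <- simulate_hr_noise_grid(hrs = c(60, 90), noise_levels = c(0, 0.4),
                                 segments_per_patient = 8, seed = 2)
  df <- as.data.frame(grid)
  lvl <- vapply(grid, function(s) s$meta$noise_level, 0)
  expect_true(all(df$y[lvl == 0] == 0))
  expect_true(all(abs(df$y[lvl == 0.4] - 0.4) < 0.05))
})
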