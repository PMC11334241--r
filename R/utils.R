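# internal helpers

stopf <- function(...) stop(sprintf(...), call. = FALSE)

assert_scalar_num <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stopf("`%s` must be a single finite number", name)
  if (x < lower || x > upper)
    stopf("`%s` must be in [%s, %s], got %s", name, lower, upper, x)
  invisible(x)
}

assert_fraction <- function(x, name) assert_scalar_num(x, name, 0, 1)

# Derive a child seed from a base seed and a stream index, staying well below
# .Machine$integer.max so downstream arithmetic on seeds is safe.
derive_seed <- function(seed, stream) {
  (as.integer(seed) %% 1000003L) * 1009L + as.integer(stream) %% 1009L
}

# dominant non-DC frequency of a real signal, in Hz
dominant_frequency <- function(x, fs) {
  n <- length(x)
  spec <- Mod(fft(x - mean(x)))[seq_len(n %/% 2)]
  spec[1] <- 0  # guard residual DC
  freqs <- (seq_len(n %/% 2) - 1) * fs / n
  freqs[which.max(spec)]
}

# run-length encode a logical mask into a list of (start, length) runs of TRUE
mask_to_runs <- function(mask) {
  r <- rle(as.logical(mask))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start = starts[keep], length = r$lengths[keep])
}

runs_to_mask <- function(runs, n) {
  mask <- logical(n)
  if (length(runs$start))
    for (i in seq_along(runs$start))
      mask[seq(runs$start[i], length.out = runs$length[i])] <- TRUE
  mask
}
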