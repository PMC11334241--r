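# Independent oracles and fixture builders shared across tests.
# Oracles are deliberately naive (double loops, direct formulas) and never
# call the implementation paths they check.

# brute-force pair enumerator: all anchors x all candidates, same rule
brute_force_pairs <- function(df, window_seconds = 300,
                              low_quality_threshold = 0.2,
                              anchor_threshold = 0) {
  out <- list()
  k <- 0L
  for (a in seq_len(nrow(df))) {
    if (df$y[a] > anchor_threshold) next
    best <- NULL
    for (j in seq_len(nrow(df))) {
      if (j == a) next
      if (df$patient_id[j] != df$patient_id[a]) next
      if (df$y[j] <= low_quality_threshold) next
      dt <- abs(df$t[j] - df$t[a])
      if (dt >= window_seconds) next
      if (is.null(best)) { best <- j; next }
      bdt <- abs(df$t[best] - df$t[a])
      if (dt > bdt ||
          (dt == bdt && (df$t[j] > df$t[best] ||
                         (df$t[j] == df$t[best] && df$y[j] > df$y[best]))))
        best <- j
    }
    if (!is.null(best)) {
      k <- k + 1L
      out[[k]] <- data.frame(good_id = df$segment_id[a],
                             bad_id = df$segment_id[best],
                             c = abs(df$y[best] - df$y[a]),
                             stringsAsFactors = FALSE)
    }
  }
  if (k) do.call(rbind, out)
  else data.frame(good_id = character(), bad_id = character(), c = numeric())
}

# random toy segment table (metadata only) for pairing tests
random_segment_table <- function(n, n_patients = 2) {
  data.frame(segment_id = sprintf("S%03d", seq_len(n)),
             patient_id = sample(sprintf("P%d", seq_len(n_patients)), n,
                                 replace = TRUE),
             t = round(runif(n, 0, 900), 1),
             y = round(runif(n)^2, 3),  # skew toward clean
             stringsAsFactors = FALSE)
}

mae_oracle <- function(a, b) {
  s <- 0
  for (i in seq_along(a)) s <- s + abs(a[i] - b[i])
  s / length(a)
}

f1_oracle <- function(tp, fp, fn) {
  if (tp == 0) return(if (fp == 0 && fn == 0) 1 else 0)
  p <- tp / (tp + fp)
  r <- tp / (tp + fn)
  2 * p * r / (p + r)
}

# brute-force filter-and-score AT-curve
at_curve_oracle <- function(quality, y_true, y_pred, metric, thresholds) {
  res <- data.frame(threshold = numeric(), n = integer(), metric = numeric())
  for (u in thresholds) {
    keep <- quality <= u
    m <- if (!any(keep)) NA_real_
    else if (metric == "mae") mae_oracle(y_true[keep], y_pred[keep])
    else {
      tp <- sum(y_true[keep] == 1 & y_pred[keep] == 1)
      fp <- sum(y_true[keep] == 0 & y_pred[keep] == 1)
      fn <- sum(y_true[keep] == 1 & y_pred[keep] == 0)
      f1_oracle(tp, fp, fn)
    }
    res <- rbind(res, data.frame(threshold = u, n = sum(keep), metric = m))
  }
  res
}

# double-loop within/between group cosine gap
gap_oracle <- function(emb, group) {
  cosv <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  w <- c(); b <- c()
  for (i in seq_len(nrow(emb) - 1)) for (j in (i + 1):nrow(emb)) {
    v <- cosv(emb[i, ], emb[j, ])
    if (group[i] == group[j]) w <- c(w, v) else b <- c(b, v)
  }
  mean(w) - mean(b)
}

# small segment collection for model tests (short input for speed)
tiny_test_config <- function(input_length = 200)
  model_config(encoder_variant = "tiny_1d", input_length = input_length,
               feature_dim = 16, projection_dim = 8, projector_hidden = 12,
               predictor_hidden = 4)

random_input <- function(input_length, n, seed = 1) {
  withr::with_seed(seed, matrix(runif(input_length * n), input_length, n))
}
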