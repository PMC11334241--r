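test_that("the worked anchor/candidate example picks the most distant candidate", {
  df <- data.frame(segment_id = c("a", "c1", "c2", "c3"),
                   patient_id = "P1",
                   t = c(0, 60, 120, 280),
                   y = c(0, 0.1, 0.3, 0.5))
  pairs <- find_pairs(df)
  expect_identical(nrow(pairs), 1L)
  expect_identical(pairs$bad_id, "c3")
  expect_identical(pairs$c, 0.5)
})

test_that("anchors without an eligible candidate yield no pair", {
  df <- data.frame(segment_id = c("a", "c1"), patient_id = "P1",
                   t = c(0, 100), y = c(0, 0.15))
  expect_identical(nrow(find_pairs(df)), 0L)
  # candidate outside the 5-minute window
  df2 <- data.frame(segment_id = c("a", "c1"), patient_id = "P1",
                    t = c(0, 301), y = c(0, 0.9))
  expect_identical(nrow(find_pairs(df2)), 0L)
  # cross-patient candidates never pair
  df3 <- data.frame(segment_id = c("a", "c1"), patient_id = c("P1", "P2"),
                    t = c(0, 100), y = c(0, 0.9))
  expect_identical(nrow(find_pairs(df3)), 0L)
})

test_that("find_pairs matches the brute-force enumerator on random toys", {
  withr::with_seed(7, {
    for (i in 1:100) {
      df <- random_segment_table(sample(5:50, 1))
      got <- find_pairs(df); got <- got[order(got$good_id), ]
      want <- brute_force_pairs(df); want <- want[order(want$good_id), ]
      expect_identical(got$good_id, want$good_id)
      expect_identical(got$bad_id, want$bad_id)
      expect_equal(got$c, want$c)
    }
  })
})

test_that("every emitted pair satisfies the pairing invariants", {
  withr::with_seed(12, {
    for (i in 1:20) {
      df <- random_segment_table(40)
      pairs <- find_pairs(df)
      if (!nrow(pairs)) next
      gi <- match(pairs$good_id, df$segment_id)
      bi <- match(pairs$bad_id, df$segment_id)
      expect_true(all(df$patient_id[gi] == df$patient_id[bi]))
      expect_true(all(abs(df$t[bi] - df$t[gi]) < 300))
      expect_true(all(df$y[gi] <= 0))
      expect_true(all(df$y[bi] > 0.2))
      expect_equal(pairs$c, abs(df$y[bi] - df$y[gi]))
      # pair count bounded by anchor count; no pairs without low-quality
      expect_lte(nrow(pairs), sum(df$y <= 0))
      clean_only <- df[df$y <= 0.2, , drop = FALSE]
      expect_identical(nrow(find_pairs(clean_only)), 0L)
    }
  })
})

test_that("the literal max-index selection differs from max-distance when intended", {
  df <- data.frame(segment_id = c("a", "before", "after"), patient_id = "P",
                   t = c(100, 0, 150), y = c(0, 0.9, 0.9))
  d <- find_pairs(df, pairing_config(selection = "max_distance"))
  i <- find_pairs(df, pairing_config(selection = "max_index"))
  expect_identical(d$bad_id, "before")  # |dt| = 100 > 50
  expect_identical(i$bad_id, "after")   # larger timestamp
})

test_that("curriculum measure is the symmetric absolute difference", {
  expect_identical(curriculum_measure(0, 0.5), 0.5)
  expect_identical(curriculum_measure(0.3, 0.3), 0)
  withr::with_seed(3, {
    a <- runif(50); b <- runif(50)
    expect_identical(curriculum_measure(a, b), curriculum_measure(b, a))
    expect_true(all(curriculum_measure(a, b) >= 0 &
                      curriculum_measure(a, b) <= 1))
  })
  expect_error(curriculum_measure(-0.1, 0.5), "\\[0, 1\\]")
})

test_that("strict sorting is stable and ascending in c", {
  p <- data.frame(good_id = letters[1:3], bad_id = LETTERS[1:3],
                  good_idx = 1:3, bad_idx = 1:3, patient_id = "P",
                  c = c(0.4, 0.1, 0.9))
  class(p) <- c("quality_pairs", "data.frame")
  expect_identical(curriculum_order(p, "strict_sort")$c, c(0.1, 0.4, 0.9))
  sorted <- curriculum_order(p, "strict_sort")
  expect_identical(curriculum_order(sorted, "strict_sort"), sorted)
})

test_that("staged buckets separate non-adjacent difficulty levels reproducibly", {
  withr::with_seed(5, {
    for (i in 1:20) {
      n <- sample(20:80, 1)
      p <- data.frame(good_id = as.character(1:n), bad_id = as.character(1:n),
                      good_idx = 1:n, bad_idx = 1:n, patient_id = "P",
                      c = runif(n))
      class(p) <- c("quality_pairs", "data.frame")
      o1 <- curriculum_order(p, "staged_buckets", n_buckets = 5, seed = i)
      o2 <- curriculum_order(p, "staged_buckets", n_buckets = 5, seed = i)
      expect_identical(o1, o2)
      bin <- pmin(floor(o1$c * 5) + 1, 5)
      expect_true(!is.unsorted(bin))
      # bucket k fully precedes bucket k+2
      for (b in sort(unique(bin))) {
        later <- which(bin >= b + 2)
        if (length(later))
          expect_true(max(which(bin == b)) < min(later))
      }
      # bucket-level mean c non-decreasing
      means <- tapply(o1$c, bin, mean)
      expect_true(!is.unsorted(as.numeric(means)))
    }
  })
  p1 <- data.frame(good_id = "a", bad_id = "b", good_idx = 1L, bad_idx = 2L,
                   patient_id = "P", c = 0.3)
  class(p1) <- c("quality_pairs", "data.frame")
  expect_error(curriculum_order(p1, "staged_buckets", n_buckets = 0),
               "n_buckets")
  expect_error(curriculum_order(p1[0, ], "strict_sort"), "non-empty")
})
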