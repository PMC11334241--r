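test_that("mae matches hand values, symmetry and the independent oracle", {
  expect_identical(mae(c(1, 2), c(1, 2)), 0)
  expect_identical(mae(c(70, 80), c(72, 77)), 2.5)
  withr::with_seed(2, {
    for (i in 1:200) {
      a <- rnorm(sample(1:20, 1)); b <- rnorm(length(a))
      expect_equal(mae(a, b), mae_oracle(a, b), tolerance = 1e-12)
      expect_identical(mae(a, b), mae(b, a))
      expect_gte(mae(a, b), 0)
    }
  })
  expect_error(mae(1:3, 1:2), "length")
  expect_error(mae(numeric(), numeric()), "non-empty")
})

test_that("f1 matches hand values, the zero-rule and the independent oracle", {
  expect_identical(f1_score(5, 0, 0)$f1, 1)
  r <- f1_score(2, 1, 1)
  expect_equal(r$precision, 2 / 3)
  expect_equal(r$recall, 2 / 3)
  expect_equal(r$f1, 2 / 3)
  expect_identical(f1_score(0, 3, 2)$f1, 0)
  withr::with_seed(4, {
    for (i in 1:200) {
      tp <- sample(0:20, 1); fp <- sample(0:20, 1); fn <- sample(0:20, 1)
      f <- f1_score(tp, fp, fn)$f1
      expect_equal(f, f1_oracle(tp, fp, fn), tolerance = 1e-12)
      expect_true(f >= 0 && f <= 1)
      if (f == 1) expect_true(fp == 0 && fn == 0)
      if (fp == 0 && fn == 0 && tp > 0) expect_identical(f, 1)
    }
  })
  expect_error(f1_score(-1, 0, 0), "non-negative")
})

test_that("the hand-worked AT-curve example reproduces exactly", {
  curve <- at_curve(c(0.1, 0.5, 0.9), c(0, 0, 0), c(1, 2, 3), "mae",
                    c(0.2, 1.0))
  expect_identical(curve$n, c(1L, 3L))
  expect_identical(curve$metric, c(1, 2))
})

test_that("AT-curve equals the filter-and-score oracle and keeps its invariants", {
  withr::with_seed(6, {
    for (i in 1:100) {
      n <- sample(3:60, 1)
      q <- runif(n)
      metric <- sample(c("mae", "f1"), 1)
      if (metric == "mae") {
        yt <- rnorm(n); yp <- rnorm(n)
      } else {
        yt <- sample(0:1, n, replace = TRUE)
        yp <- sample(0:1, n, replace = TRUE)
      }
      th <- sort(runif(sample(2:8, 1)))
      th[length(th)] <- 1
      got <- at_curve(q, yt, yp, metric, th)
      want <- at_curve_oracle(q, yt, yp, metric, th)
      expect_equal(got$n, want$n)
      expect_equal(got$metric, want$metric, tolerance = 1e-12)
      expect_true(!is.unsorted(got$n))
      expect_identical(got$n[nrow(got)], n)
      overall <- if (metric == "mae") mae(yt, yp) else {
        cc <- list(tp = sum(yt == 1 & yp == 1), fp = sum(yt == 0 & yp == 1),
                   fn = sum(yt == 1 & yp == 0))
        f1_score(cc$tp, cc$fp, cc$fn)$f1
      }
      expect_equal(got$metric[nrow(got)], overall, tolerance = 1e-12)
    }
  })
})

test_that("degenerate quality distributions give a constant AT-curve", {
  curve <- at_curve(rep(0, 4), c(1, 2, 3, 4), c(2, 3, 4, 5), "mae")
  expect_true(all(curve$n == 4))
  expect_true(all(curve$metric == 1))
  expect_error(at_curve(c(0.1, 0.2), 1, 1, "mae"), "aligned")
  expect_error(at_curve(0.5, 1, 1, "mae", c(0.9, 0.1)), "ascending")
})

test_that("latent diagnostics recover ideal clustering and match the gap oracle", {
  e <- diag(3)
  emb <- rbind(e[1, ], e[1, ], e[2, ], e[2, ], e[3, ], e[3, ])
  ld <- latent_diagnostics(emb, rep(c("a", "b", "c"), each = 2))
  expect_equal(ld$gap, 1)
  expect_equal(ld$silhouette, 1)

  same <- matrix(rep(c(1, 1, 0), 4), 4, 3, byrow = TRUE)
  ld0 <- latent_diagnostics(same, c("a", "a", "b", "b"))
  expect_equal(ld0$gap, 0)

  withr::with_seed(8, {
    for (i in 1:20) {
      n <- sample(4:12, 1)
      emb <- matrix(rnorm(n * 5), n, 5)
      g <- sample(c("x", "y"), n, replace = TRUE)
      if (length(unique(g)) < 2) next
      ld <- latent_diagnostics(emb, g)
      expect_equal(ld$gap, gap_oracle(emb, g), tolerance = 1e-12)
    }
  })
  expect_error(latent_diagnostics(diag(2), c("a", "a")), "two distinct")
})

test_that("noise annotations restrict within-group pairs to across-noise ones", {
  emb <- rbind(c(1, 0), c(1, 0), c(0, 1))
  # group a: two members with the same noise level; fallback uses all pairs
  ld_same <- latent_diagnostics(emb, c("a", "a", "b"), noise_level = c(1, 1, 2))
  expect_equal(ld_same$within, 1)
  # distinct noise levels: the single across-noise pair defines within
  ld_across <- latent_diagnostics(emb, c("a", "a", "b"), noise_level = c(1, 2, 1))
  expect_equal(ld_across$within, 1)
})
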