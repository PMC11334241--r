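make_small_grid <- function(seed = 11, spp = 60)
  simulate_hr_noise_grid(hrs = c(60, 100), noise_levels = c(0, 0.5),
                         segments_per_patient = spp, seed = seed)

test_that("pretraining decreases the mean epoch loss on synthetic pairs", {
  grid <- make_small_grid()
  pairs <- find_pairs(grid)
  fit <- pretrain(grid, pairs, siam_model(model_config(), seed = 11),
                  pretrain_config(epochs = 4, seed = 11))
  expect_lt(tail(fit$trace$epoch_loss, 1), fit$trace$epoch_loss[1])
  expect_true(all(is.finite(fit$trace$steps$loss)))
  expect_true(all(abs(fit$trace$steps$loss) <= 2 + 1e-9))
})

test_that("identical seeds reproduce the training trace bit-for-bit", {
  grid <- make_small_grid(spp = 20)
  pairs <- find_pairs(grid)
  cfg <- pretrain_config(epochs = 2, seed = 5)
  f1 <- pretrain(grid, pairs, siam_model(model_config(), seed = 5), cfg)
  f2 <- pretrain(grid, pairs, siam_model(model_config(), seed = 5), cfg)
  expect_identical(f1$trace$steps$loss, f2$trace$steps$loss)
  ns <- asNamespace("siamquality")
  expect_identical(ns$nn_param_vector(f1$model$encoder),
                   ns$nn_param_vector(f2$model$encoder))
})

test_that("strict-sort curriculum yields non-decreasing batch difficulty", {
  grid <- make_small_grid(spp = 20)
  pairs <- find_pairs(grid)
  fit <- pretrain(grid, pairs, siam_model(model_config(), seed = 3),
                  pretrain_config(epochs = 2, batch_size = 4,
                                  curriculum_mode = "strict_sort", seed = 3))
  for (ep in unique(fit$trace$steps$epoch)) {
    mc <- fit$trace$steps$mean_c[fit$trace$steps$epoch == ep]
    expect_true(!is.unsorted(mc))
  }
})

test_that("pretraining rejects empty pairs and aborts on non-finite loss", {
  grid <- make_small_grid(spp = 4)
  empty <- find_pairs(as.data.frame(grid)[0, ])
  expect_error(pretrain(grid, empty), "non-empty")
})

test_that("collapse diagnostic is zero for identical embeddings and ~1/sqrt(d) for random ones", {
  z <- matrix(rep(c(1, 2, 3, 4), each = 10), nrow = 10)
  expect_equal(collapse_diagnostic(z), 0)
  withr::with_seed(17, {
    R <- matrix(rnorm(1000 * 32), 1000, 32)
    d <- collapse_diagnostic(R)
    expect_lt(abs(d - 1 / sqrt(32)) / (1 / sqrt(32)), 0.3)
  })
  expect_error(collapse_diagnostic(matrix(1, 1, 4)), "at least 2")
})

test_that("fine-tune-last freezes the encoder bit-for-bit", {
  ns <- asNamespace("siamquality")
  grid <- make_small_grid(spp = 10)
  hr <- vapply(grid, function(s) s$meta$hr_bpm, 0)
  m <- siam_model(model_config(), seed = 2)
  before <- ns$nn_param_vector(m$encoder)
  ft <- finetune(m, grid, hr, finetune_config("fine_tune_last", epochs = 3,
                                              seed = 2))
  expect_identical(ns$nn_param_vector(ft$model$encoder), before)
  # and the caller's model object is also untouched
  expect_identical(ns$nn_param_vector(m$encoder), before)
  preds <- predict(ft, grid)
  expect_length(preds, length(grid))
})

test_that("fine-tune-all updates the encoder and fits the task", {
  ns <- asNamespace("siamquality")
  grid <- make_small_grid(spp = 16, seed = 4)
  hr <- vapply(grid, function(s) s$meta$hr_bpm, 0)
  m <- siam_model(model_config(), seed = 4)
  before <- ns$nn_param_vector(m$encoder)
  ft <- finetune(m, grid, hr, finetune_config("fine_tune_all", epochs = 4,
                                              seed = 4))
  expect_false(identical(ns$nn_param_vector(ft$model$encoder), before))
  expect_lt(tail(ft$epoch_loss, 1), ft$epoch_loss[1])
})

test_that("classification fine-tuning predicts factor labels", {
  grid <- make_small_grid(spp = 12, seed = 6)
  lab <- factor(ifelse(vapply(grid, function(s) s$meta$hr_bpm, 0) > 80,
                       "fast", "slow"))
  m <- siam_model(model_config(), seed = 6)
  ft <- finetune(m, grid, lab,
                 finetune_config("fine_tune_last", task_kind = "classification",
                                 head_dim = 2, epochs = 10, seed = 6))
  preds <- predict(ft, grid)
  expect_s3_class(preds, "factor")
  expect_identical(levels(preds), c("fast", "slow"))
  expect_error(finetune(m, grid, lab, finetune_config("fine_tune_last")),
               "numeric targets")
})

test_that("target/task mismatches raise explicit errors", {
  grid <- make_small_grid(spp = 4)
  m <- siam_model(model_config(), seed = 1)
  expect_error(finetune(m, grid, 1:3), "length")
})
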