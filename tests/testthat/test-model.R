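test_that("encoder output dimensions follow the configuration", {
  cfg <- tiny_test_config()
  m <- siam_model(cfg, seed = 1)
  h <- encode(m, random_input(200, 3))
  expect_identical(dim(h), c(3L, 16L))
  out <- siam_forward(m, random_input(200, 2))
  expect_identical(dim(out$z), c(8L, 2L))
  expect_identical(dim(out$p), c(8L, 2L))
  expect_error(encode(m, matrix(runif(100), 50, 2)), "length mismatch")
})

test_that("evaluation-mode encoding is deterministic and batch-consistent", {
  m <- siam_model(tiny_test_config(), seed = 2)
  X <- random_input(200, 5, seed = 3)
  h1 <- encode(m, X)
  h2 <- encode(m, X)
  expect_identical(h1, h2)
  singles <- t(vapply(seq_len(5), function(i) encode(m, X[, i])[1, ],
                      numeric(16)))
  expect_equal(unname(h1), unname(singles), tolerance = 1e-12)
})

test_that("the predictor preserves dimension so it can be applied twice", {
  m <- siam_model(tiny_test_config(), seed = 4)
  z <- matrix(rnorm(8 * 2), 8, 2)
  ns <- asNamespace("siamquality")
  p1 <- ns$nn_forward(m$predictor, z, training = FALSE)$out
  p2 <- ns$nn_forward(m$predictor, p1, training = FALSE)$out
  expect_identical(dim(p2), dim(z))
})

test_that("negative cosine matches its algebraic definition and bounds", {
  v <- c(1, 2, 3)
  expect_equal(negative_cosine(v, v), -1)
  expect_equal(negative_cosine(c(1, 0), c(0, 1)), 0)
  withr::with_seed(11, {
    for (i in 1:200) {
      p <- rnorm(3); z <- rnorm(3)
      direct <- -sum(p * z) / (sqrt(sum(p^2)) * sqrt(sum(z^2)))
      expect_equal(negative_cosine(p, z), direct, tolerance = 1e-12)
      expect_true(abs(negative_cosine(p, z)) <= 1 + 1e-12)
      # positive rescaling of either argument changes nothing
      expect_equal(negative_cosine(3.7 * p, z), negative_cosine(p, z),
                   tolerance = 1e-12)
      expect_equal(negative_cosine(p, 0.2 * z), negative_cosine(p, z),
                   tolerance = 1e-12)
    }
  })
  expect_error(negative_cosine(c(0, 0), c(1, 1)), "zero vectors")
  expect_error(negative_cosine(c(1, 0, 0), c(1, 1)), "equal dimensions")
})

test_that("pair loss attains its analytic extremes and scales linearly", {
  u1 <- c(1, 0, 0); u2 <- c(0, 1, 0)
  # p_good = z_bad and p_bad = z_good: both cosines are 1, loss = -2
  expect_equal(pair_loss(list(p = u1, z = u2), list(p = u2, z = u1)), -2)
  # four mutually orthogonal unit vectors: both terms vanish
  e <- diag(4)
  expect_equal(pair_loss(list(p = e[, 1], z = e[, 2]),
                         list(p = e[, 3], z = e[, 4])), 0)
  withr::with_seed(13, {
    for (i in 1:50) {
      a <- list(p = rnorm(4), z = rnorm(4))
      b <- list(p = rnorm(4), z = rnorm(4))
      l1 <- pair_loss(a, b, scale = 1)
      expect_equal(pair_loss(a, b, scale = 0.5), l1 / 2, tolerance = 1e-12)
      expect_true(l1 >= -2 - 1e-12 && l1 <= 2 + 1e-12)
      expect_equal(pair_loss(b, a), l1, tolerance = 1e-12)  # symmetry
    }
  })
})

test_that("backpropagated gradients match finite differences without stop-gradient", {
  ns <- asNamespace("siamquality")
  cfg <- model_config(encoder_variant = "tiny_1d", input_length = 80,
                      feature_dim = 8, projection_dim = 4,
                      projector_hidden = 6, predictor_hidden = 3,
                      stop_gradient = FALSE)
  m <- siam_model(cfg, seed = 2)
  xg <- random_input(80, 3, seed = 21)
  xb <- random_input(80, 3, seed = 22)
  envs <- c(ns$nn_param_envs(m$encoder), ns$nn_param_envs(m$projector),
            ns$nn_param_envs(m$predictor))
  lossfun <- function() {
    fg <- siam_forward(m, xg, training = TRUE)
    fb <- siam_forward(m, xb, training = TRUE)
    mean(negative_cosine(fg$p, fb$z) + negative_cosine(fb$p, fg$z))
  }
  ns$nn_zero_grads(envs)
  fg <- siam_forward(m, xg, training = TRUE)
  fb <- siam_forward(m, xb, training = TRUE)
  B <- 3
  dpg <- (1 / B) * ns$negcos_grad_p(fg$p, fb$z)
  dpb <- (1 / B) * ns$negcos_grad_p(fb$p, fg$z)
  dzg <- ns$nn_backward(m$predictor, fg$caches$predictor, dpg) +
    (1 / B) * ns$negcos_grad_p(fg$z, fb$p)
  dzb <- ns$nn_backward(m$predictor, fb$caches$predictor, dpb) +
    (1 / B) * ns$negcos_grad_p(fb$z, fg$p)
  dhg <- ns$nn_backward(m$projector, fg$caches$projector, dzg)
  dhb <- ns$nn_backward(m$projector, fb$caches$projector, dzb)
  ns$nn_backward(m$encoder, fg$caches$encoder, dhg)
  ns$nn_backward(m$encoder, fb$caches$encoder, dhb)
  withr::with_seed(31, {
    for (t in 1:15) {
      e <- envs[[sample(length(envs), 1)]]
      nm <- sample(intersect(c("W", "b", "gamma", "beta"), ls(e)), 1)
      v <- e[[nm]]; i <- sample(length(v), 1); eps <- 1e-6; v0 <- v[i]
      v[i] <- v0 + eps; e[[nm]] <- v; lp <- lossfun()
      v[i] <- v0 - eps; e[[nm]] <- v; lm <- lossfun()
      v[i] <- v0; e[[nm]] <- v
      g_num <- (lp - lm) / (2 * eps)
      g_an <- e[[paste0("g", if (nm == "W") "W" else if (nm == "b") "b" else nm)]][i]
      expect_lt(abs(g_num - g_an) / max(1e-6, abs(g_num) + abs(g_an)), 1e-4)
    }
  })
})

test_that("the stop-gradient contract blocks the projection-target pathway", {
  ns <- asNamespace("siamquality")
  cfg <- model_config(encoder_variant = "tiny_1d", input_length = 80,
                      feature_dim = 8, projection_dim = 4,
                      projector_hidden = 6, predictor_hidden = 3)
  xg <- random_input(80, 2, seed = 41)
  xb <- random_input(80, 2, seed = 42)
  grads_with_flag <- function(stop_gradient) {
    m <- siam_model(cfg, seed = 6)
    envs <- c(ns$nn_param_envs(m$encoder), ns$nn_param_envs(m$projector),
              ns$nn_param_envs(m$predictor))
    ns$nn_zero_grads(envs)
    fg <- siam_forward(m, xg, training = TRUE)
    fb <- siam_forward(m, xb, training = TRUE)
    dpg <- 0.5 * ns$negcos_grad_p(fg$p, fb$z)
    dpb <- 0.5 * ns$negcos_grad_p(fb$p, fg$z)
    dzg <- ns$nn_backward(m$predictor, fg$caches$predictor, dpg)
    dzb <- ns$nn_backward(m$predictor, fb$caches$predictor, dpb)
    if (!stop_gradient) {
      dzg <- dzg + 0.5 * ns$negcos_grad_p(fg$z, fb$p)
      dzb <- dzb + 0.5 * ns$negcos_grad_p(fb$z, fg$p)
    }
    dhg <- ns$nn_backward(m$projector, fg$caches$projector, dzg)
    dhb <- ns$nn_backward(m$projector, fb$caches$projector, dzb)
    ns$nn_backward(m$encoder, fg$caches$encoder, dhg)
    ns$nn_backward(m$encoder, fb$caches$encoder, dhb)
    proj_env <- ns$nn_param_envs(m$projector)[[1]]
    pred_env <- ns$nn_param_envs(m$predictor)[[1]]
    list(proj = proj_env$gW, pred = pred_env$gW)
  }
  g_sg <- grads_with_flag(TRUE)
  g_full <- grads_with_flag(FALSE)
  # predictor gradients identical (its only input path is p); projector
  # gradients differ because stop-gradient removes the target pathway
  expect_equal(g_sg$pred, g_full$pred, tolerance = 1e-12)
  expect_gt(max(abs(g_sg$proj - g_full$proj)), 1e-8)
})

test_that("a predictor-only update leaves encoder and projector parameters untouched", {
  ns <- asNamespace("siamquality")
  m <- siam_model(tiny_test_config(), seed = 8)
  before_enc <- ns$nn_param_vector(m$encoder)
  before_proj <- ns$nn_param_vector(m$projector)
  pred_envs <- ns$nn_param_envs(m$predictor)
  xg <- random_input(200, 2, seed = 51)
  xb <- random_input(200, 2, seed = 52)
  ns$siam_train_step(m, xg, xb, 1, TRUE, pred_envs, 0.05, 0.9, 0)
  after_enc <- ns$nn_param_vector(m$encoder)
  after_proj <- ns$nn_param_vector(m$projector)
  # learnable parameters identical (running statistics evolve by design)
  learn <- function(v) v[!grepl("rmean|rvar", names(v))]
  expect_identical(learn(before_enc), learn(after_enc))
  expect_identical(learn(before_proj), learn(after_proj))
  expect_false(identical(ns$nn_param_vector(m$predictor),
                         ns$nn_param_vector(m$predictor) * 0))
})

test_that("checkpoints round-trip parameters and verify configuration", {
  m <- siam_model(tiny_test_config(), seed = 9)
  path <- tempfile(fileext = ".rds")
  save_checkpoint(m, path)
  m2 <- load_checkpoint(path)
  X <- random_input(200, 3, seed = 7)
  expect_identical(encode(m, X), encode(m2, X))
  bad <- tempfile(fileext = ".rds")
  saveRDS(list(a = 1), bad)
  expect_error(load_checkpoint(bad), "checkpoint")
})

test_that("bottleneck encoder variants build with the canonical feature width", {
  cfg <- model_config(encoder_variant = "resnet50_1d", input_length = 96)
  expect_identical(cfg$feature_dim, 2048L)
  m <- siam_model(cfg, seed = 1)
  h <- encode(m, random_input(96, 1))
  expect_identical(dim(h), c(1L, 2048L))
})
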