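#' Pretraining configuration
#'
#' Hyperparameters of the self-supervised stage.  Defaults follow the
#' SimSiam reference recipe the architecture is based on (momentum SGD,
#' cosine learning-rate decay, decoupled weight decay), sized for desk-scale
#' encoders.
#'
#' @param epochs Number of passes over the pair set (>= 1).
#' @param batch_size Pairs per gradient step (>= 1).
#' @param learning_rate Base learning rate.
#' @param momentum SGD momentum.
#' @param weight_decay L2 weight decay on conv/dense weights.
#' @param cosine_decay Whether to decay the learning rate with a half-cosine
#'   over the run; off by default, since at desk-scale step counts a constant
#'   rate trains further.
#' @param warmup_frac Fraction of total steps over which the learning rate
#'   ramps linearly from zero; stabilizes the noisy early phase.
#' @param clip_norm Global gradient-norm ceiling per step (Inf disables).
#' @param curriculum_mode \code{"staged_buckets"} (default: equal-width
#'   c-bins consumed easy-to-hard, shuffled within bins),
#'   \code{"strict_sort"} (deterministic ascending c), or
#'   \code{"shuffled_control"} (no curriculum; for ablation).
#' @param n_buckets Bins for the staged mode.
#' @param reorder_each_epoch Re-draw within-bin shuffles per epoch (seeded);
#'   with \code{FALSE} the first ordering is replayed every epoch.
#' @param loss_scale Pair-loss scale: 1 = two-term sum, 0.5 = averaged form.
#' @param seed Integer seed governing ordering and any training randomness.
#' @return A list of class \code{pretrain_config}.
#' @export
pretrain_config <- function(epochs = 5, batch_size = 8, learning_rate = 0.05,
                            momentum = 0.9, weight_decay = 1e-4,
                            cosine_decay = FALSE, warmup_frac = 0.1,
                            clip_norm = 5,
                            curriculum_mode = c("staged_buckets", "strict_sort",
                                                "shuffled_control"),
                            n_buckets = 5, reorder_each_epoch = TRUE,
                            loss_scale = 1, seed = 1L) {
  stopifnot(epochs >= 1, batch_size >= 1, learning_rate > 0)
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, momentum = momentum,
                 weight_decay = weight_decay, cosine_decay = cosine_decay,
                 warmup_frac = warmup_frac, clip_norm = clip_norm,
                 curriculum_mode = match.arg(curriculum_mode),
                 n_buckets = n_buckets,
                 reorder_each_epoch = isTRUE(reorder_each_epoch),
                 loss_scale = loss_scale, seed = as.integer(seed)),
            class = "pretrain_config")
}

order_for_epoch <- function(pairs, config, epoch) {
  eseed <- if (config$reorder_each_epoch)
    derive_seed(config$seed, epoch) else derive_seed(config$seed, 1L)
  switch(config$curriculum_mode,
    strict_sort = curriculum_order(pairs, "strict_sort"),
    staged_buckets = curriculum_order(pairs, "staged_buckets",
                                      n_buckets = config$n_buckets,
                                      seed = eseed),
    shuffled_control = {
      ord <- withr::with_seed(eseed, sample.int(nrow(pairs)))
      out <- pairs[ord, , drop = FALSE]; rownames(out) <- NULL; out
    })
}

# rescale all gradients so their global L2 norm is at most clip_norm
nn_clip_grads <- function(envs, clip_norm) {
  if (!is.finite(clip_norm)) return(invisible(NULL))
  total <- 0
  for (e in envs) {
    if (!is.null(e$gW)) total <- total + sum(e$gW^2)
    if (!is.null(e$gb)) total <- total + sum(e$gb^2)
    if (!is.null(e$ggamma)) total <- total + sum(e$ggamma^2) + sum(e$gbeta^2)
  }
  gnorm <- sqrt(total)
  if (gnorm <= clip_norm) return(invisible(NULL))
  f <- clip_norm / gnorm
  for (e in envs) {
    if (!is.null(e$gW)) e$gW <- e$gW * f
    if (!is.null(e$gb)) e$gb <- e$gb * f
    if (!is.null(e$ggamma)) { e$ggamma <- e$ggamma * f; e$gbeta <- e$gbeta * f }
  }
  invisible(NULL)
}

# one gradient step on a batch of pairs; returns the mean batch loss
siam_train_step <- function(model, xg, xb, scale, stop_gradient, envs,
                            lr, momentum, weight_decay, clip_norm = Inf) {
  fg <- siam_forward(model, xg, training = TRUE)
  fb <- siam_forward(model, xb, training = TRUE)
  B <- ncol(fg$p)
  loss <- scale * mean(negative_cosine(fg$p, fb$z) +
                         negative_cosine(fb$p, fg$z))
  if (!is.finite(loss))
    stopf("non-finite pretraining loss (%s); aborting", loss)

  nn_zero_grads(envs)
  dpg <- (scale / B) * negcos_grad_p(fg$p, fb$z)
  dpb <- (scale / B) * negcos_grad_p(fb$p, fg$z)
  # branch "good": gradient reaches z_good through the predictor, plus --
  # only if the stop-gradient contract is lifted -- directly from the
  # second loss term where z_good is the target
  dzg <- nn_backward(model$predictor, fg$caches$predictor, dpg)
  dzb <- nn_backward(model$predictor, fb$caches$predictor, dpb)
  if (!stop_gradient) {
    dzg <- dzg + (scale / B) * negcos_grad_p(fg$z, fb$p)
    dzb <- dzb + (scale / B) * negcos_grad_p(fb$z, fg$p)
  }
  dhg <- nn_backward(model$projector, fg$caches$projector, dzg)
  dhb <- nn_backward(model$projector, fb$caches$projector, dzb)
  nn_backward(model$encoder, fg$caches$encoder, dhg)
  nn_backward(model$encoder, fb$caches$encoder, dhb)
  nn_clip_grads(envs, clip_norm)
  nn_sgd_step(envs, lr, momentum, weight_decay)
  loss
}

#' Self-supervised pretraining on quality pairs
#'
#' Trains the shared encoder/projector/predictor on (high-quality,
#' low-quality) segment pairs with the symmetric negative-cosine loss,
#' consuming batches in curriculum order.  Both branches use the single
#' parameter store of \code{model}; the run is reproducible bit-for-bit
#' given the configuration seed.
#'
#' @param segments The \code{ppg_segments} collection the pair indices refer
#'   to.
#' @param pairs A non-empty \code{quality_pairs} data.frame from
#'   \code{\link{find_pairs}}.
#' @param model A \code{siam_model} (modified in place and also returned).
#' @param config A \code{\link{pretrain_config}}.
#' @return List with \code{model} and \code{trace}; the trace holds
#'   per-step losses with batch mean c, per-epoch mean losses, and a
#'   per-epoch embedding-dispersion diagnostic (collapse guard).
#' @export
pretrain <- function(segments, pairs, model = NULL,
                     config = pretrain_config()) {
  if (is.null(pairs) || !nrow(pairs)) stopf("`pairs` must be non-empty")
  stopifnot(inherits(config, "pretrain_config"))
  if (is.null(model)) model <- siam_model(model_config(), seed = config$seed)

  X <- segment_matrix(segments)
  envs <- c(nn_param_envs(model$encoder), nn_param_envs(model$projector),
            nn_param_envs(model$predictor))
  total_steps <- config$epochs * ceiling(nrow(pairs) / config$batch_size)
  steps <- data.frame(step = integer(), epoch = integer(), loss = numeric(),
                      mean_c = numeric())
  epoch_loss <- numeric(config$epochs)
  epoch_dispersion <- numeric(config$epochs)
  step <- 0L
  for (epoch in seq_len(config$epochs)) {
    ordered <- order_for_epoch(pairs, config, epoch)
    starts <- seq(1L, nrow(ordered), by = config$batch_size)
    losses <- numeric(length(starts))
    for (bi in seq_along(starts)) {
      idx <- starts[bi]:min(starts[bi] + config$batch_size - 1L, nrow(ordered))
      step <- step + 1L
      lr <- if (config$cosine_decay)
        config$learning_rate * 0.5 * (1 + cos(pi * (step - 1) / total_steps))
      else config$learning_rate
      warm_steps <- ceiling(config$warmup_frac * total_steps)
      if (warm_steps > 0 && step <= warm_steps)
        lr <- lr * step / warm_steps
      xg <- X[, ordered$good_idx[idx], drop = FALSE]
      xb <- X[, ordered$bad_idx[idx], drop = FALSE]
      losses[bi] <- siam_train_step(model, xg, xb, config$loss_scale,
                                    model$config$stop_gradient, envs, lr,
                                    config$momentum, config$weight_decay,
                                    config$clip_norm)
      steps <- rbind(steps, data.frame(step = step, epoch = epoch,
                                       loss = losses[bi],
                                       mean_c = mean(ordered$c[idx])))
    }
    epoch_loss[epoch] <- mean(losses)
    # dispersion of projections over (a sample of) the pair segments
    probe <- unique(c(ordered$good_idx, ordered$bad_idx))
    if (length(probe) > 64L) probe <- probe[seq_len(64L)]
    fz <- siam_forward(model, X[, probe, drop = FALSE], training = FALSE)
    epoch_dispersion[epoch] <- collapse_diagnostic(t(fz$z))
  }
  list(model = model,
       trace = list(steps = steps, epoch_loss = epoch_loss,
                    epoch_dispersion = epoch_dispersion))
}

#' Embedding-dispersion collapse diagnostic
#'
#' Mean per-dimension standard deviation of length-normalized embeddings.
#' Values near zero indicate representational collapse (all embeddings
#' identical up to scale); independent random unit vectors in dimension d
#' give roughly 1/sqrt(d).
#'
#' @param embeddings Matrix with one row per embedding (>= 2 rows).
#' @return Non-negative scalar.
#' @export
collapse_diagnostic <- function(embeddings) {
  if (is.vector(embeddings)) embeddings <- matrix(embeddings, nrow = 1)
  if (nrow(embeddings) < 2) stopf("need at least 2 embeddings")
  nrm <- sqrt(rowSums(embeddings^2))
  nrm[nrm == 0] <- 1
  zn <- embeddings / nrm
  mean(apply(zn, 2, sd))
}

#' Fine-tuning configuration
#'
#' @param strategy \code{"fine_tune_all"} updates encoder and head;
#'   \code{"fine_tune_last"} freezes the encoder (parameters and running
#'   statistics bit-identical before and after) and trains only the newly
#'   initialized head; \code{"in_domain_pretrain_then_last"} first pretrains
#'   on the target dataset's own unlabeled quality pairs, then fine-tunes
#'   the head on the frozen result.
#' @param task_kind \code{"regression"} (linear head on h, squared-error
#'   loss) or \code{"classification"} (linear + softmax head, cross-entropy).
#' @param head_dim Output dimension (1 for regression; number of classes for
#'   classification).
#' @param epochs,batch_size,learning_rate,momentum Optimization settings for
#'   the supervised stage.
#' @param clip_norm Global gradient-norm ceiling per step (Inf disables).
#' @param pretrain Optional \code{\link{pretrain_config}} for the in-domain
#'   strategy.
#' @param seed Integer seed.
#' @return A list of class \code{finetune_config}.
#' @export
finetune_config <- function(strategy = c("fine_tune_all", "fine_tune_last",
                                         "in_domain_pretrain_then_last"),
                            task_kind = c("regression", "classification"),
                            head_dim = 1, epochs = 30, batch_size = 16,
                            learning_rate = 0.01, momentum = 0.9,
                            clip_norm = 5, pretrain = NULL, seed = 1L) {
  structure(list(strategy = match.arg(strategy),
                 task_kind = match.arg(task_kind),
                 head_dim = as.integer(head_dim), epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, momentum = momentum,
                 clip_norm = clip_norm,
                 pretrain = pretrain, seed = as.integer(seed)),
            class = "finetune_config")
}

softmax_cols <- function(s) {
  s <- sweep(s, 2, apply(s, 2, max))
  es <- exp(s)
  sweep(es, 2, colSums(es), "/")
}

#' Fine-tune a pretrained model on a labelled task
#'
#' Attaches a newly initialized linear head to the encoder representation h
#' and trains according to the chosen strategy.  Regression targets are
#' standardized internally (the returned predictor reports on the original
#' scale); classification targets must be a factor or integer class labels.
#'
#' @param model A pretrained \code{siam_model}; it is cloned via checkpoint
#'   round-trip, so the caller's model is never modified.
#' @param segments A \code{ppg_segments} collection (the labelled dataset).
#' @param targets Numeric vector (regression) or factor/integer
#'   (classification), one per segment.
#' @param config A \code{\link{finetune_config}}.
#' @param pairs Optional \code{quality_pairs} for the in-domain strategy;
#'   computed from \code{segments} with default pairing if omitted.
#' @return An object of class \code{siam_finetune}: list with the adapted
#'   \code{model}, \code{head} parameters, \code{config}, target scaling,
#'   and the per-epoch training-loss trace.  Use \code{predict()} on new
#'   segments.
#' @export
finetune <- function(model, segments, targets, config = finetune_config(),
                     pairs = NULL) {
  stopifnot(inherits(model, "siam_model"), inherits(config, "finetune_config"))
  n <- length(segments)
  if (length(targets) != n)
    stopf("`targets` length (%d) must match segments (%d)", length(targets), n)
  if (config$task_kind == "regression" && !is.numeric(targets))
    stopf("regression requires numeric targets")
  if (config$task_kind == "classification" &&
      !(is.factor(targets) || is.integer(targets) || is.character(targets)))
    stopf("classification requires factor/integer/character targets")

  # work on a private copy so the caller's model is untouched
  tmp <- tempfile(fileext = ".rds")
  on.exit(unlink(tmp), add = TRUE)
  save_checkpoint(model, tmp)
  model <- load_checkpoint(tmp)

  if (config$strategy == "in_domain_pretrain_then_last") {
    if (is.null(pairs)) pairs <- find_pairs(segments)
    pc <- if (is.null(config$pretrain))
      pretrain_config(epochs = 3, seed = config$seed) else config$pretrain
    if (nrow(pairs)) model <- pretrain(segments, pairs, model, pc)$model
  }
  freeze <- config$strategy != "fine_tune_all"

  X <- segment_matrix(segments)
  fd <- model$config$feature_dim
  if (config$task_kind == "regression") {
    mu_t <- mean(targets); sd_t <- sd(targets)
    if (!is.finite(sd_t) || sd_t == 0) sd_t <- 1
    Y <- matrix((targets - mu_t) / sd_t, nrow = 1)
    classes <- NULL
    out_dim <- 1L
  } else {
    f <- factor(targets)
    classes <- levels(f)
    out_dim <- length(classes)
    Y <- matrix(0, out_dim, n)
    Y[cbind(as.integer(f), seq_len(n))] <- 1
    mu_t <- 0; sd_t <- 1
  }

  head <- withr::with_seed(derive_seed(config$seed, 99L),
                           nn_dense(fd, out_dim, bias = TRUE))
  head_envs <- nn_param_envs(head)
  enc_envs <- nn_param_envs(model$encoder)
  envs <- if (freeze) head_envs else c(head_envs, enc_envs)

  # frozen encoder: representations are fixed, compute them once
  H_fixed <- if (freeze) t(encode(model, X)) else NULL  # (fd x n)

  epoch_loss <- numeric(config$epochs)
  for (epoch in seq_len(config$epochs)) {
    ord <- withr::with_seed(derive_seed(config$seed, 1000L + epoch),
                            sample.int(n))
    starts <- seq(1L, n, by = config$batch_size)
    losses <- numeric(length(starts))
    for (bi in seq_along(starts)) {
      idx <- ord[starts[bi]:min(starts[bi] + config$batch_size - 1L, n)]
      B <- length(idx)
      if (freeze) {
        h <- H_fixed[, idx, drop = FALSE]
        fh <- nn_forward(head, h, training = TRUE)
      } else {
        fe <- nn_forward(model$encoder,
                         as_model_input(X[, idx, drop = FALSE],
                                        model$config$input_length),
                         training = TRUE)
        h <- fe$out
        fh <- nn_forward(head, h, training = TRUE)
      }
      yb <- Y[, idx, drop = FALSE]
      if (config$task_kind == "regression") {
        err <- fh$out - yb
        losses[bi] <- mean(err^2)
        dout <- 2 * err / (B * nrow(err))
      } else {
        pr <- softmax_cols(fh$out)
        losses[bi] <- -mean(colSums(yb * log(pmax(pr, 1e-12))))
        dout <- (pr - yb) / B
      }
      nn_zero_grads(envs)
      dh <- nn_backward(head, fh$cache, dout)
      if (!freeze) nn_backward(model$encoder, fe$cache, dh)
      nn_clip_grads(envs, config$clip_norm)
      nn_sgd_step(envs, config$learning_rate, config$momentum, 0)
    }
    epoch_loss[epoch] <- mean(losses)
  }

  structure(list(model = model, head = head, config = config,
                 target_mean = mu_t, target_sd = sd_t, classes = classes,
                 epoch_loss = epoch_loss),
            class = "siam_finetune")
}

#' Predict with a fine-tuned model
#'
#' @param object A \code{siam_finetune}.
#' @param newdata Segments (see \code{\link{encode}} for accepted forms).
#' @param ... Unused.
#' @return Numeric predictions on the original target scale (regression) or
#'   a factor of class labels (classification).
#' @export
predict.siam_finetune <- function(object, newdata, ...) {
  H <- t(encode(object$model, newdata))  # (fd x n)
  out <- nn_forward(object$head, H, training = FALSE)$out
  if (object$config$task_kind == "regression") {
    as.numeric(out) * object$target_sd + object$target_mean
  } else {
    factor(object$classes[apply(out, 2, which.max)], levels = object$classes)
  }
}
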