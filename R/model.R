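#' Configuration of the siamese network
#'
#' The network has three parts sharing one parameter store across the two
#' branches: an encoder E (1-D residual convolutional network ending in
#' global average pooling, h = E(x)), a projector P of three fully-connected
#' layers (z = P(h)), and a predictor D of three fully-connected layers with
#' equal input and output dimension (p = D(z)).  Hidden layers use ReLU with
#' batch normalization; the projector output is batch-normalized, the
#' predictor has a bottleneck hidden layer, following the SimSiam reference
#' design the architecture builds on.
#'
#' @param encoder_variant One of \code{"tiny_1d"} (4 basic residual blocks;
#'   desk-scale), \code{"resnet50_1d"}, \code{"resnet101_1d"},
#'   \code{"resnet152_1d"} (bottleneck blocks, canonical 1-D translation of
#'   the 2-D originals: stem kernel 7 stride 2, max-pooling, stage widths
#'   64/128/256/512 with expansion 4).
#' @param input_length Expected segment length in samples (default 1200 =
#'   30 s at 40 Hz).
#' @param feature_dim Encoder output dimension h; fixed at 2048 for the
#'   bottleneck variants, configurable (default 64) for \code{tiny_1d}.
#' @param projection_dim Dimension of z and p.
#' @param projector_hidden,predictor_hidden Hidden-layer widths.
#' @param stop_gradient Whether the projection of the opposite branch is
#'   treated as a constant in the loss (the collapse-avoidance contract);
#'   exposed as a flag for ablation.
#' @return A list of class \code{model_config}.
#' @export
model_config <- function(encoder_variant = c("tiny_1d", "resnet50_1d",
                                             "resnet101_1d", "resnet152_1d"),
                         input_length = 1200, feature_dim = NULL,
                         projection_dim = 32, projector_hidden = 64,
                         predictor_hidden = 16, stop_gradient = TRUE) {
  encoder_variant <- match.arg(encoder_variant)
  feature_dim <- encoder_feature_dim(encoder_variant, feature_dim)
  stopifnot(input_length >= 1, feature_dim >= 1, projection_dim >= 1,
            projector_hidden >= 1, predictor_hidden >= 1)
  structure(list(encoder_variant = encoder_variant,
                 input_length = as.integer(input_length),
                 feature_dim = as.integer(feature_dim),
                 projection_dim = as.integer(projection_dim),
                 projector_hidden = as.integer(projector_hidden),
                 predictor_hidden = as.integer(predictor_hidden),
                 stop_gradient = isTRUE(stop_gradient)),
            class = "model_config")
}

#' Build a siamese model
#'
#' Instantiates encoder, projector and predictor with seeded random weights.
#' The same object serves both branches (weight sharing by construction).
#'
#' @param config A \code{\link{model_config}}.
#' @param seed Integer seed for weight initialization.
#' @return An object of class \code{siam_model}.
#' @examples
#' m <- siam_model(model_config(input_length = 1200), seed = 1)
#' h <- encode(m, matrix(runif(1200), ncol = 1))
#' dim(h)  # 1 x feature_dim
#' @export
siam_model <- function(config = model_config(), seed = 1L) {
  stopifnot(inherits(config, "model_config"))
  withr::with_seed(as.integer(seed), {
    encoder <- build_encoder(config$encoder_variant, config$feature_dim)
    projector <- nn_seq(
      nn_dense(config$feature_dim, config$projector_hidden, bias = FALSE),
      nn_bn(config$projector_hidden), nn_relu(),
      nn_dense(config$projector_hidden, config$projector_hidden, bias = FALSE),
      nn_bn(config$projector_hidden), nn_relu(),
      nn_dense(config$projector_hidden, config$projection_dim, bias = FALSE),
      nn_bn(config$projection_dim))
    predictor <- nn_seq(
      nn_dense(config$projection_dim, config$predictor_hidden, bias = FALSE),
      nn_bn(config$predictor_hidden), nn_relu(),
      nn_dense(config$predictor_hidden, config$predictor_hidden, bias = FALSE),
      nn_bn(config$predictor_hidden), nn_relu(),
      nn_dense(config$predictor_hidden, config$projection_dim, bias = TRUE))
    structure(list(config = config, encoder = encoder, projector = projector,
                   predictor = predictor, seed = as.integer(seed)),
              class = "siam_model")
  })
}

#' @export
print.siam_model <- function(x, ...) {
  np <- length(nn_param_vector(x$encoder)) + length(nn_param_vector(x$projector)) +
    length(nn_param_vector(x$predictor))
  cat(sprintf("<siam_model> %s: input %d, h %d, z/p %d; %d parameters\n",
              x$config$encoder_variant, x$config$input_length,
              x$config$feature_dim, x$config$projection_dim, np))
  invisible(x)
}

# coerce segments / matrix / vector into the (1, L, B) input array
as_model_input <- function(x, input_length) {
  if (inherits(x, "ppg_segments") || (is.list(x) && !is.data.frame(x) &&
                                      inherits(x[[1]], "ppg_segment")))
    x <- segment_matrix(x)
  if (is.vector(x) && is.numeric(x)) x <- matrix(x, ncol = 1)
  if (inherits(x, "ppg_segment")) x <- matrix(x$samples, ncol = 1)
  if (nrow(x) != input_length && ncol(x) == input_length) x <- t(x)
  if (nrow(x) != input_length)
    stopf("input length mismatch: expected %d samples, got %d",
          input_length, nrow(x))
  array(x, c(1L, nrow(x), ncol(x)))
}

#' Encode segments into representations
#'
#' Runs the network in evaluation mode (batch-norm uses running statistics,
#' so batched encoding equals stacked single encodings and repeated calls are
#' bit-identical).  \code{space = "representation"} returns the encoder
#' output h = E(x); \code{space = "projection"} returns the latent
#' representation z = P(E(x)), the space in which the contrastive objective
#' aligns pair members.
#'
#' @param model A \code{siam_model}.
#' @param x A \code{ppg_segments} collection, a numeric matrix with one
#'   column (or row) per segment, or a single numeric vector.
#' @param space \code{"representation"} (h) or \code{"projection"} (z).
#' @param use_batch_stats Normalize with the statistics of the encoded set
#'   itself instead of the stored running statistics (no state is updated).
#'   This is the appropriate convention when comparing against an untrained
#'   network, whose running statistics have never seen data and would
#'   otherwise make its embeddings degenerate.
#' @return Matrix with one row per segment.
#' @export
encode <- function(model, x, space = c("representation", "projection"),
                   use_batch_stats = FALSE) {
  stopifnot(inherits(model, "siam_model"))
  space <- match.arg(space)
  xin <- as_model_input(x, model$config$input_length)
  h <- nn_forward(model$encoder, xin, training = use_batch_stats,
                  update_stats = FALSE)$out
  if (space == "representation") return(t(h))
  t(nn_forward(model$projector, h, training = use_batch_stats,
               update_stats = FALSE)$out)
}

#' Full forward pass of one branch
#'
#' @param model A \code{siam_model}.
#' @param x Input segments (see \code{\link{encode}}).
#' @param training Logical; training mode uses batch statistics in the
#'   normalization layers.
#' @return List of class \code{siam_outputs} with matrices \code{h}, \code{z},
#'   \code{p} (one column per segment) and, invisibly, the caches needed for
#'   backpropagation.
#' @export
siam_forward <- function(model, x, training = FALSE) {
  xin <- as_model_input(x, model$config$input_length)
  fe <- nn_forward(model$encoder, xin, training)
  fp <- nn_forward(model$projector, fe$out, training)
  fd <- nn_forward(model$predictor, fp$out, training)
  structure(list(h = fe$out, z = fp$out, p = fd$out,
                 caches = list(encoder = fe$cache, projector = fp$cache,
                               predictor = fd$cache)),
            class = "siam_outputs")
}

#' Negative cosine similarity
#'
#' \code{-(p . z) / (||p|| ||z||)}, in [-1, 1].  During training the
#' \code{z} argument is treated as a constant (stop-gradient contract): no
#' update signal flows through it.
#'
#' @param p,z Nonzero numeric vectors of equal dimension, or matrices with
#'   one column per vector (vectorized over columns).
#' @return Numeric scalar (or vector, one value per column).
#' @examples
#' negative_cosine(c(1, 0), c(1, 0))  # -1
#' @export
negative_cosine <- function(p, z) {
  if (is.vector(p)) p <- matrix(p, ncol = 1)
  if (is.vector(z)) z <- matrix(z, ncol = 1)
  if (!all(dim(p) == dim(z)))
    stopf("`p` and `z` must have equal dimensions")
  np <- sqrt(colSums(p * p))
  nz <- sqrt(colSums(z * z))
  if (any(np == 0) || any(nz == 0))
    stopf("cosine similarity undefined for zero vectors")
  val <- -colSums(p * z) / (np * nz)
  if (length(val) == 1L) as.numeric(val) else val
}

# gradient of negative_cosine w.r.t. p (z constant), columnwise
negcos_grad_p <- function(p, z) {
  np <- sqrt(colSums(p * p))
  nz <- sqrt(colSums(z * z))
  d <- colSums(p * z)
  sweep(z, 2, np * nz, "/") * (-1) +
    sweep(p, 2, d / (np^3 * nz), "*")
}

#' Symmetric pair loss
#'
#' \code{scale * (negative_cosine(p_good, z_bad) + negative_cosine(p_bad,
#' z_good))}.  The default \code{scale = 1} is the displayed two-term loss;
#' \code{scale = 0.5} gives the averaged form.  Minimum \code{-2 * scale},
#' attained when each prediction aligns with the opposite projection.
#'
#' @param out_good,out_bad \code{siam_outputs} of the two branches (or lists
#'   with elements \code{p} and \code{z}).
#' @param scale Loss scale.
#' @return Numeric scalar (mean over the batch if the outputs are batched).
#' @export
pair_loss <- function(out_good, out_bad, scale = 1) {
  l <- negative_cosine(out_good$p, out_bad$z) +
    negative_cosine(out_bad$p, out_good$z)
  scale * mean(l)
}

#' Save / load a model checkpoint
#'
#' The checkpoint is a single RDS archive holding all parameters (including
#' batch-norm running statistics), the full \code{\link{model_config}} and
#' package-version metadata; loading verifies config compatibility.
#'
#' @param model A \code{siam_model}.
#' @param path File path.
#' @return \code{save_checkpoint} returns \code{path} invisibly;
#'   \code{load_checkpoint} returns the restored \code{siam_model}.
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "siam_model"))
  saveRDS(list(config = model$config, seed = model$seed,
               params = list(encoder = nn_param_vector(model$encoder),
                             projector = nn_param_vector(model$projector),
                             predictor = nn_param_vector(model$predictor)),
               package_version = as.character(utils::packageVersion("siamquality"))),
          path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  if (!inherits(ck$config, "model_config"))
    stopf("not a siamquality checkpoint: %s", path)
  model <- siam_model(ck$config, seed = ck$seed)
  nn_set_param_vector(model$encoder, ck$params$encoder)
  nn_set_param_vector(model$projector, ck$params$projector)
  nn_set_param_vector(model$predictor, ck$params$predictor)
  model
}
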