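# SGAN model: generator and discriminator specifications, forward passes,
# and the four loss quantities.  The discriminator emits two class logits
# (l1 = benign, l2 = oncogenic); the probability that an input is real
# rather than generated is D(x) = Z/(Z+1) with Z = exp(l1) + exp(l2) --
# algebraically the complement of the synthetic-class probability of a
# 3-class softmax whose third logit is pinned at 0.

#' Generator network specification
#'
#' Four linear layers: three hidden blocks (linear, batch normalization,
#' leaky ReLU, dropout) and a linear output passed through tanh and affinely
#' mapped into `[0, 1]` to match the min-max-scaled real features.
#'
#' @param noise_dim Dimension of the Gaussian noise input (default 100).
#' @param hidden Three hidden widths (default 128, 256, 512).
#' @param output_dim Width of the generated feature vector (default 71,
#'   the encoded-matrix column count).
#' @param leaky_slope Leaky-ReLU negative slope (default 0.2).
#' @param dropout Dropout rate in hidden layers (default 0.6).
#' @return An object of class `generator_spec`.
#' @export
generator_spec <- function(noise_dim = 100L, hidden = c(128L, 256L, 512L),
                           output_dim = 71L, leaky_slope = 0.2,
                           dropout = 0.6) {
  stopifnot(noise_dim >= 1, length(hidden) == 3L, all(hidden >= 1),
            output_dim >= 1, dropout >= 0, dropout < 1)
  structure(list(noise_dim = as.integer(noise_dim),
                 hidden = as.integer(hidden),
                 output_dim = as.integer(output_dim),
                 leaky_slope = leaky_slope, dropout = dropout),
            class = "generator_spec")
}

#' Discriminator network specification
#'
#' Three 1-d convolution stages (leaky ReLU, valid padding) over the encoded
#' feature vector treated as a single-channel signal, flattened into the
#' penultimate feature vector, then a linear head to two class logits.
#'
#' @param input_dim Length of the input feature vector (default 71).
#' @param channels Output channels of the three convolution stages
#'   (default 32, 64, 128).
#' @param kernel Convolution kernel width (default 3).
#' @param stride Convolution stride (default 2).
#' @param leaky_slope Leaky-ReLU negative slope (default 0.2).
#' @param feature_source Which activations the feature-matching loss uses:
#'   the flattened penultimate layer (default) or the logits.
#' @return An object of class `discriminator_spec`.
#' @export
discriminator_spec <- function(input_dim = 71L, channels = c(32L, 64L, 128L),
                               kernel = 3L, stride = 2L, leaky_slope = 0.2,
                               feature_source = c("penultimate", "logits")) {
  stopifnot(input_dim >= 1, length(channels) == 3L, all(channels >= 1),
            kernel >= 1, stride >= 1)
  structure(list(input_dim = as.integer(input_dim),
                 channels = as.integer(channels),
                 kernel = as.integer(kernel), stride = as.integer(stride),
                 leaky_slope = leaky_slope,
                 feature_source = match.arg(feature_source)),
            class = "discriminator_spec")
}

#' Initialize an SGAN model
#'
#' Draws initial weights from the caller's RNG stream (call `set.seed()`
#' first for reproducibility).
#'
#' @param generator A [generator_spec()].
#' @param discriminator A [discriminator_spec()].
#' @return An object of class `sgan_model` with components `generator` and
#'   `discriminator`.
#' @export
sgan_model <- function(generator = generator_spec(),
                       discriminator = discriminator_spec()) {
  stopifnot(inherits(generator, "generator_spec"),
            inherits(discriminator, "discriminator_spec"))
  structure(list(generator = init_generator(generator),
                 discriminator = init_discriminator(discriminator)),
            class = "sgan_model")
}

#' Generate synthetic feature vectors from noise
#'
#' @param model An `sgan_model` (or `sgan_fit`).
#' @param z Matrix of Gaussian noise, one row per sample, `noise_dim`
#'   columns.
#' @param training Logical; use batch statistics and dropout (training mode)
#'   or running statistics (evaluation mode, deterministic).
#' @return Matrix of generated samples in `[0, 1]`, one row per noise vector.
#' @export
generator_forward <- function(model, z, training = FALSE) {
  gen <- model$generator %||% stop_oncosgan("model has no generator")
  gen_forward(gen, z, training = training)$out
}

#' Discriminator forward pass
#'
#' @param model An `sgan_model` (or `sgan_fit`).
#' @param x Encoded feature matrix (rows are variants).
#' @param training Logical, kept for interface symmetry (the discriminator
#'   has no stochastic layers).
#' @return A list with `logits` (n x 2, columns benign/oncogenic) and
#'   `features` (the flattened penultimate activations).
#' @export
discriminator_forward <- function(model, x, training = FALSE) {
  fw <- disc_forward(model$discriminator, x, training = training)
  list(logits = fw$logits, features = fw$features)
}

#' Softmax class probabilities from the two logits
#'
#' `p_i = exp(l_i) / (exp(l_1) + exp(l_2))`, computed via log-sum-exp.
#'
#' @param logits Matrix with 2 columns (or a length-2 vector).
#' @return Matrix with columns `p_benign`, `p_oncogenic`, rows summing to 1.
#' @export
class_probabilities <- function(logits) {
  logits <- as_logit_matrix(logits)
  lp <- logits - lse2(logits)
  p <- exp(lp)
  colnames(p) <- c("p_benign", "p_oncogenic")
  p
}

as_logit_matrix <- function(logits) {
  if (is.null(dim(logits))) logits <- matrix(logits, ncol = 2L)
  if (ncol(logits) != 2L) stop_oncosgan("expected 2 logits per example")
  if (any(!is.finite(logits))) stop_oncosgan("logits must be finite")
  logits
}

#' Supervised cross-entropy loss
#'
#' Mean over the batch of `-log p_model(y_true | x)` under the softmax of
#' the two class logits.
#'
#' @param logits Matrix with 2 columns (benign, oncogenic).
#' @param labels Character vector in `c("benign", "oncogenic")` (or the
#'   integer class indices 1/2).
#' @return Scalar loss.
#' @export
supervised_loss <- function(logits, labels) {
  logits <- as_logit_matrix(logits)
  y <- label_index(labels)
  if (nrow(logits) == 0L) stop_oncosgan("empty batch")
  lp <- logits - lse2(logits)
  -mean(lp[cbind(seq_len(nrow(logits)), y)])
}

label_index <- function(labels) {
  if (is.numeric(labels)) {
    if (!all(labels %in% c(1, 2))) stop_oncosgan("class indices must be 1 or 2")
    return(as.integer(labels))
  }
  y <- match(as.character(labels), CLASSES)
  if (anyNA(y)) {
    stop_oncosgan("labels must be 'benign' or 'oncogenic' (no unlabeled examples)")
  }
  y
}

# Gradient of supervised_loss w.r.t. the logits: (softmax - onehot)/n.
supervised_loss_grad <- function(logits, y) {
  p <- exp(logits - lse2(logits))
  p[cbind(seq_len(nrow(logits)), y)] <- p[cbind(seq_len(nrow(logits)), y)] - 1
  p / nrow(logits)
}

#' Probability that an input is real rather than generated
#'
#' `D(x) = Z/(Z+1)` with `Z = exp(l1) + exp(l2)`, computed stably as
#' `exp(lse(l1, l2) - lse(l1, l2, 0))`.  Equals one minus the
#' synthetic-class probability of the 3-class softmax obtained by appending
#' a zero logit.
#'
#' @param logits Matrix with 2 columns (or a length-2 vector).
#' @return Vector of probabilities strictly inside `(0, 1)`.
#' @export
real_fake_probability <- function(logits) {
  logits <- as_logit_matrix(logits)
  exp(lse2(logits) - lse3(logits))
}

#' Unsupervised adversarial loss of the discriminator
#'
#' `-( mean log D(x_real) + mean log(1 - D(G(z))) )`, with
#' `log D = lse(l1,l2) - lse(l1,l2,0)` and `log(1-D) = -lse(l1,l2,0)`.
#'
#' @param real_logits Logit matrix of a real (unlabeled) batch.
#' @param fake_logits Logit matrix of a generated batch.
#' @return Scalar loss.
#' @export
unsupervised_loss <- function(real_logits, fake_logits) {
  real_logits <- as_logit_matrix(real_logits)
  fake_logits <- as_logit_matrix(fake_logits)
  if (nrow(real_logits) == 0L || nrow(fake_logits) == 0L) {
    stop_oncosgan("empty batch")
  }
  mean(lse3(real_logits) - lse2(real_logits)) + mean(lse3(fake_logits))
}

# Gradients of unsupervised_loss w.r.t. the two logit matrices.
unsupervised_loss_grads <- function(real_logits, fake_logits) {
  e3r <- exp(real_logits - lse3(real_logits))   # 3-class softmax, real
  p2r <- exp(real_logits - lse2(real_logits))
  e3f <- exp(fake_logits - lse3(fake_logits))
  list(real = (e3r - p2r) / nrow(real_logits),
       fake = e3f / nrow(fake_logits))
}

#' Total discriminator loss
#'
#' The unweighted sum of the supervised and unsupervised terms.
#'
#' @param sup Supervised loss value.
#' @param unsup Unsupervised loss value.
#' @return `sup + unsup`.
#' @export
discriminator_loss <- function(sup, unsup) sup + unsup

#' Feature-matching loss of the generator
#'
#' Squared Euclidean norm of the difference between the batch-mean
#' discriminator feature vectors of a real and a generated batch.  By
#' default the features are the penultimate-layer activations (following
#' the feature-matching formulation for GAN training); the logits can be
#' selected via the discriminator spec.
#'
#' @param real_features Feature matrix (or `discriminator_forward()` output)
#'   of a real batch.
#' @param fake_features Feature matrix (or forward output) of a generated
#'   batch.
#' @return Scalar loss, `>= 0`, zero iff the mean features coincide.
#' @export
feature_matching_loss <- function(real_features, fake_features) {
  fr <- extract_features(real_features)
  ff <- extract_features(fake_features)
  if (ncol(fr) != ncol(ff)) {
    stop_oncosgan("feature dimensionality mismatch: ", ncol(fr), " vs ", ncol(ff))
  }
  sum((colMeans(fr) - colMeans(ff))^2)
}

extract_features <- function(x) {
  if (is.list(x) && !is.null(x$features)) x <- x$features
  assert_matrix_like(x, "feature batch")
  if (nrow(x) == 0L) stop_oncosgan("empty batch")
  x
}
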