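# Alternating discriminator-then-generator optimization over labeled,
# unlabeled and synthetic minibatches.

#' Training configuration
#'
#' Defaults follow the reference training protocol: minibatches of 500
#' labeled, 500 unlabeled and 500 synthetic variants, Adam with initial
#' learning rate 0.0095, 2000 epochs (desk-scale runs use far fewer), and
#' class-rebalanced resampling of the labeled pool.  One epoch is one pass
#' of `ceiling(n_unlabeled / unlabeled_batch)` minibatch cycles.
#'
#' @param labeled_batch,unlabeled_batch,synthetic_batch Minibatch sizes.
#' @param learning_rate Adam initial learning rate.
#' @param beta1,beta2 Adam moment decay rates.
#' @param epochs Number of epochs.
#' @param rebalance Draw labeled minibatches with equal class probability
#'   (with replacement) to counter the oncogenic:benign imbalance.
#' @param seed Integer seed governing all training randomness.
#' @return An object of class `training_config`.
#' @export
training_config <- function(labeled_batch = 500L, unlabeled_batch = 500L,
                            synthetic_batch = 500L, learning_rate = 0.0095,
                            beta1 = 0.9, beta2 = 0.999, epochs = 2000L,
                            rebalance = TRUE, seed = 1L) {
  stopifnot(labeled_batch >= 1, unlabeled_batch >= 1, synthetic_batch >= 1,
            learning_rate > 0, epochs >= 0)
  structure(list(labeled_batch = as.integer(labeled_batch),
                 unlabeled_batch = as.integer(unlabeled_batch),
                 synthetic_batch = as.integer(synthetic_batch),
                 learning_rate = learning_rate, beta1 = beta1, beta2 = beta2,
                 epochs = as.integer(epochs), rebalance = isTRUE(rebalance),
                 seed = as.integer(seed)),
            class = "training_config")
}

#' Sample a labeled minibatch, optionally class-rebalanced
#'
#' With `rebalance`, each slot draws its class with probability 1/2 and then
#' a row uniformly (with replacement) within that class, giving an expected
#' 50/50 composition regardless of pool imbalance.  Without it, rows are
#' drawn uniformly from the pool.  Uses the caller's RNG stream.
#'
#' @param labels Character label vector of the labeled pool.
#' @param size Minibatch size.
#' @param rebalance Logical (default TRUE).
#' @param replace Logical; sampling with replacement for the non-rebalanced
#'   path (default TRUE).  Rebalanced draws always use replacement.
#' @return Integer vector of row indices into the pool.
#' @export
sample_labeled_minibatch <- function(labels, size, rebalance = TRUE,
                                     replace = TRUE) {
  y <- label_index(labels)
  if (rebalance) {
    idx_by_class <- split(seq_along(y), y)
    if (length(idx_by_class) < 2L) {
      stop_oncosgan("rebalanced sampling needs both classes in the labeled pool")
    }
    cls <- sample(2L, size, replace = TRUE)
    idx <- integer(size)
    for (cl in 1:2) {
      slots <- cls == cl
      pool <- idx_by_class[[as.character(cl)]]
      if (any(slots)) {
        idx[slots] <- pool[sample.int(length(pool), sum(slots), replace = TRUE)]
      }
    }
    idx
  } else {
    sample.int(length(y), size, replace = replace)
  }
}

# One optimizer update of the discriminator on a labeled batch, an unlabeled
# (real) batch and a generated batch.  Generator parameters are untouched.
#' Single discriminator update
#'
#' Minimizes the sum of the supervised cross-entropy (labeled batch) and the
#' unsupervised adversarial loss (unlabeled real batch vs generated batch);
#' one Adam step on discriminator parameters only.
#'
#' @param model An `sgan_model`.
#' @param opt Adam state for the discriminator (from internal init; managed
#'   by [sgan_train()]).
#' @param labeled_x,labeled_y Encoded labeled batch and its labels.
#' @param unlabeled_x Encoded unlabeled (real) batch.
#' @param fake_x Generated batch.
#' @param config A [training_config()].
#' @return List with updated `model`, `opt`, and the pre-update `sup`,
#'   `unsup` loss values.
#' @export
discriminator_step <- function(model, opt, labeled_x, labeled_y, unlabeled_x,
                               fake_x, config) {
  disc <- model$discriminator
  y <- label_index(labeled_y)
  spec <- disc$spec
  st <- disc_step_grads_cpp(labeled_x, y, unlabeled_x, fake_x,
                            disc$params$conv, disc$params$head$W,
                            disc$params$head$b, spec$kernel, spec$stride,
                            spec$leaky_slope)
  upd <- adam_update(disc$params, st$grads, opt, config$learning_rate,
                     config$beta1, config$beta2)
  model$discriminator$params <- upd$params
  list(model = model, opt = upd$state, sup = st$sup, unsup = st$unsup)
}

#' Single generator update
#'
#' Generates a fresh batch from `z`, and takes one Adam step on generator
#' parameters minimizing the feature-matching loss against the real batch.
#' Discriminator parameters are untouched.
#'
#' @param model An `sgan_model`.
#' @param opt Adam state for the generator.
#' @param real_x Encoded real (unlabeled) batch.
#' @param z Noise matrix for the synthetic batch.
#' @param config A [training_config()].
#' @return List with updated `model`, `opt`, and the feature-matching `loss`.
#' @export
generator_step <- function(model, opt, real_x, z, config) {
  gen <- model$generator
  disc <- model$discriminator
  gspec <- gen$spec
  dspec <- disc$spec
  st <- gen_step_grads_cpp(z, gen$params$layers, gen$bn_state,
                           gen$params$out$W, gen$params$out$b,
                           gspec$leaky_slope, gspec$dropout, real_x,
                           disc$params$conv, disc$params$head$W,
                           disc$params$head$b, dspec$kernel, dspec$stride,
                           dspec$leaky_slope,
                           dspec$feature_source == "logits")
  gen$bn_state <- st$bn_state
  upd <- adam_update(gen$params, st$grads, opt, config$learning_rate,
                     config$beta1, config$beta2)
  gen$params <- upd$params
  model$generator <- gen
  list(model = model, opt = upd$state, loss = st$loss)
}

add_grads <- function(a, b) {
  if (is.list(a)) Map(add_grads, a, b) else a + b
}

#' Train an SGAN on labeled and unlabeled encoded variants
#'
#' Runs `epochs` passes over the unlabeled pool; each minibatch cycle first
#' updates the discriminator (supervised + unsupervised loss) and then the
#' generator (feature matching), drawing fresh noise for each step and a
#' fresh class-rebalanced labeled minibatch.  Fully reproducible from
#' `config$seed`.
#'
#' @param labeled An `encoded_matrix` whose labels are all
#'   benign/oncogenic, or a plain matrix (then supply `labels`).
#' @param unlabeled An `encoded_matrix` (labels ignored) or a plain matrix.
#' @param config A [training_config()].
#' @param generator A [generator_spec()]; `output_dim` is aligned to the
#'   data automatically.
#' @param discriminator A [discriminator_spec()]; `input_dim` is aligned to
#'   the data automatically.
#' @param labels Labels for `labeled` when it is a plain matrix.
#' @param validation Optional `encoded_matrix` with labels; when supplied,
#'   MCC and ROC-AUC on it are logged every `eval_every` epochs.
#' @param eval_every Epoch interval for validation logging (0 = never).
#' @param verbose Print per-epoch loss lines.
#' @return An object of class `sgan_fit`: the trained model plus `history`
#'   (one row per epoch: mean supervised, unsupervised and generator loss),
#'   the column manifest, specs and config.
#' @export
sgan_train <- function(labeled, unlabeled, config = training_config(),
                       generator = generator_spec(),
                       discriminator = discriminator_spec(),
                       labels = NULL, validation = NULL, eval_every = 0L,
                       verbose = FALSE) {
  lab <- as_encoded(labeled, labels)
  unl <- as_encoded(unlabeled)
  if (ncol(lab$matrix) != ncol(unl$matrix)) {
    stop_oncosgan("labeled and unlabeled matrices have different widths")
  }
  if (!is.null(lab$manifest) && !is.null(unl$manifest) &&
      !identical(lab$manifest$column, unl$manifest$column)) {
    stop_oncosgan("labeled and unlabeled tables do not share a column manifest")
  }
  y <- label_index(lab$labels)
  if (length(unique(y)) < 2L && config$rebalance) {
    stop_oncosgan("labeled pool must contain both classes")
  }
  generator$output_dim <- ncol(lab$matrix)
  discriminator$input_dim <- ncol(lab$matrix)

  set.seed(config$seed)
  model <- sgan_model(generator, discriminator)
  opt_d <- adam_init(model$discriminator$params)
  opt_g <- adam_init(model$generator$params)

  n_unl <- nrow(unl$matrix)
  steps <- max(1L, ceiling(n_unl / config$unlabeled_batch))
  history <- data.frame(epoch = integer(0), supervised = numeric(0),
                        unsupervised = numeric(0), generator = numeric(0),
                        val_mcc = numeric(0), val_roc_auc = numeric(0))
  for (ep in seq_len(config$epochs)) {
    perm <- sample.int(n_unl)
    sup_acc <- unsup_acc <- gen_acc <- 0
    for (s in seq_len(steps)) {
      lo <- (s - 1L) * config$unlabeled_batch + 1L
      hi <- min(s * config$unlabeled_batch, n_unl)
      u_idx <- perm[lo:hi]
      l_idx <- sample_labeled_minibatch(lab$labels, config$labeled_batch,
                                        rebalance = config$rebalance)
      z_d <- matrix(rnorm(config$synthetic_batch * generator$noise_dim),
                    config$synthetic_batch)
      fake <- gen_sample(model$generator, z_d, training = TRUE)
      model$generator <- fake$gen
      dstep <- discriminator_step(model, opt_d,
                                  lab$matrix[l_idx, , drop = FALSE],
                                  y[l_idx],
                                  unl$matrix[u_idx, , drop = FALSE],
                                  fake$out, config)
      model <- dstep$model
      opt_d <- dstep$opt
      z_g <- matrix(rnorm(config$synthetic_batch * generator$noise_dim),
                    config$synthetic_batch)
      gstep <- generator_step(model, opt_g,
                              unl$matrix[u_idx, , drop = FALSE], z_g, config)
      model <- gstep$model
      opt_g <- gstep$opt
      sup_acc <- sup_acc + dstep$sup
      unsup_acc <- unsup_acc + dstep$unsup
      gen_acc <- gen_acc + gstep$loss
    }
    row <- data.frame(epoch = ep, supervised = sup_acc / steps,
                      unsupervised = unsup_acc / steps,
                      generator = gen_acc / steps,
                      val_mcc = NA_real_, val_roc_auc = NA_real_)
    if (!is.null(validation) && eval_every > 0L && ep %% eval_every == 0L) {
      fit_tmp <- as_sgan_fit(model, lab$manifest, config)
      sc <- interpretation_scores(fit_tmp, validation)
      truth <- validation$labels
      rep_m <- suppressWarnings(
        binary_metrics(confusion_counts(classify_variants(sc), truth)))
      row$val_mcc <- rep_m$mcc
      row$val_roc_auc <- roc_auc(sc, truth)
    }
    history <- rbind(history, row)
    if (verbose) {
      message(sprintf("epoch %d  sup %.4f  unsup %.4f  gen %.4f",
                      ep, row$supervised, row$unsupervised, row$generator))
    }
  }
  fit <- as_sgan_fit(model, lab$manifest, config)
  fit$history <- history
  fit
}

as_sgan_fit <- function(model, manifest, config, mode = "sgan") {
  structure(list(generator = model$generator,
                 discriminator = model$discriminator,
                 manifest = manifest, config = config, classes = CLASSES,
                 mode = mode, history = NULL),
            class = "sgan_fit")
}

as_encoded <- function(x, labels = NULL) {
  if (inherits(x, "encoded_matrix")) return(x)
  assert_matrix_like(x, "encoded input")
  list(matrix = x, manifest = NULL,
       labels = labels %||% rep("unlabeled", nrow(x)))
}

#' Train the supervised-only baseline
#'
#' Trains the same discriminator architecture with the supervised
#' cross-entropy loss alone -- no generator, no unlabeled data -- as the
#' matched baseline for quantifying the semi-supervision benefit.  The
#' optimizer schedule mirrors [sgan_train()]: `steps_per_epoch` minibatch
#' updates per epoch with rebalanced labeled sampling.
#'
#' @param labeled An `encoded_matrix` (or matrix plus `labels`).
#' @param config A [training_config()].
#' @param discriminator A [discriminator_spec()].
#' @param labels Labels when `labeled` is a plain matrix.
#' @param steps_per_epoch Minibatch updates per epoch; defaults to
#'   `ceiling(nrow(labeled) / labeled_batch)`; pass the SGAN's step count
#'   for an update-matched comparison.
#' @return An `sgan_fit` with `mode = "supervised"` and no generator.
#' @export
supervised_train <- function(labeled, config = training_config(),
                             discriminator = discriminator_spec(),
                             labels = NULL, steps_per_epoch = NULL) {
  lab <- as_encoded(labeled, labels)
  y <- label_index(lab$labels)
  if (length(unique(y)) < 2L && config$rebalance) {
    stop_oncosgan("labeled pool must contain both classes")
  }
  discriminator$input_dim <- ncol(lab$matrix)
  steps <- as.integer(steps_per_epoch %||%
                        ceiling(nrow(lab$matrix) / config$labeled_batch))
  set.seed(config$seed)
  disc <- init_discriminator(discriminator)
  opt <- adam_init(disc$params)
  history <- data.frame(epoch = integer(0), supervised = numeric(0))
  for (ep in seq_len(config$epochs)) {
    acc <- 0
    for (s in seq_len(steps)) {
      l_idx <- sample_labeled_minibatch(lab$labels, config$labeled_batch,
                                        rebalance = config$rebalance)
      yy <- y[l_idx]
      st <- disc_sup_grads_cpp(lab$matrix[l_idx, , drop = FALSE], yy,
                               disc$params$conv, disc$params$head$W,
                               disc$params$head$b, discriminator$kernel,
                               discriminator$stride,
                               discriminator$leaky_slope)
      loss <- st$sup
      upd <- adam_update(disc$params, st$grads, opt, config$learning_rate,
                         config$beta1, config$beta2)
      disc$params <- upd$params
      opt <- upd$state
      acc <- acc + loss
    }
    history <- rbind(history, data.frame(epoch = ep, supervised = acc / steps))
  }
  fit <- as_sgan_fit(list(generator = NULL, discriminator = disc),
                     lab$manifest, config, mode = "supervised")
  fit$history <- history
  fit
}

#' @export
print.sgan_fit <- function(x, ...) {
  cat("<sgan_fit> mode:", x$mode, "\n")
  if (!is.null(x$discriminator)) {
    cat("discriminator: conv channels",
        paste(x$discriminator$spec$channels, collapse = "/"),
        "on input_dim", x$discriminator$spec$input_dim, "\n")
  }
  if (!is.null(x$generator)) {
    cat("generator: hidden", paste(x$generator$spec$hidden, collapse = "/"),
        "noise_dim", x$generator$spec$noise_dim, "\n")
  }
  cat("epochs trained:", if (is.null(x$history)) 0L else nrow(x$history), "\n")
  invisible(x)
}
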