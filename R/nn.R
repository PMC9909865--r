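# Neural-network machinery: parameter initialization and Adam live in R;
# the forward/backward passes of both networks are compiled (src/), with
# layouts shared between the two sides.  Parameters are nested lists of
# numeric arrays; gradients mirror the structure.  All randomness (weight
# init, dropout masks) is drawn from the caller's R RNG stream.

glorot_mat <- function(fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(runif(fan_in * fan_out, -lim, lim), fan_in, fan_out)
}

# ---- generator: stack of [linear -> batchnorm -> leaky ReLU -> dropout],
# output layer linear -> tanh -> affine map into [0, 1] ------------------

init_generator <- function(spec) {
  dims <- c(spec$noise_dim, spec$hidden)
  layers <- lapply(seq_along(spec$hidden), function(i) {
    list(W = glorot_mat(dims[i], dims[i + 1L]), b = numeric(dims[i + 1L]),
         gamma = rep(1, dims[i + 1L]), beta = numeric(dims[i + 1L]))
  })
  params <- list(layers = layers,
                 out = list(W = glorot_mat(dims[length(dims)], spec$output_dim),
                            b = numeric(spec$output_dim)))
  bn_state <- lapply(spec$hidden, function(h) {
    list(mean = numeric(h), var = rep(1, h))
  })
  list(spec = spec, params = params, bn_state = bn_state)
}

gen_forward <- function(gen, Z, training = TRUE) {
  spec <- gen$spec
  if (!is.matrix(Z)) Z <- matrix(Z, ncol = spec$noise_dim)
  if (ncol(Z) != spec$noise_dim) {
    stop_oncosgan("noise dimension ", ncol(Z), " does not match noise_dim ",
                  spec$noise_dim)
  }
  fw <- gen_fwd_cpp(Z, gen$params$layers, gen$bn_state, gen$params$out$W,
                    gen$params$out$b, spec$leaky_slope, training,
                    spec$dropout)
  if (training) gen$bn_state <- fw$bn_state
  list(out = fw$out, gen = gen,
       cache = list(caches = fw$caches, H_last = fw$H_last,
                    t_out = fw$t_out))
}

gen_backward <- function(gen, cache, dOut) {
  gen_bwd_cpp(gen$params$layers, gen$params$out$W, cache$caches,
              cache$H_last, cache$t_out, dOut)
}

# ---- discriminator: three 1-d convolution stages (valid padding, leaky
# ReLU) over the encoded feature vector as a single-channel signal, then a
# linear head from the flattened (penultimate) features to the two logits ---

conv_out_len <- function(len, kernel, stride) (len - kernel) %/% stride + 1L

init_discriminator <- function(spec) {
  chans <- c(1L, spec$channels)
  len <- spec$input_dim
  conv <- vector("list", length(spec$channels))
  for (i in seq_along(spec$channels)) {
    conv[[i]] <- list(K = glorot_mat(spec$kernel * chans[i], chans[i + 1L]),
                      b = numeric(chans[i + 1L]))
    len <- conv_out_len(len, spec$kernel, spec$stride)
    if (len < 1L) {
      stop_oncosgan("input_dim ", spec$input_dim,
                    " is too short for the convolution stack")
    }
  }
  feat_dim <- len * chans[length(chans)]
  params <- list(conv = conv,
                 head = list(W = glorot_mat(feat_dim, 2L), b = numeric(2L)))
  list(spec = spec, params = params, feat_dim = feat_dim, final_len = len)
}

disc_forward <- function(disc, X, training = TRUE, want_caches = TRUE) {
  spec <- disc$spec
  if (!is.matrix(X)) X <- matrix(X, ncol = spec$input_dim)
  if (ncol(X) != spec$input_dim) {
    stop_oncosgan("input has ", ncol(X), " columns but the discriminator expects ",
                  spec$input_dim)
  }
  fw <- disc_fwd_cpp(X, disc$params$conv, disc$params$head$W,
                     disc$params$head$b, spec$kernel, spec$stride,
                     spec$leaky_slope, want_caches)
  list(logits = fw$logits, features = fw$features,
       cache = list(caches = fw$caches, features = fw$features,
                    logits = fw$logits))
}

disc_backward <- function(disc, cache, dlogits = NULL, dfeatures = NULL,
                          need_input_grad = FALSE) {
  spec <- disc$spec
  disc_bwd_cpp(disc$params$conv, disc$params$head$W, cache$caches,
               cache$features, cache$logits, dlogits, dfeatures,
               spec$kernel, spec$stride, spec$leaky_slope, need_input_grad)
}

# Cheap generator sampling path (no caches cross the boundary); updates the
# batch-norm running statistics when training.
gen_sample <- function(gen, Z, training = TRUE) {
  spec <- gen$spec
  fw <- gen_sample_cpp(Z, gen$params$layers, gen$bn_state, gen$params$out$W,
                       gen$params$out$b, spec$leaky_slope, training,
                       spec$dropout)
  if (training) gen$bn_state <- fw$bn_state
  list(out = fw$out, gen = gen)
}

# ---- Adam over nested parameter lists -----------------------------------

adam_init <- function(params) {
  zero <- function(p) if (is.list(p)) lapply(p, zero) else p * 0
  list(m = zero(params), v = zero(params), t = 0L)
}

adam_update <- function(params, grads, state, lr,
                        beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  rec <- function(p, g, m, v) {
    if (is.list(p)) {
      out <- Map(rec, p, g, m, v)
      list(p = lapply(out, `[[`, "p"),
           m = lapply(out, `[[`, "m"),
           v = lapply(out, `[[`, "v"))
    } else {
      m <- beta1 * m + (1 - beta1) * g
      v <- beta2 * v + (1 - beta2) * g^2
      p_new <- p - lr * (m / c1) / (sqrt(v / c2) + eps)
      attributes(p_new) <- attributes(p)
      list(p = p_new, m = m, v = v)
    }
  }
  res <- rec(params, grads, state$m, state$v)
  list(params = res$p, state = list(m = res$m, v = res$v, t = state$t))
}
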