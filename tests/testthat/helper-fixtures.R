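# Shared fixture builders: everything is generated in code at test time.

evi_names <- sprintf("evi_%02d", 1:12)
score_names <- sprintf("score_%02d", 1:23)

# A small raw feature table with controllable missingness.
make_toy_table <- function(n = 20L, seed = 1L, missing_rate = 0,
                           labels = NULL) {
  withr::with_seed(seed, {
    ev <- matrix(sample(c(-1, 0, 1, 2), n * 12, replace = TRUE), n,
                 dimnames = list(NULL, evi_names))
    sc <- matrix(rnorm(n * 23), n, dimnames = list(NULL, score_names))
    df <- data.frame(variant_id = sprintf("v%04d", seq_len(n)),
                     label = labels %||%
                       sample(c("oncogenic", "benign"), n, replace = TRUE),
                     ev, sc, check.names = FALSE, stringsAsFactors = FALSE)
    tab <- raw_feature_table(df)
    if (missing_rate > 0) tab <- inject_missingness(tab, missing_rate)
    tab
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Tiny network specs for fast training tests.
tiny_gspec <- function(d) generator_spec(noise_dim = 8L, hidden = c(8L, 8L, 8L),
                                         output_dim = d)
tiny_dspec <- function(d) discriminator_spec(input_dim = d,
                                             channels = c(2L, 4L, 4L))

quick_config <- function(epochs = 2L, seed = 1L, ...) {
  training_config(labeled_batch = 64L, unlabeled_batch = 64L,
                  synthetic_batch = 64L, epochs = epochs, seed = seed, ...)
}

# A linearly separable encoded toy problem: two Gaussian blobs.
make_blobs <- function(n_per_class = 60L, d = 20L, sep = 6, seed = 1L) {
  withr::with_seed(seed, {
    x <- rbind(matrix(rnorm(n_per_class * d), n_per_class),
               matrix(rnorm(n_per_class * d, mean = sep / sqrt(d)),
                      n_per_class))
    x <- (x - min(x)) / (max(x) - min(x))
    list(x = x,
         y = rep(c("benign", "oncogenic"), each = n_per_class))
  })
}

# Independent brute-force k-NN mean imputation oracle (per-entry loops,
# shares no code with the implementation).
oracle_impute <- function(X, k) {
  p <- ncol(X)
  out <- X
  for (i in seq_len(nrow(X))) {
    miss <- which(is.na(X[i, ]))
    if (!length(miss)) next
    d <- rep(Inf, nrow(X))
    for (j in seq_len(nrow(X))) {
      shared <- which(!is.na(X[i, ]) & !is.na(X[j, ]))
      if (length(shared)) {
        d[j] <- sqrt(p / length(shared) * sum((X[i, shared] - X[j, shared])^2))
      }
    }
    for (cc in miss) {
      donors <- which(!is.na(X[, cc]) & is.finite(d))
      donors <- donors[order(d[donors], donors)]
      take <- donors[seq_len(min(k, length(donors)))]
      out[i, cc] <- mean(X[take, cc])
    }
  }
  out
}
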