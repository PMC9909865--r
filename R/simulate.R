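# Synthetic per-variant feature tables with the statistical structure the
# method assumes: a 23-dimensional score block drawn from per-class Gaussian
# mixtures (several clusters per class), a 12-column discrete evidence block
# drawn from class-conditional categorical profiles over {-1,0,1,2},
# completely-at-random missingness, and a large unlabeled pool sharing the
# mixture with the labeled classes.

#' Synthetic dataset configuration
#'
#' Defaults emulate the reference study conditions: a labeled training pool
#' of 1669 oncogenic and 4829 benign variants (about 1:3 imbalance), a test
#' set of 1335 oncogenic and 4829 benign variants, and an unlabeled pool of
#' 10,000 variants (desk scale; the full-scale 60,000 is config-reachable).
#' Each class is a mixture of `n_clusters_per_class` Gaussian clusters in
#' the 23-dimensional score space.  The cluster geometry is shared between
#' the classes: base centres scatter with sd `cluster_spread`, and the two
#' classes see each centre shifted by `+/- class_separation / 2` along a
#' fixed direction (spread evenly over the score dimensions), so every
#' cluster straddles the class boundary and the classes overlap by
#' construction.  Points scatter within a cluster with sd `within_sd`.
#' Evidence columns are drawn i.i.d. from the class row of
#' `evidence_profile`.
#'
#' @param n_labeled_oncogenic,n_labeled_benign Labeled training pool sizes.
#' @param n_unlabeled Unlabeled pool size.
#' @param n_test_oncogenic,n_test_benign Held-out test set sizes.
#' @param n_clusters_per_class Gaussian clusters per class (default 3).
#' @param class_separation Distance between class mean vectors (default 2).
#' @param cluster_spread Sd of cluster centres around the class mean
#'   (default 1.5).
#' @param within_sd Within-cluster sd (default 1).
#' @param evidence_profile 2 x 4 matrix of per-class probabilities over the
#'   evidence levels (-1, 0, 1, 2); rows `oncogenic`, `benign`, each summing
#'   to 1.
#' @param missing_rate Probability that a raw feature entry is masked
#'   (default 0.05), in `[0, 1)`.
#' @param seed Integer seed; the whole dataset is a deterministic function
#'   of the config.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_labeled_oncogenic = 1669L,
                             n_labeled_benign = 4829L,
                             n_unlabeled = 10000L,
                             n_test_oncogenic = 1335L,
                             n_test_benign = 4829L,
                             n_clusters_per_class = 3L,
                             class_separation = 1.2,
                             cluster_spread = 1.5,
                             within_sd = 1,
                             evidence_profile = default_evidence_profile(),
                             missing_rate = 0.05,
                             seed = 1L) {
  stopifnot(n_labeled_oncogenic >= 0, n_labeled_benign >= 0,
            n_unlabeled >= 0, n_test_oncogenic >= 0, n_test_benign >= 0,
            n_clusters_per_class >= 1, class_separation >= 0,
            cluster_spread >= 0, within_sd >= 0,
            missing_rate >= 0, missing_rate < 1)
  evidence_profile <- validate_profile(evidence_profile)
  structure(list(n_labeled_oncogenic = as.integer(n_labeled_oncogenic),
                 n_labeled_benign = as.integer(n_labeled_benign),
                 n_unlabeled = as.integer(n_unlabeled),
                 n_test_oncogenic = as.integer(n_test_oncogenic),
                 n_test_benign = as.integer(n_test_benign),
                 n_clusters_per_class = as.integer(n_clusters_per_class),
                 class_separation = class_separation,
                 cluster_spread = cluster_spread, within_sd = within_sd,
                 evidence_profile = evidence_profile,
                 missing_rate = missing_rate, seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Default class-conditional evidence-level profiles
#'
#' Oncogenic variants skew toward supporting/strong evidence (levels 1 and
#' 2), benign variants toward benign/no-support (levels -1 and 0), with
#' substantial overlap so the classes are informative but not separable
#' from evidence alone.
#'
#' @return A 2 x 4 probability matrix (rows `oncogenic`, `benign`; columns
#'   the levels -1, 0, 1, 2).
#' @export
default_evidence_profile <- function() {
  matrix(c(0.20, 0.32, 0.30, 0.18,
           0.28, 0.36, 0.24, 0.12),
         nrow = 2L, byrow = TRUE,
         dimnames = list(c("oncogenic", "benign"),
                         as.character(EVIDENCE_LEVELS)))
}

validate_profile <- function(p) {
  p <- as.matrix(p)
  if (!all(dim(p) == c(2L, 4L))) stop_oncosgan("evidence_profile must be 2 x 4")
  if (any(p < 0)) stop_oncosgan("evidence_profile has negative probabilities")
  if (any(rowSums(p) == 0)) {
    stop_oncosgan("degenerate evidence_profile: a row is all zero")
  }
  if (any(abs(rowSums(p) - 1) > 1e-8)) {
    stop_oncosgan("evidence_profile rows must sum to 1")
  }
  rownames(p) <- c("oncogenic", "benign")
  p
}

#' Generate a synthetic labeled/unlabeled/test dataset
#'
#' Draws cluster centres, then the labeled pool, the unlabeled pool (class
#' mixture proportions matching the labeled pool, true classes recorded in
#' `ground_truth` for auditing only) and the held-out test table, and
#' finally masks raw feature entries at `missing_rate`.  Deterministic
#' given `config$seed`.
#'
#' @param config A [synthetic_config()].
#' @return An object of class `sgan_dataset`: `labeled`, `unlabeled`,
#'   `test` (each a `raw_feature_table`), `ground_truth` (hidden labels of
#'   the unlabeled rows) and `config`.
#' @export
generate_dataset <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  # Shared cluster geometry, class-shifted centres: every cluster straddles
  # the class boundary, so the classes are overlapping mixtures whose
  # separation is governed by class_separation alone (class-pure, widely
  # separated clusters would make cluster identity a perfect label
  # predictor and the labeled-data-limited regime unreachable).
  dir_shift <- rep(1 / sqrt(N_SCORES), N_SCORES) * config$class_separation / 2
  base <- matrix(rnorm(config$n_clusters_per_class * N_SCORES,
                       sd = config$cluster_spread),
                 config$n_clusters_per_class)
  centers <- list(
    oncogenic = base + rep(dir_shift, each = config$n_clusters_per_class),
    benign = base - rep(dir_shift, each = config$n_clusters_per_class))

  draw_rows <- function(n, class) {
    cl <- sample.int(config$n_clusters_per_class, n, replace = TRUE)
    scores <- centers[[class]][cl, , drop = FALSE] +
      matrix(rnorm(n * N_SCORES, sd = config$within_sd), n)
    ev <- matrix(sample(EVIDENCE_LEVELS, n * N_EVIDENCE, replace = TRUE,
                        prob = config$evidence_profile[class, ]),
                 n, N_EVIDENCE)
    list(scores = scores, evidence = ev)
  }

  build_table <- function(n_onco, n_ben, prefix, shuffle = FALSE) {
    onco <- draw_rows(n_onco, "oncogenic")
    ben <- draw_rows(n_ben, "benign")
    scores <- rbind(onco$scores, ben$scores)
    ev <- rbind(onco$evidence, ben$evidence)
    truth <- c(rep("oncogenic", n_onco), rep("benign", n_ben))
    if (shuffle) {
      perm <- sample.int(length(truth))
      scores <- scores[perm, , drop = FALSE]
      ev <- ev[perm, , drop = FALSE]
      truth <- truth[perm]
    }
    colnames(ev) <- sprintf("evi_%02d", seq_len(N_EVIDENCE))
    colnames(scores) <- sprintf("score_%02d", seq_len(N_SCORES))
    df <- data.frame(variant_id = sprintf("%s%06d", prefix, seq_along(truth)),
                     label = truth, ev, scores, check.names = FALSE,
                     stringsAsFactors = FALSE)
    list(table = df, truth = truth)
  }

  lab <- build_table(config$n_labeled_oncogenic, config$n_labeled_benign, "L")
  p_onco <- if (config$n_labeled_oncogenic + config$n_labeled_benign > 0) {
    config$n_labeled_oncogenic /
      (config$n_labeled_oncogenic + config$n_labeled_benign)
  } else 0.5
  n_unl_onco <- sum(runif(config$n_unlabeled) < p_onco)
  unl <- build_table(n_unl_onco, config$n_unlabeled - n_unl_onco, "U",
                     shuffle = TRUE)
  tst <- build_table(config$n_test_oncogenic, config$n_test_benign, "T")

  unl$table$label <- "unlabeled"
  labeled <- raw_feature_table(lab$table)
  unlabeled <- raw_feature_table(unl$table)
  test <- raw_feature_table(tst$table)
  if (config$missing_rate > 0) {
    labeled <- inject_missingness(labeled, config$missing_rate)
    unlabeled <- inject_missingness(unlabeled, config$missing_rate)
    test <- inject_missingness(test, config$missing_rate)
  }
  structure(list(labeled = labeled, unlabeled = unlabeled, test = test,
                 ground_truth = unl$truth, config = config),
            class = "sgan_dataset")
}

#' Mask raw feature entries completely at random
#'
#' Each of the 35 raw feature entries is masked independently with
#' probability `rate`; the label column is never masked.
#'
#' @param table A `raw_feature_table`.
#' @param rate Masking probability in `[0, 1)`.
#' @param seed Optional seed; by default the caller's RNG stream is used.
#' @return The table with masked entries set to `NA`.
#' @export
inject_missingness <- function(table, rate, seed = NULL) {
  stopifnot(rate >= 0, rate < 1)
  if (rate == 0) return(table)
  run <- function() {
    df <- as.data.frame(table)
    cols <- feature_columns(df)
    all_cols <- c(cols$evidence, cols$scores)
    mask <- matrix(runif(nrow(df) * length(all_cols)) < rate, nrow(df))
    for (j in seq_along(all_cols)) {
      df[[all_cols[j]]][mask[, j]] <- NA
    }
    class(df) <- c("raw_feature_table", "data.frame")
    df
  }
  if (is.null(seed)) run() else local_seed(seed, run())
}

#' Audit model recovery on a synthetic dataset
#'
#' Scores the held-out test table and, using the hidden ground truth kept by
#' the generator, the unlabeled pool, reporting the eight-metric panel on
#' the test set and the unlabeled-pool ROC-AUC.  Deterministic given model
#' and dataset.
#'
#' @param fit A trained `sgan_fit`.
#' @param dataset An `sgan_dataset`.
#' @param prep The fitted [fit_preprocessor()] state used for training.
#' @param cutoff Decision threshold for the test-set panel.
#' @return A list with `test_report` (one-row data.frame) and
#'   `unlabeled_roc_auc`.
#' @export
audit_recovery <- function(fit, dataset, prep, cutoff = 0.5) {
  stopifnot(inherits(dataset, "sgan_dataset"))
  enc_test <- preprocess_table(filter_by_missingness(dataset$test), prep)
  test_scores <- interpretation_scores(fit, enc_test)
  report <- metric_report(test_scores, enc_test$labels, cutoff)
  enc_unl <- preprocess_table(filter_by_missingness(dataset$unlabeled), prep)
  keep <- match(enc_unl$variant_id, dataset$unlabeled$variant_id)
  unl_scores <- interpretation_scores(fit, enc_unl)
  list(test_report = report,
       unlabeled_roc_auc = roc_auc(unl_scores, dataset$ground_truth[keep]))
}
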