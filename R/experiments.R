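# Scripted experiments on synthetic data: label-budget sweeps,
# feature-group ablations, the supervised-only comparison, score
# histograms and a 2-D embedding plot.

# Desk-scale network sizes used by the experiment drivers: small enough for
# repeated single-CPU training runs, large enough to fit the reference
# synthetic mixtures.  Paper-scale sizes remain the spec constructors'
# defaults and can be passed explicitly.
experiment_generator_spec <- function(output_dim) {
  generator_spec(noise_dim = 16L, hidden = c(16L, 16L, 16L),
                 output_dim = output_dim)
}

experiment_discriminator_spec <- function(input_dim) {
  discriminator_spec(input_dim = input_dim, channels = c(4L, 4L, 8L))
}

#' Preprocess a synthetic dataset for training and evaluation
#'
#' Filters each table by missingness, fits the imputer and min-max scaler on
#' the union of labeled and unlabeled training rows only, and encodes all
#' three tables.
#'
#' @param dataset An `sgan_dataset`.
#' @param k Imputation neighbour count.
#' @param noise_sd Evidence dither sd.
#' @param seed Dither seed.
#' @param max_missing Missingness filter threshold.
#' @return A list of class `sgan_encoded_dataset` with `prep` and encoded
#'   `labeled`, `unlabeled`, `test`.
#' @export
preprocess_dataset <- function(dataset, k = 40L, noise_sd = 0.02, seed = 1L,
                               max_missing = 13L) {
  stopifnot(inherits(dataset, "sgan_dataset"))
  lab <- filter_by_missingness(dataset$labeled, max_missing)
  unl <- filter_by_missingness(dataset$unlabeled, max_missing)
  tst <- filter_by_missingness(dataset$test, max_missing)
  train_table <- rbind(as.data.frame(lab), as.data.frame(unl))
  class(train_table) <- c("raw_feature_table", "data.frame")
  prep <- fit_preprocessor(train_table, k = k, noise_sd = noise_sd,
                           seed = seed)
  structure(list(prep = prep,
                 labeled = preprocess_table(lab, prep),
                 unlabeled = preprocess_table(unl, prep),
                 test = preprocess_table(tst, prep)),
            class = "sgan_encoded_dataset")
}

# Draw a class-stratified label budget from the encoded labeled pool.
draw_budget <- function(labels, budget) {
  y <- label_index(labels)
  if (budget > length(y)) {
    stop_oncosgan("label budget ", budget, " exceeds the labeled pool (",
                  length(y), ")")
  }
  n_onco <- round(budget * mean(y == 2L))
  n_onco <- max(1L, min(n_onco, sum(y == 2L), budget - 1L))
  pos <- which(y == 2L)
  neg <- which(y == 1L)
  c(pos[sample.int(length(pos), n_onco)],
    neg[sample.int(length(neg), budget - n_onco)])
}

subset_encoded <- function(enc, idx) {
  encoded_matrix(enc$matrix[idx, , drop = FALSE], enc$manifest,
                 enc$labels[idx],
                 variant_id = enc$variant_id[idx])
}

# Train one model (SGAN or supervised-only) at a budget and evaluate it on
# the encoded test set.
train_and_eval <- function(encoded, budget, seed, epochs, method = "sgan",
                           cutoff = 0.5, config = NULL) {
  set.seed(seed)
  idx <- draw_budget(encoded$labeled$labels, budget)
  lab_sub <- subset_encoded(encoded$labeled, idx)
  cfg <- config %||% training_config(epochs = epochs, seed = seed)
  cfg$epochs <- as.integer(epochs)
  cfg$seed <- as.integer(seed)
  d <- ncol(encoded$labeled$matrix)
  steps <- max(1L, ceiling(nrow(encoded$unlabeled$matrix) / cfg$unlabeled_batch))
  fit <- if (method == "sgan") {
    sgan_train(lab_sub, encoded$unlabeled, cfg,
               generator = experiment_generator_spec(d),
               discriminator = experiment_discriminator_spec(d))
  } else if (method == "supervised") {
    supervised_train(lab_sub, cfg,
                     discriminator = experiment_discriminator_spec(d),
                     steps_per_epoch = steps)
  } else {
    stop_oncosgan("unknown method: ", method)
  }
  scores <- interpretation_scores(fit, encoded$test)
  report <- suppressWarnings(metric_report(scores, encoded$test$labels, cutoff))
  list(fit = fit, scores = scores, label_indices = idx,
       row = cbind(data.frame(method = method, budget = budget, seed = seed),
                   report))
}

#' Label-budget sweep
#'
#' Trains one SGAN per (budget, seed) combination on the encoded dataset
#' and evaluates the eight-metric panel on the held-out test table,
#' emulating the experimental design of varying the number of labeled
#' variants available to supervised training.
#'
#' @param dataset An `sgan_dataset` or a preprocessed
#'   `sgan_encoded_dataset`.
#' @param budgets Label budgets (default 250, 500, 1000, 2000, 4000).
#' @param seeds One training seed per replicate (default 1:5).
#' @param epochs Training epochs per run (default 200, desk scale).
#' @param cutoff Decision threshold for the panel.
#' @return A data.frame of class `sweep_result`: one row per
#'   (budget, seed) with the metric panel.
#' @export
label_budget_sweep <- function(dataset,
                               budgets = c(250L, 500L, 1000L, 2000L, 4000L),
                               seeds = 1:5, epochs = 200L, cutoff = 0.5) {
  encoded <- ensure_encoded_dataset(dataset)
  rows <- list()
  for (budget in budgets) {
    for (seed in seeds) {
      res <- train_and_eval(encoded, budget, seed, epochs, "sgan", cutoff)
      res$row$feature_group <- "ensemble"
      rows[[length(rows) + 1L]] <- res$row
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("sweep_result", "data.frame")
  out
}

ensure_encoded_dataset <- function(dataset, ...) {
  if (inherits(dataset, "sgan_encoded_dataset")) return(dataset)
  preprocess_dataset(dataset, ...)
}

#' Feature-group ablation
#'
#' Trains and evaluates one model per feature group: the 23 scaled
#' deleteriousness scores (`scores_only`), the 48 dithered one-hot evidence
#' columns (`evidence_only`), or the full 71-column ensemble (`ensemble`).
#'
#' @param dataset An `sgan_dataset` or `sgan_encoded_dataset`.
#' @param groups Character subset of
#'   `c("scores_only", "evidence_only", "ensemble")`.
#' @param budget Label budget per run.
#' @param seeds Training seeds.
#' @param epochs Training epochs per run.
#' @param cutoff Decision threshold.
#' @return A `sweep_result` data.frame, one row per (group, seed).
#' @export
feature_group_ablation <- function(dataset,
                                   groups = c("scores_only", "evidence_only",
                                              "ensemble"),
                                   budget = 1000L, seeds = 1:3,
                                   epochs = 200L, cutoff = 0.5) {
  encoded <- ensure_encoded_dataset(dataset)
  known <- c("scores_only", "evidence_only", "ensemble")
  bad <- setdiff(groups, known)
  if (length(bad)) stop_oncosgan("unknown feature group(s): ",
                                 paste(bad, collapse = ", "))
  rows <- list()
  for (group in groups) {
    enc_g <- subset_feature_group(encoded, group)
    for (seed in seeds) {
      res <- train_and_eval(enc_g, budget, seed, epochs, "sgan", cutoff)
      res$row$feature_group <- group
      rows[[length(rows) + 1L]] <- res$row
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("sweep_result", "data.frame")
  out
}

subset_feature_group <- function(encoded, group) {
  keep_block <- switch(group,
                       scores_only = "score",
                       evidence_only = "evidence",
                       ensemble = c("evidence", "score"))
  take <- function(enc) {
    cols <- which(enc$manifest$block %in% keep_block)
    encoded_matrix(enc$matrix[, cols, drop = FALSE],
                   enc$manifest[cols, , drop = FALSE], enc$labels,
                   enc$variant_id)
  }
  structure(list(prep = encoded$prep, labeled = take(encoded$labeled),
                 unlabeled = take(encoded$unlabeled),
                 test = take(encoded$test)),
            class = "sgan_encoded_dataset")
}

#' Supervised-only comparison
#'
#' Trains, for each seed, the SGAN and the update-matched supervised-only
#' baseline (same discriminator architecture, labeled minibatches only) at
#' one label budget, and returns the paired metric rows for quantifying the
#' semi-supervision benefit.
#'
#' @param dataset An `sgan_dataset` or `sgan_encoded_dataset`.
#' @param budget Label budget.
#' @param seeds Training seeds.
#' @param epochs Training epochs per run.
#' @param cutoff Decision threshold.
#' @return A `sweep_result` data.frame with a `method` column
#'   (`"sgan"` / `"supervised"`).
#' @export
supervised_ablation <- function(dataset, budget = 250L, seeds = 1:5,
                                epochs = 200L, cutoff = 0.5) {
  encoded <- ensure_encoded_dataset(dataset)
  rows <- list()
  for (seed in seeds) {
    for (method in c("sgan", "supervised")) {
      res <- train_and_eval(encoded, budget, seed, epochs, method, cutoff)
      res$row$feature_group <- "ensemble"
      rows[[length(rows) + 1L]] <- res$row
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("sweep_result", "data.frame")
  out
}

#' Aggregate a sweep result
#'
#' Mean and standard deviation of every metric per (method, budget,
#' feature_group) cell, recomputable from the raw rows.
#'
#' @param result A `sweep_result`.
#' @return A data.frame of cell means and sds.
#' @export
summarize_sweep <- function(result) {
  metrics <- intersect(c("accuracy", "precision", "sensitivity",
                         "specificity", "f1", "mcc", "roc_auc", "pr_auc"),
                       names(result))
  keys <- intersect(c("method", "budget", "feature_group"), names(result))
  agg_mean <- aggregate(result[metrics], result[keys], mean)
  agg_sd <- aggregate(result[metrics], result[keys], sd)
  names(agg_sd)[match(metrics, names(agg_sd))] <- paste0(metrics, "_sd")
  merge(agg_mean, agg_sd, by = keys)
}

#' Histogram table of interpretation scores per class
#'
#' Bins the scores of each method into `breaks` separately for oncogenic
#' and benign variants.
#'
#' @param scores A named list of numeric score vectors (one per method), or
#'   a single vector.
#' @param truth True labels aligned with every score vector.
#' @param breaks Bin boundaries over `[0, 1]`.
#' @param plot Return a ggplot2 figure as attribute `"plot"` (requires
#'   ggplot2).
#' @return Data.frame with `method`, `class`, `bin_low`, `bin_high`,
#'   `count`.
#' @export
score_histograms <- function(scores, truth, breaks = seq(0, 1, by = 0.05),
                             plot = FALSE) {
  if (!is.list(scores)) scores <- list(scores = scores)
  t <- label_index(truth)
  rows <- list()
  for (method in names(scores)) {
    s <- scores[[method]]
    stopifnot(length(s) == length(t), all(s >= 0), all(s <= 1))
    for (cl in 1:2) {
      h <- hist(s[t == cl], breaks = breaks, plot = FALSE,
                include.lowest = TRUE, right = TRUE)
      rows[[length(rows) + 1L]] <- data.frame(
        method = method, class = CLASSES[cl],
        bin_low = head(breaks, -1L), bin_high = breaks[-1L],
        count = h$counts)
    }
  }
  out <- do.call(rbind, rows)
  if (plot) attr(out, "plot") <- histogram_plot(out)
  out
}

histogram_plot <- function(tab) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop_oncosgan("ggplot2 is required for plotting")
  }
  ggplot2::ggplot(tab, ggplot2::aes(x = (bin_low + bin_high) / 2, y = count,
                                    fill = class)) +
    ggplot2::geom_col(position = "identity", alpha = 0.6) +
    ggplot2::facet_wrap(~method) +
    ggplot2::labs(x = "interpretation score", y = "variants")
}

#' Two-dimensional embedding of fake, unlabeled and labeled variants
#'
#' Projects the three point sets onto the first two principal components of
#' their union (a deterministic linear embedding) and colours points by
#' source, optionally shading unlabeled points by interpretation score.
#' Decorative: intended for eyeballing whether generated variants trace the
#' cluster boundaries of the real data.
#'
#' @param fake Matrix of generated feature vectors.
#' @param unlabeled Encoded matrix (or matrix) of unlabeled variants.
#' @param labeled Encoded matrix (or matrix) of labeled variants.
#' @param scores Optional interpretation scores for the unlabeled points.
#' @param file Optional output path (png or svg inferred from extension).
#' @return Invisibly, the data.frame of embedding coordinates with a
#'   `source` column; the ggplot object as attribute `"plot"` when ggplot2
#'   is available.
#' @export
embedding_plot <- function(fake, unlabeled, labeled, scores = NULL,
                           file = NULL) {
  unl <- as_encoded(unlabeled)
  lab <- as_encoded(labeled)
  if (!all(ncol(fake) == c(ncol(unl$matrix), ncol(lab$matrix)))) {
    stop_oncosgan("point sets do not share a column manifest")
  }
  all_x <- rbind(fake, unl$matrix, lab$matrix)
  pc <- prcomp(all_x, rank. = 2L, center = TRUE, scale. = FALSE)
  coords <- as.data.frame(pc$x)
  names(coords) <- c("dim1", "dim2")
  coords$source <- c(rep("fake", nrow(fake)),
                     rep("unlabeled", nrow(unl$matrix)),
                     lab$labels)
  coords$score <- NA_real_
  if (!is.null(scores)) {
    coords$score[seq(nrow(fake) + 1L, nrow(fake) + nrow(unl$matrix))] <- scores
  }
  if (requireNamespace("ggplot2", quietly = TRUE)) {
    p <- ggplot2::ggplot(coords,
                         ggplot2::aes(dim1, dim2, colour = source)) +
      ggplot2::geom_point(size = 0.6, alpha = 0.6) +
      ggplot2::labs(x = "PC1", y = "PC2")
    attr(coords, "plot") <- p
    if (!is.null(file)) {
      ggplot2::ggsave(file, p, width = 7, height = 5)
    }
  } else if (!is.null(file)) {
    grDevices::png(file, width = 700, height = 500)
    plot(coords$dim1, coords$dim2,
         col = as.integer(factor(coords$source)), pch = 20,
         xlab = "PC1", ylab = "PC2")
    grDevices::dev.off()
  }
  invisible(coords)
}
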