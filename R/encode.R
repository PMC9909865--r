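# Encoding of the imputed feature table into the numeric matrix the networks
# consume: discrete evidence scores become Gaussian-dithered one-hot blocks,
# continuous deleteriousness scores are min-max scaled to [0,1].

#' Evidence one-hot encoder state
#'
#' Each of the 12 discrete evidence scores is expanded into a 4-slot one-hot
#' vector over the fixed category order (-1, 0, 1, 2); additive Gaussian
#' noise (mean 0, sd `noise_sd`) on every slot makes the encoding continuous
#' while keeping the slots separable.  The dither is applied once, at
#' preprocessing time, under `seed`.
#'
#' @param noise_sd Standard deviation of the additive dither (default 0.02).
#' @param seed Integer seed making the dither reproducible.
#' @return An object of class `evidence_encoder`.
#' @export
evidence_encoder <- function(noise_sd = 0.02, seed = 1L) {
  stopifnot(noise_sd >= 0)
  structure(list(levels = EVIDENCE_LEVELS, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "evidence_encoder")
}

#' One-hot encode the evidence block with Gaussian dither
#'
#' Continuous (imputed) evidence values are first rounded to the nearest
#' integer, which must be a member of \{-1, 0, 1, 2\}.
#'
#' @param table A fully imputed `raw_feature_table`.
#' @param encoder An [evidence_encoder()].
#' @return Numeric matrix with `12 * 4 = 48` columns named
#'   `<evi_col>.m1/.p0/.p1/.p2` in category order.
#' @export
encode_evidence <- function(table, encoder) {
  stopifnot(inherits(encoder, "evidence_encoder"))
  cols <- feature_columns(table)$evidence
  ev <- as.matrix(as.data.frame(table)[, cols, drop = FALSE])
  if (anyNA(ev)) stop_oncosgan("evidence block contains missing values; impute first")
  ev <- round(ev)
  bad <- !(ev %in% encoder$levels)
  if (any(bad)) {
    stop_oncosgan("evidence value(s) outside {-1,0,1,2} after rounding in row(s): ",
                  paste(head(unique(which(matrix(bad, nrow(ev)), arr.ind = TRUE)[, 1L]), 10L),
                        collapse = ", "))
  }
  n <- nrow(ev)
  out <- matrix(0, n, length(cols) * 4L)
  suffix <- c("m1", "p0", "p1", "p2")
  colnames(out) <- as.vector(t(outer(cols, suffix, paste, sep = ".")))
  for (j in seq_along(cols)) {
    slot <- match(ev[, j], encoder$levels)
    out[cbind(seq_len(n), (j - 1L) * 4L + slot)] <- 1
  }
  if (n > 0L) {
    noise <- local_seed(encoder$seed,
                        matrix(rnorm(n * ncol(out), 0, encoder$noise_sd), n))
    out <- out + noise
  }
  out
}

#' Fit a per-column min-max scaler
#'
#' @param x Numeric matrix (the 23-column score block of the training set,
#'   labeled plus unlabeled).
#' @return An object of class `minmax_scaler` holding per-column min and max.
#'   Constant columns trigger a warning and are later mapped to 0.
#' @export
fit_scaler <- function(x) {
  assert_matrix_like(x, "score block")
  if (anyNA(x)) stop_oncosgan("score block contains missing values; impute first")
  mins <- apply(x, 2L, min)
  maxs <- apply(x, 2L, max)
  constant <- maxs == mins
  if (any(constant)) {
    warning("constant column(s) mapped to 0: ",
            paste(colnames(x)[constant] %||% which(constant), collapse = ", "),
            call. = FALSE)
  }
  structure(list(min = mins, max = maxs, constant = constant,
                 columns = colnames(x)),
            class = "minmax_scaler")
}

#' Apply a fitted min-max scaler
#'
#' Values from the fitting set map into `[0, 1]`; out-of-range values seen at
#' apply time (e.g. test variants) are clipped to `[0, 1]`; constant columns
#' map to 0.
#'
#' @param x Numeric matrix with the same columns the scaler was fitted on.
#' @param scaler A `minmax_scaler`.
#' @return The scaled matrix.
#' @export
apply_scaler <- function(x, scaler) {
  stopifnot(inherits(scaler, "minmax_scaler"))
  assert_matrix_like(x, "score block")
  if (ncol(x) != length(scaler$min)) {
    stop_oncosgan("column count does not match the fitted scaler")
  }
  rng <- scaler$max - scaler$min
  rng[scaler$constant] <- 1
  out <- sweep(sweep(x, 2L, scaler$min, "-"), 2L, rng, "/")
  out[, scaler$constant] <- 0
  out[out < 0] <- 0
  out[out > 1] <- 1
  out
}

#' Assemble the encoded model-input matrix
#'
#' Composes the preprocessing pipeline on one table: impute missing entries,
#' one-hot encode the evidence block with dither, min-max scale the score
#' block, and bind the blocks (evidence first) into the
#' `12 * 4 + 23 = 71`-column matrix the networks consume.
#'
#' @param table A `raw_feature_table` (already missingness-filtered).
#' @param imputer A fitted [knn_imputer()].
#' @param encoder An [evidence_encoder()].
#' @param scaler A fitted [fit_scaler()] state.
#' @return An `encoded_matrix`: list with `matrix` (n x 71), `manifest`
#'   (data.frame of column name, block, source column, category level),
#'   `labels` and `variant_id`.
#' @export
assemble_features <- function(table, imputer, encoder, scaler) {
  imputed <- impute_missing(table, imputer)
  cols <- feature_columns(imputed)
  E <- encode_evidence(imputed, encoder)
  S <- apply_scaler(as.matrix(as.data.frame(imputed)[, cols$scores, drop = FALSE]),
                    scaler)
  mat <- cbind(E, S)
  manifest <- data.frame(
    column = colnames(mat),
    block = c(rep("evidence", ncol(E)), rep("score", ncol(S))),
    source = c(rep(cols$evidence, each = 4L), cols$scores),
    level = c(rep(EVIDENCE_LEVELS, times = length(cols$evidence)),
              rep(NA_real_, ncol(S))),
    stringsAsFactors = FALSE)
  if (ncol(mat) != nrow(manifest)) {
    stop_oncosgan("column count does not match the manifest")
  }
  encoded_matrix(mat, manifest, labels = imputed$label,
                 variant_id = imputed$variant_id)
}

#' Construct an encoded matrix object
#'
#' @param matrix Numeric matrix of encoded features.
#' @param manifest Data.frame describing every column (name, block, source,
#'   level).
#' @param labels Character label vector aligned with the rows.
#' @param variant_id Character id vector aligned with the rows.
#' @return An object of class `encoded_matrix`.
#' @export
encoded_matrix <- function(matrix, manifest, labels, variant_id = NULL) {
  assert_matrix_like(matrix, "encoded matrix")
  if (anyNA(matrix)) stop_oncosgan("encoded matrix must not contain missing values")
  if (ncol(matrix) != nrow(manifest)) {
    stop_oncosgan("manifest does not describe every column")
  }
  if (length(labels) != nrow(matrix)) {
    stop_oncosgan("labels are not aligned with the matrix rows")
  }
  structure(list(matrix = matrix, manifest = manifest,
                 labels = normalize_labels(labels),
                 variant_id = variant_id %||% rownames(matrix)),
            class = "encoded_matrix")
}

#' @export
print.encoded_matrix <- function(x, ...) {
  cat("<encoded_matrix> ", nrow(x$matrix), " variants x ", ncol(x$matrix),
      " columns (", sum(x$manifest$block == "evidence"), " evidence + ",
      sum(x$manifest$block == "score"), " score)\n", sep = "")
  cat("labels:", paste(sprintf("%s=%d", names(table(x$labels)),
                               as.integer(table(x$labels))), collapse = ", "),
      "\n")
  invisible(x)
}

#' Fit the full preprocessing state on training data
#'
#' Fits the imputer reference and the min-max scaler on the union of labeled
#' and unlabeled training variants (the test set is never seen), and fixes
#' the dither encoder.
#'
#' @param train_table `raw_feature_table` of all training rows (labeled and
#'   unlabeled), already missingness-filtered.
#' @param k Imputation neighbour count.
#' @param noise_sd Evidence dither standard deviation.
#' @param seed Dither seed.
#' @return A list of class `sgan_preprocessor` with `imputer`, `encoder`,
#'   `scaler`.
#' @export
fit_preprocessor <- function(train_table, k = 40L, noise_sd = 0.02, seed = 1L) {
  imputer <- knn_imputer(train_table, k = k)
  imputed <- impute_missing(train_table, imputer)
  cols <- feature_columns(imputed)
  scaler <- fit_scaler(as.matrix(as.data.frame(imputed)[, cols$scores, drop = FALSE]))
  structure(list(imputer = imputer, encoder = evidence_encoder(noise_sd, seed),
                 scaler = scaler),
            class = "sgan_preprocessor")
}

#' Apply a fitted preprocessor to a table
#'
#' @param table A `raw_feature_table`.
#' @param prep A fitted [fit_preprocessor()] state.
#' @return An `encoded_matrix`.
#' @export
preprocess_table <- function(table, prep) {
  stopifnot(inherits(prep, "sgan_preprocessor"))
  assemble_features(table, prep$imputer, prep$encoder, prep$scaler)
}
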