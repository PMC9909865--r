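# Raw per-variant feature tables: the TSV dialect shared by the synthetic
# generator, the preprocessing pipeline and the command-line tools.

#' Construct a raw per-variant feature table
#'
#' A raw feature table holds one row per variant: an opaque `variant_id`, a
#' `label` (`"oncogenic"`, `"benign"` or `"unlabeled"`), 12 discrete clinical
#' evidence scores (columns prefixed `evi_`, values in \{-1, 0, 1, 2\} per the
#' AMP/ASCO/CAP 2017 evidence tiers: -1 benign, 0 no support, 1 supporting,
#' 2 strong) and 23 continuous deleteriousness scores (columns prefixed
#' `score_`).  Missing entries are `NA`.
#'
#' @param df A data.frame with columns `variant_id`, `label`, 12 `evi_*`
#'   columns and 23 `score_*` columns.
#' @return The validated data.frame with class `raw_feature_table`.
#' @export
#' @examples
#' tab <- raw_feature_table(data.frame(
#'   variant_id = c("v1", "v2"), label = c("oncogenic", "benign"),
#'   matrix(0, 2, 12, dimnames = list(NULL, sprintf("evi_%02d", 1:12))),
#'   matrix(0.5, 2, 23, dimnames = list(NULL, sprintf("score_%02d", 1:23)))))
raw_feature_table <- function(df) {
  if (!is.data.frame(df)) stop_oncosgan("expected a data.frame")
  required <- c("variant_id", "label")
  miss <- setdiff(required, names(df))
  if (length(miss)) {
    stop_oncosgan("missing required column(s): ", paste(miss, collapse = ", "))
  }
  cols <- feature_columns(df)
  if (length(cols$evidence) != N_EVIDENCE) {
    stop_oncosgan("expected ", N_EVIDENCE, " 'evi_' columns, found ",
                  length(cols$evidence))
  }
  if (length(cols$scores) != N_SCORES) {
    stop_oncosgan("expected ", N_SCORES, " 'score_' columns, found ",
                  length(cols$scores))
  }
  if (anyDuplicated(df$variant_id)) {
    stop_oncosgan("variant_id values must be unique")
  }
  df$label <- normalize_labels(df$label)
  for (cn in c(cols$evidence, cols$scores)) {
    if (!is.numeric(df[[cn]])) {
      stop_oncosgan("column '", cn, "' is not numeric")
    }
  }
  bad <- validate_evidence_values(df, cols$evidence)
  if (length(bad)) {
    stop_oncosgan("evidence values outside {-1,0,1,2} in row(s): ",
                  paste(head(bad, 10L), collapse = ", "))
  }
  class(df) <- c("raw_feature_table", "data.frame")
  df
}

normalize_labels <- function(label) {
  lab <- as.character(label)
  lab[is.na(lab) | lab %in% c("", ".", "NA")] <- "unlabeled"
  lab[lab == "1"] <- "oncogenic"
  lab[lab == "0"] <- "benign"
  bad <- setdiff(unique(lab), LABEL_VALUES)
  if (length(bad)) {
    stop_oncosgan("invalid label value(s): ", paste(bad, collapse = ", "))
  }
  lab
}

validate_evidence_values <- function(df, evidence_cols) {
  ev <- as.matrix(df[, evidence_cols, drop = FALSE])
  ok <- is.na(ev) | matrix(ev %in% EVIDENCE_LEVELS, nrow(ev))
  which(rowSums(!ok) > 0L)
}

#' Names of the evidence and score columns of a feature table
#'
#' @param df A `raw_feature_table` (or any data.frame using the same naming).
#' @return A list with character vectors `evidence` and `scores`.
#' @export
feature_columns <- function(df) {
  list(evidence = grep("^evi_", names(df), value = TRUE),
       scores = grep("^score_", names(df), value = TRUE))
}

# The 35 raw feature columns as a numeric matrix (evidence block first).
feature_matrix <- function(table) {
  cols <- feature_columns(table)
  m <- as.matrix(as.data.frame(table)[, c(cols$evidence, cols$scores)])
  storage.mode(m) <- "double"
  rownames(m) <- table$variant_id
  m
}

#' Count missing raw-feature entries per variant
#'
#' @param table A `raw_feature_table`.
#' @return Integer vector, one count per row (0 to 35).
#' @export
missing_per_row <- function(table) {
  as.integer(rowSums(is.na(feature_matrix(table))))
}

#' Drop variants with too many missing feature values
#'
#' Variants with more than `max_missing` missing entries across the 35 raw
#' feature columns are removed before imputation; the default keeps variants
#' with at most 13 missing values.
#'
#' @param table A `raw_feature_table`.
#' @param max_missing Maximum tolerated number of missing entries per row.
#' @return The filtered table, row order preserved (possibly zero rows).
#' @export
filter_by_missingness <- function(table, max_missing = 13L) {
  stopifnot(max_missing >= 0)
  keep <- missing_per_row(table) <= max_missing
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read a per-variant feature table from TSV
#'
#' Expects a header row with columns `variant_id`, `label` (values
#' `oncogenic`/`benign`/`unlabeled`, or `1`/`0`/`NA`), 12 `evi_*` columns and
#' 23 `score_*` columns.  Empty fields and `"."` are treated as missing.
#'
#' @param path Path to a tab-separated file.
#' @return A `raw_feature_table`.
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) stop_oncosgan("no such file: ", path)
  df <- read.delim(path, sep = "\t", header = TRUE,
                   na.strings = c("", ".", "NA"),
                   stringsAsFactors = FALSE, check.names = FALSE,
                   colClasses = NA)
  if (!"label" %in% names(df)) {
    stop_oncosgan("missing required column(s): label")
  }
  df$label <- as.character(df$label)
  if ("variant_id" %in% names(df)) df$variant_id <- as.character(df$variant_id)
  cols <- feature_columns(df)
  for (cn in c(cols$evidence, cols$scores)) {
    if (is.character(df[[cn]])) {
      bad <- which(!is.na(df[[cn]]) & is.na(suppressWarnings(as.numeric(df[[cn]]))))
      if (length(bad)) {
        stop_oncosgan("non-numeric value(s) in column '", cn, "', row(s): ",
                      paste(head(bad, 10L), collapse = ", "))
      }
    }
    df[[cn]] <- as.numeric(df[[cn]])
  }
  raw_feature_table(df)
}

#' Write a per-variant feature table as TSV
#'
#' Missing entries are written as `"."`; the output round-trips through
#' [read_feature_table()].
#'
#' @param table A `raw_feature_table`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path) {
  df <- as.data.frame(table)
  cols <- feature_columns(df)
  for (cn in c(cols$evidence, cols$scores)) {
    v <- format_exact(df[[cn]])
    v[is.na(df[[cn]])] <- "."
    df[[cn]] <- v
  }
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = ".")
  invisible(path)
}
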