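# k-nearest-neighbour imputation of missing raw feature values, in the style
# of the classic KNN imputer: distances are Euclidean over mutually observed
# coordinates, rescaled by the proportion of coordinates used, and each
# missing entry is filled with the mean of that column over the k nearest
# reference rows that observe it.

#' Fit a k-nearest-neighbour imputer
#'
#' Stores the raw 35-column feature matrix of `table` as the reference set
#' against which missing entries (in this or any other table) are imputed.
#'
#' @param table A `raw_feature_table` used as the neighbour reference
#'   (typically the union of labeled and unlabeled training variants).
#' @param k Number of nearest neighbours averaged per missing entry
#'   (default 40).  When fewer eligible reference rows exist, all of them
#'   are used.
#' @return An object of class `knn_imputer`.
#' @export
knn_imputer <- function(table, k = 40L) {
  if (k < 1) stop_oncosgan("k must be >= 1")
  X <- feature_matrix(table)
  if (nrow(X) < 2L) stop_oncosgan("imputer needs at least 2 reference rows")
  all_missing <- colSums(!is.na(X)) == 0L
  if (any(all_missing)) {
    stop_oncosgan("column(s) missing in all reference rows: ",
                  paste(colnames(X)[all_missing], collapse = ", "))
  }
  structure(list(k = as.integer(k), reference = X), class = "knn_imputer")
}

# Pairwise distances between rows of Q and rows of R with missing entries:
# d(x, y)^2 = (p / |obs|) * sum over mutually observed j of (x_j - y_j)^2,
# Inf when no coordinate is mutually observed.
nan_euclidean_dist <- function(Q, R) {
  Mq <- 1 * !is.na(Q)
  Mr <- 1 * !is.na(R)
  Qz <- Q
  Qz[is.na(Q)] <- 0
  Rz <- R
  Rz[is.na(R)] <- 0
  S <- (Qz^2) %*% t(Mr) - 2 * (Qz %*% t(Rz)) + Mq %*% t(Rz^2)
  C <- Mq %*% t(Mr)
  D2 <- ncol(Q) * S / C            # C == 0 yields NaN, mapped to Inf below
  D2[!is.finite(D2)] <- Inf
  D2[D2 < 0] <- 0                  # guard tiny negative rounding residue
  sqrt(D2)
}

#' Impute missing feature values by the k-nearest-neighbour mean
#'
#' Every missing entry of `table` is replaced by the mean of that column over
#' the `k` nearest reference rows (fitted in [knn_imputer()]) that observe
#' the column.  Distances are computed over mutually observed raw columns and
#' rescaled by the proportion of columns used; ties are broken by reference
#' row order.  Observed entries are never altered.
#'
#' @param table A `raw_feature_table` (should already have passed
#'   [filter_by_missingness()]).
#' @param imputer A fitted `knn_imputer`.
#' @param chunk_size Number of query rows processed per distance block
#'   (memory/speed trade-off; the result does not depend on it).
#' @return The table with all missing feature entries filled in.
#' @export
impute_missing <- function(table, imputer, chunk_size = 1024L) {
  if (!inherits(imputer, "knn_imputer")) stop_oncosgan("not a knn_imputer")
  if (nrow(table) < 2L && anyNA(feature_matrix(table))) {
    stop_oncosgan("imputation needs at least 2 rows")
  }
  Q <- feature_matrix(table)
  if (!anyNA(Q)) return(table)
  R <- imputer$reference
  if (ncol(Q) != ncol(R) || !identical(colnames(Q), colnames(R))) {
    stop_oncosgan("table columns do not match the imputer reference")
  }
  obs_ref <- !is.na(R)
  n_donors <- colSums(obs_ref)
  k <- imputer$k
  need <- which(rowSums(is.na(Q)) > 0L)
  filled <- Q
  # Candidate pool for the partial-selection fast path: enough of the nearest
  # rows that >= k donors almost surely observe any given column; exactness
  # is preserved by falling back to the full ordering when they do not.
  pool <- min(nrow(R), as.integer(k + 64L + ceiling(0.25 * k)))
  for (start in seq(1L, length(need), by = chunk_size)) {
    idx <- need[start:min(start + chunk_size - 1L, length(need))]
    D <- nan_euclidean_dist(Q[idx, , drop = FALSE], R)
    for (ii in seq_along(idx)) {
      i <- idx[ii]
      d <- D[ii, ]
      ord_full <- NULL
      ord_near <- if (pool < length(d)) {
        thr <- sort(d, partial = pool)[pool]
        cand <- which(d <= thr)
        cand[order(d[cand], cand)]        # stable: ties by reference row order
      } else {
        ord_full <- order(d, seq_along(d))
      }
      for (j in which(is.na(Q[i, ]))) {
        want <- min(k, n_donors[j])
        donors <- ord_near[obs_ref[ord_near, j]]
        donors <- donors[is.finite(d[donors])]
        if (length(donors) < want) {      # rare: fall back to the exact path
          if (is.null(ord_full)) ord_full <- order(d, seq_along(d))
          donors <- ord_full[obs_ref[ord_full, j]]
          donors <- donors[is.finite(d[donors])]
        }
        if (!length(donors)) {
          stop_oncosgan("no eligible neighbour for column '",
                        colnames(Q)[j], "'")
        }
        take <- donors[seq_len(min(k, length(donors)))]
        filled[i, j] <- mean(R[take, j])
      }
    }
  }
  out <- as.data.frame(table)
  cols <- c(feature_columns(table)$evidence, feature_columns(table)$scores)
  out[, cols] <- filled[, cols, drop = FALSE]
  class(out) <- c("raw_feature_table", "data.frame")
  out
}
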