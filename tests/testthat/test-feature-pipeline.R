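# Missingness filter, k-NN imputation, dithered one-hot encoding, min-max
# scaling, and the assembled 71-column model input.

test_that("missingness filter keeps exactly the rows at or below the threshold", {
  tab <- make_toy_table(3, seed = 1)
  df <- as.data.frame(tab)
  df[1, evi_names] <- NA                   # 12 missing
  df[1, score_names[1:2]] <- NA            # 14 missing -> dropped
  df[2, score_names[1:13]] <- NA           # 13 missing -> kept
  tab <- raw_feature_table(df)
  out <- filter_by_missingness(tab)
  expect_equal(out$variant_id, df$variant_id[2:3])

  big <- make_toy_table(100, seed = 2, missing_rate = 0.35)
  counts <- rowSums(is.na(as.data.frame(big)[, c(evi_names, score_names)]))
  for (mm in c(0L, 5L, 13L)) {
    expect_equal(filter_by_missingness(big, mm)$variant_id,
                 big$variant_id[counts <= mm])
  }
})

test_that("imputation fills a missing entry with the mean of its k nearest neighbours", {
  df <- as.data.frame(make_toy_table(3, seed = 3))
  df[, score_names] <- 0
  df[, evi_names] <- 0
  df[1, "score_01"] <- NA
  df[2, "score_01"] <- 0.2
  df[3, "score_01"] <- 0.4
  tab <- raw_feature_table(df)
  imp <- impute_missing(tab, knn_imputer(tab, k = 2))
  expect_equal(imp$score_01, c(0.3, 0.2, 0.4))
})

test_that("a fully observed table is returned unchanged", {
  tab <- make_toy_table(10, seed = 4)
  out <- impute_missing(tab, knn_imputer(tab, k = 5))
  expect_identical(as.data.frame(out), as.data.frame(tab))
})

test_that("imputation matches the exhaustive nearest-neighbour oracle and preserves observed entries", {
  tab <- make_toy_table(200, seed = 5, missing_rate = 0.05)
  imp <- impute_missing(tab, knn_imputer(tab, k = 40))
  X <- as.matrix(as.data.frame(tab)[, c(evi_names, score_names)])
  want <- oracle_impute(X, k = 40)
  got <- as.matrix(as.data.frame(imp)[, c(evi_names, score_names)])
  expect_lt(max(abs(got - want)), 1e-9)
  obs <- !is.na(X)
  expect_identical(got[obs], X[obs])
})

test_that("imputation errors on a column with no observed reference values", {
  df <- as.data.frame(make_toy_table(5, seed = 6))
  df$score_07 <- NA_real_
  expect_error(knn_imputer(raw_feature_table(df)), "score_07")
})

test_that("evidence one-hot uses category order (-1,0,1,2) and seeded dither", {
  tab <- make_toy_table(4, seed = 7)
  df <- as.data.frame(tab)
  df[, evi_names] <- 0
  df[1, "evi_01"] <- 1
  df[2, "evi_01"] <- -1
  df[3, "evi_01"] <- 2
  tab <- raw_feature_table(df)
  enc0 <- evidence_encoder(noise_sd = 0, seed = 1)
  E <- encode_evidence(tab, enc0)
  expect_equal(E[1, 1:4], c(0, 0, 1, 0), ignore_attr = TRUE)
  expect_equal(E[2, 1:4], c(1, 0, 0, 0), ignore_attr = TRUE)
  expect_equal(E[3, 1:4], c(0, 0, 0, 1), ignore_attr = TRUE)
  enc <- evidence_encoder(noise_sd = 0.02, seed = 9)
  expect_identical(encode_evidence(tab, enc), encode_evidence(tab, enc))
  expect_false(identical(encode_evidence(tab, enc),
                         encode_evidence(tab, evidence_encoder(0.02, 10))))
  # continuous (imputed) values are rounded to the nearest level first;
  # such tables exist only downstream of imputation, so bypass the
  # constructor's discrete-domain check
  df2 <- df
  df2[4, "evi_01"] <- 0.8
  class(df2) <- c("raw_feature_table", "data.frame")
  E2 <- encode_evidence(df2, enc0)
  expect_equal(E2[4, 1:4], c(0, 0, 1, 0), ignore_attr = TRUE)
  df2[4, "evi_01"] <- 5
  expect_error(encode_evidence(df2, enc0), "outside")
})

test_that("with no dither, argmax decoding recovers the evidence scores exactly", {
  tab <- make_toy_table(50, seed = 8)
  E <- encode_evidence(tab, evidence_encoder(noise_sd = 0, seed = 1))
  lv <- c(-1, 0, 1, 2)
  for (j in seq_along(evi_names)) {
    dec <- lv[apply(E[, (j - 1) * 4 + 1:4], 1, which.max)]
    expect_equal(dec, as.data.frame(tab)[[evi_names[j]]])
  }
})

test_that("min-max scaling maps the fitting set to [0,1], clips, and flags constant columns", {
  x <- cbind(a = c(2, 4, 6), b = c(0, 1, 2))
  sc <- fit_scaler(x)
  expect_equal(apply_scaler(x, sc)[, "a"], c(0, 0.5, 1))
  out <- apply_scaler(cbind(a = c(-5, 10), b = c(0.5, 1)), sc)
  expect_equal(out[, "a"], c(0, 1))
  expect_warning(sc2 <- fit_scaler(cbind(k = c(5, 5, 5))), "constant")
  expect_equal(apply_scaler(cbind(k = c(5, 7, 3)), sc2)[, "k"], c(0, 0, 0))
})

test_that("assembled matrices have 71 documented columns, no missing values, and are seed-reproducible", {
  tab <- make_toy_table(30, seed = 9, missing_rate = 0.05)
  tab <- filter_by_missingness(tab)
  prep <- fit_preprocessor(tab, k = 5, noise_sd = 0.02, seed = 3)
  enc <- preprocess_table(tab, prep)
  expect_s3_class(enc, "encoded_matrix")
  expect_equal(ncol(enc$matrix), 71L)
  expect_equal(nrow(enc$manifest), 71L)
  expect_equal(sum(enc$manifest$block == "evidence"), 48L)
  expect_equal(sum(enc$manifest$block == "score"), 23L)
  expect_false(anyNA(enc$matrix))
  # score block of the fitting set lies in [0,1]
  sb <- enc$matrix[, enc$manifest$block == "score"]
  expect_true(all(sb >= 0 & sb <= 1))
  # bitwise determinism of the full pipeline
  prep2 <- fit_preprocessor(tab, k = 5, noise_sd = 0.02, seed = 3)
  expect_identical(preprocess_table(tab, prep2)$matrix, enc$matrix)
})

test_that("unlabeled-only tables keep their label vector", {
  tab <- make_toy_table(8, seed = 10,
                        labels = rep("unlabeled", 8))
  prep <- fit_preprocessor(tab, k = 3)
  enc <- preprocess_table(tab, prep)
  expect_true(all(enc$labels == "unlabeled"))
})

test_that("feature tables round-trip through TSV read/write", {
  tab <- make_toy_table(15, seed = 11, missing_rate = 0.1)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_feature_table(tab, path)
  back <- read_feature_table(path)
  expect_identical(as.data.frame(back), as.data.frame(tab))
})

test_that("encoded matrices round-trip through TSV bitwise", {
  tab <- make_toy_table(12, seed = 12)
  prep <- fit_preprocessor(tab, k = 3)
  enc <- preprocess_table(tab, prep)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_encoded_matrix(enc, path)
  back <- read_encoded_matrix(path)
  expect_identical(unname(back$matrix), unname(enc$matrix))
  expect_identical(back$labels, enc$labels)
  expect_identical(back$manifest$block, enc$manifest$block)
})

test_that("malformed tables are rejected with informative errors", {
  df <- as.data.frame(make_toy_table(5, seed = 13))
  expect_error(raw_feature_table(df[, setdiff(names(df), "label")]), "label")
  df2 <- df
  df2$evi_01[2] <- 7
  expect_error(raw_feature_table(df2), "evidence")
  df3 <- df
  names(df3)[names(df3) == "score_23"] <- "other"
  expect_error(raw_feature_table(df3), "23")
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines("variant_id\tevi_01\nv1\t0", path)
  expect_error(read_feature_table(path), "label")
})
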