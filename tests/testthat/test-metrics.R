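# The eight-metric evaluation panel against independent oracles.

test_that("threshold metrics agree with a direct-arithmetic oracle on the exhaustive small grid", {
  oracle <- function(tp, fp, tn, fn) {
    # written straight from the defining ratios, independently of the package
    div <- function(a, b) if (b == 0) NaN else a / b
    prec <- div(tp, tp + fp)
    rec <- div(tp, tp + fn)
    list(accuracy = (tp + tn) / (tp + fp + tn + fn),
         precision = prec,
         sensitivity = rec,
         specificity = div(tn, fp + tn),
         f1 = if (is.nan(prec) || is.nan(rec)) NaN else
           div(2 * prec * rec, prec + rec),
         mcc = div(tp * tn - fp * fn,
                   sqrt((tn + fn) * (tn + fp) * (tp + fn) * (tp + fp))))
  }
  grid <- expand.grid(tp = 0:8, fp = 0:8, tn = 0:8, fn = 0:8)
  grid <- grid[rowSums(grid) > 0, ]
  got <- suppressWarnings(
    do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
      binary_metrics(as.list(grid[i, ]))
    })))
  want <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
    as.data.frame(do.call(oracle, as.list(grid[i, ])))
  }))
  for (m in names(want)) {
    expect_equal(got[[m]], want[[m]], tolerance = 1e-12, info = m)
  }
})

test_that("perfect, chance-level and degenerate confusion counts behave as defined", {
  perfect <- binary_metrics(list(tp = 50, fp = 0, tn = 50, fn = 0))
  expect_equal(unlist(perfect), c(accuracy = 1, precision = 1,
                                  sensitivity = 1, specificity = 1,
                                  f1 = 1, mcc = 1))
  chance <- binary_metrics(list(tp = 25, fp = 25, tn = 25, fn = 25))
  expect_equal(chance$mcc, 0)
  expect_error(binary_metrics(list(tp = 0, fp = 0, tn = 0, fn = 0)), "zero")
  w <- capture_warnings(m <- binary_metrics(list(tp = 0, fp = 0, tn = 5, fn = 5)))
  expect_match(w, "precision", all = FALSE)
  expect_true(is.nan(m$precision))
})

test_that("confusion counts partition the set and swap under prediction inversion", {
  withr::with_seed(42, {
    truth <- sample(c("benign", "oncogenic"), 200, replace = TRUE)
    calls <- sample(c("benign", "oncogenic"), 200, replace = TRUE)
  })
  cc <- confusion_counts(calls, truth)
  expect_equal(cc$tp + cc$fp + cc$tn + cc$fn, 200)
  # brute-force tally
  expect_equal(cc$tp, sum(calls == "oncogenic" & truth == "oncogenic"))
  expect_equal(cc$fn, sum(calls == "benign" & truth == "oncogenic"))
  inv <- confusion_counts(ifelse(calls == "benign", "oncogenic", "benign"),
                          truth)
  expect_equal(inv$tp, cc$fn)
  expect_equal(inv$tn, cc$fp)
  expect_error(confusion_counts(calls, rep("unlabeled", 200)), "benign")
})

test_that("ROC-AUC equals the all-pairs counting oracle (ties half) and pROC", {
  withr::with_seed(7, {
    scores <- round(runif(200), 2)          # force ties
    truth <- sample(c("benign", "oncogenic"), 200, replace = TRUE)
  })
  pos <- scores[truth == "oncogenic"]
  neg <- scores[truth == "benign"]
  pairs <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  expect_equal(roc_auc(scores, truth), mean(pairs), tolerance = 1e-12)
  expect_equal(as.numeric(pROC::auc(pROC::roc(truth, scores,
                                              levels = c("benign", "oncogenic"),
                                              direction = "<", quiet = TRUE))),
               roc_auc(scores, truth), tolerance = 1e-12)
  expect_equal(roc_auc(rep(0.5, 200), truth), 0.5)
  sep <- c(rep(0.9, 5), rep(0.1, 5))
  lab <- rep(c("oncogenic", "benign"), each = 5)
  expect_equal(roc_auc(sep, lab), 1)
  expect_error(roc_auc(scores, rep("benign", 200)), "both classes")
})

test_that("ROC-AUC flip identities hold", {
  withr::with_seed(11, {
    scores <- runif(150)
    truth <- sample(c("benign", "oncogenic"), 150, replace = TRUE)
  })
  flipped <- ifelse(truth == "benign", "oncogenic", "benign")
  expect_equal(roc_auc(scores, flipped), 1 - roc_auc(scores, truth),
               tolerance = 1e-12)
  expect_equal(roc_auc(1 - scores, flipped), roc_auc(scores, truth),
               tolerance = 1e-12)
})

test_that("PR-AUC matches an independent step-summation oracle", {
  oracle_pr <- function(scores, truth) {
    th <- sort(unique(scores), decreasing = TRUE)
    n_pos <- sum(truth == "oncogenic")
    prev_r <- 0
    area <- 0
    for (t in th) {
      call_pos <- scores >= t
      tp <- sum(call_pos & truth == "oncogenic")
      r <- tp / n_pos
      p <- tp / sum(call_pos)
      area <- area + (r - prev_r) * p
      prev_r <- r
    }
    area
  }
  withr::with_seed(13, {
    scores <- round(runif(200), 2)
    truth <- sample(c("benign", "oncogenic"), 200, replace = TRUE)
  })
  expect_equal(pr_auc(scores, truth), oracle_pr(scores, truth),
               tolerance = 1e-12)
  sep <- c(rep(0.9, 5), rep(0.1, 5))
  lab <- rep(c("oncogenic", "benign"), each = 5)
  expect_equal(pr_auc(sep, lab), 1)
})

test_that("MCC is invariant under a simultaneous class and prediction flip", {
  withr::with_seed(17, {
    truth <- sample(c("benign", "oncogenic"), 300, replace = TRUE)
    calls <- sample(c("benign", "oncogenic"), 300, replace = TRUE)
  })
  m1 <- suppressWarnings(binary_metrics(confusion_counts(calls, truth)))
  flip <- function(x) ifelse(x == "benign", "oncogenic", "benign")
  m2 <- suppressWarnings(binary_metrics(confusion_counts(flip(calls),
                                                         flip(truth))))
  expect_equal(m1$mcc, m2$mcc, tolerance = 1e-12)
})

test_that("classification uses a strict cutoff and supports the reference sweep grid", {
  expect_equal(classify_variants(0.5, 0.5), "benign")
  expect_equal(classify_variants(0.5000001, 0.5), "oncogenic")
  expect_equal(classify_variants(c(0.2, 0), 0), c("oncogenic", "benign"))
  withr::with_seed(19, {
    scores <- runif(300)
    truth <- sample(c("benign", "oncogenic"), 300, replace = TRUE)
  })
  grid <- c(seq(0.1, 0.9, by = 0.1), 0.95)
  sw <- suppressWarnings(threshold_sweep(scores, truth, grid))
  expect_equal(nrow(sw), 10L)
  expect_equal(sw$cutoff, grid)
  # per-cutoff recomputation matches the sweep rows
  for (i in c(1L, 5L, 10L)) {
    m <- suppressWarnings(metric_report(scores, truth, grid[i]))
    expect_equal(sw[i, names(m)], m, ignore_attr = TRUE)
  }
  # monotone: higher cutoff never increases sensitivity, never decreases specificity
  expect_true(all(diff(sw$sensitivity) <= 1e-12))
  expect_true(all(diff(sw$specificity) >= -1e-12))
  # AUCs identical across rows
  expect_equal(length(unique(sw$roc_auc)), 1L)
  expect_equal(length(unique(sw$pr_auc)), 1L)
})
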