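test_that("confusion-matrix metrics match hand-evaluated formulas", {
  m <- metrics_from_confusion(50, 0, 0, 50)
  expect_equal(unname(m[c("accuracy", "kappa", "mcc", "f_measure")]),
               c(1, 1, 1, 1))
  m2 <- metrics_from_confusion(40, 10, 20, 30)
  expect_equal(unname(m2["accuracy"]), 0.7)
  expect_equal(unname(m2["kappa"]), 0.4, tolerance = 1e-12)
  expect_equal(unname(m2["mcc"]), 0.4082483, tolerance = 1e-6)
  expect_equal(unname(m2["tp_rate"]), 0.8)
  expect_equal(unname(m2["tn_rate"]), 0.6)
  expect_equal(unname(m2["f_measure"]), 2 * (2/3) * 0.8 / (2/3 + 0.8))
  # degenerate all-one-class predictions: kappa and MCC are 0 by convention
  m3 <- metrics_from_confusion(10, 0, 10, 0)
  expect_equal(unname(m3["kappa"]), 0)
  expect_equal(unname(m3["mcc"]), 0)
})

test_that("metrics agree with an independent oracle over all confusions", {
  skip_if_not_installed("e1071")
  # enumerate every confusion matrix with n <= 20; oracle reconstructs the
  # label/prediction vectors and uses cor() (MCC) and e1071 (kappa)
  for (n in c(4L, 9L, 14L, 20L)) {
    parts <- expand.grid(tp = 0:n, fn = 0:n, fp = 0:n)
    parts <- parts[rowSums(parts) <= n, ]
    for (r in seq_len(nrow(parts))) {
      tp <- parts$tp[r]; fn <- parts$fn[r]; fp <- parts$fp[r]
      tn <- n - tp - fn - fp
      y <- c(rep(1, tp + fn), rep(0, fp + tn))
      p <- c(rep(1, tp), rep(0, fn), rep(1, fp), rep(0, tn))
      m <- metrics_from_confusion(tp, fn, fp, tn)
      expect_equal(unname(m["accuracy"]), mean(y == p), tolerance = 1e-12)
      mcc_oracle <- suppressWarnings(cor(y, p))
      if (is.finite(mcc_oracle)) {
        expect_equal(unname(m["mcc"]), mcc_oracle, tolerance = 1e-9)
      } else {
        expect_equal(unname(m["mcc"]), 0)
      }
      tab <- table(factor(p, levels = 0:1), factor(y, levels = 0:1))
      kap_oracle <- e1071::classAgreement(tab)$kappa
      if (is.finite(kap_oracle)) {
        expect_equal(unname(m["kappa"]), kap_oracle, tolerance = 1e-9)
      } else {
        expect_equal(unname(m["kappa"]), 0)
      }
      if (tp + fp > 0 && tp + fn > 0) {
        prec <- tp / (tp + fp); rec <- tp / (tp + fn)
        f_oracle <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
        expect_equal(unname(m["f_measure"]), f_oracle, tolerance = 1e-12)
      }
    }
  }
})

test_that("the rank-statistic AUC matches a brute-force pair count", {
  set.seed(8)
  score <- rnorm(40)
  y <- rbinom(40, 1, 0.4) == 1
  pairs <- 0; wins <- 0
  for (i in which(y)) for (j in which(!y)) {
    pairs <- pairs + 1
    wins <- wins + (score[i] > score[j]) + 0.5 * (score[i] == score[j])
  }
  expect_equal(wbnscreen:::rank_auc(score, y), wins / pairs,
               tolerance = 1e-12)
})

test_that("cross-validation pools out-of-fold predictions deterministically", {
  tab <- generate_table(table_config(n = 120, p = 8,
                                     planted = paste0("V", 1:3),
                                     loading = 5, noise_sd = 0.5,
                                     label_strength = 4, seed = 5))
  feats <- paste0("V", 1:8)
  m1 <- crossval_metrics(tab, feats, rf_learner(ntree = 50), folds = 10,
                         seed = 2)
  m2 <- crossval_metrics(tab, feats, rf_learner(ntree = 50), folds = 10,
                         seed = 2)
  expect_identical(m1, m2)
  expect_identical(unname(m1["TP"] + m1["FN"] + m1["FP"] + m1["TN"]),
                   120)
  expect_gt(m1["mcc"], 0)   # planted signal is learnable
  expect_gt(m1["auc"], 0.5)
  expect_error(crossval_metrics(tab, c("V1", "nope"), rf_learner(10)),
               "missing feature")
})

test_that("panels train one member per two-class set and vote by threshold", {
  sets <- lapply(1:3, function(s) {
    generate_table(table_config(n = 80, p = 6, planted = paste0("V", 1:2),
                                loading = 5, noise_sd = 0.5,
                                label_strength = 4, seed = 100 + s))
  })
  feats <- paste0("V", 1:6)
  panel <- train_panel(sets, feats, rf_learner(ntree = 50), seed = 9,
                       cv = FALSE)
  expect_length(panel$members, 3L)
  test <- generate_table(table_config(n = 40, p = 6,
                                      planted = paste0("V", 1:2),
                                      loading = 5, noise_sd = 0.5,
                                      label_strength = 4, seed = 999))
  res <- panel_screen(panel, test, threshold = 2L)
  expect_identical(res$votes$selected, res$votes$votes >= 2L)
  expect_true(all(res$votes$votes >= 0 & res$votes$votes <= 3))
  # unanimity selects at any threshold <= E; monotone non-increasing in t
  n_sel <- vapply(1:3, function(t)
    sum(panel_screen(panel, test, t)$votes$selected), integer(1))
  expect_true(all(diff(n_sel) <= 0))
  expect_identical(sum(res$vote_matrix[res$votes$votes == 3, ] == 0), 0L)
  # fractional threshold: ceil(0.71 * 3) = 3
  expect_identical(panel_screen(panel, test, "fractional")$threshold, 3L)
})

test_that("single-class sets are skipped with a warning", {
  good <- generate_table(table_config(n = 60, p = 4,
                                      planted = paste0("V", 1:2),
                                      loading = 5, noise_sd = 0.5,
                                      label_strength = 4, seed = 1))
  bad <- good; bad$activity <- "inactive"
  expect_warning(
    panel <- train_panel(list(good, bad), paste0("V", 1:4),
                         rf_learner(ntree = 20), seed = 1, cv = FALSE),
    "single class")
  expect_length(panel$members, 1L)
  expect_error(suppressWarnings(
    train_panel(list(bad), paste0("V", 1:4), rf_learner(20), cv = FALSE)),
    "no trainable sets")
})

test_that("identical sets and seed give identical member predictions", {
  tab <- generate_table(table_config(n = 60, p = 4,
                                     planted = paste0("V", 1:2),
                                     loading = 5, noise_sd = 0.5,
                                     label_strength = 4, seed = 77))
  feats <- paste0("V", 1:4)
  p1 <- train_panel(list(tab, tab), feats, rf_learner(ntree = 30),
                    seed = 4, cv = FALSE)
  test <- generate_table(table_config(n = 30, p = 4,
                                      planted = paste0("V", 1:2),
                                      loading = 5, noise_sd = 0.5,
                                      label_strength = 4, seed = 78))
  r1 <- panel_screen(p1, test, 1L)
  p2 <- train_panel(list(tab, tab), feats, rf_learner(ntree = 30),
                    seed = 4, cv = FALSE)
  r2 <- panel_screen(p2, test, 1L)
  expect_identical(r1$votes, r2$votes)
})
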