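#' Classification metrics from a pooled confusion matrix
#'
#' Standard formulas: TP rate (recall), TN rate, accuracy, precision,
#' F-measure `2PR/(P+R)`, Cohen's kappa `(p_o - p_e)/(1 - p_e)`, and
#' `MCC = (TP TN - FP FN)/sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`. Ratios with
#' an undefined denominator are 0 by convention (kappa, MCC included).
#'
#' @param tp,fn,fp,tn confusion counts (active = positive class).
#' @param auc optional ROC AUC to carry along.
#' @return named numeric vector of class `model_metrics`.
#' @export
metrics_from_confusion <- function(tp, fn, fp, tn, auc = NA_real_) {
  n <- tp + fn + fp + tn
  safe_div <- function(num, den) if (den > 0) num / den else 0
  tpr <- safe_div(tp, tp + fn)
  tnr <- safe_div(tn, tn + fp)
  acc <- safe_div(tp + tn, n)
  prec <- safe_div(tp, tp + fp)
  f1 <- safe_div(2 * prec * tpr, prec + tpr)
  p_e <- safe_div((tp + fn) * (tp + fp) + (tn + fp) * (tn + fn), n^2)
  kappa <- if (p_e < 1) (acc - p_e) / (1 - p_e) else 0
  den2 <- as.numeric(tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mcc <- if (den2 > 0) {
    (as.numeric(tp) * tn - as.numeric(fp) * fn) / sqrt(den2)
  } else 0
  structure(c(TP = tp, FN = fn, FP = fp, TN = tn,
              tp_rate = tpr, tn_rate = tnr, accuracy = acc,
              precision = prec, f_measure = f1, kappa = kappa, mcc = mcc,
              auc = auc),
            class = "model_metrics")
}

# rank-statistic (Mann-Whitney) AUC over scores
rank_auc <- function(score, is_pos) {
  n1 <- sum(is_pos); n0 <- sum(!is_pos)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(score)
  (sum(r[is_pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Random-forest learner configuration
#'
#' The pluggable learner contract used throughout the screening stage: a
#' list with `fit(x, y, seed)` returning a model, and `predict_prob(model,
#' x)` returning the probability of the active class. The default wraps
#' `randomForest` with per-split feature subsampling (`sqrt(p)`) and a
#' class-balanced bootstrap.
#'
#' @param ntree number of trees (default 100).
#' @return a learner object (class `ws_learner`).
#' @export
rf_learner <- function(ntree = 100L) {
  structure(list(
    name = sprintf("random_forest(ntree=%d)", ntree),
    fit = function(x, y, seed) {
      y <- factor(y, levels = c("inactive", "active"))
      set.seed(seed)
      nmin <- min(table(y))
      randomForest::randomForest(
        x = x, y = y, ntree = ntree,
        mtry = max(1L, floor(sqrt(ncol(x)))),
        strata = y, sampsize = rep(nmin, 2))
    },
    predict_prob = function(model, x) {
      unname(stats::predict(model, x, type = "prob")[, "active"])
    }
  ), class = "ws_learner")
}

# stratified fold assignment; guarantees both classes in every fold when
# feasible, otherwise reduces the fold count with a warning
stratified_folds <- function(y, folds, seed) {
  set.seed(seed)
  nmin <- min(table(y))
  if (nmin < folds) {
    folds <- max(2L, nmin)
    warning("minority class smaller than fold count; reduced to ",
            folds, " folds")
  }
  f <- integer(length(y))
  for (cl in unique(y)) {
    idx <- sample(which(y == cl))
    f[idx] <- rep_len(seq_len(folds), length(idx))
  }
  f
}

#' Cross-validated performance metrics for one training set
#'
#' Stratified k-fold cross-validation; out-of-fold predictions (probability
#' cutoff 0.5) are pooled into a single confusion matrix from which the
#' metrics are derived; ROC AUC is the rank statistic over pooled
#' out-of-fold scores.
#'
#' @param table descriptor table with an `activity` column containing both
#'   classes.
#' @param features descriptor names to use.
#' @param learner a learner (default [rf_learner()]).
#' @param folds number of folds (default 10).
#' @param seed RNG seed.
#' @return a `model_metrics` vector.
#' @export
crossval_metrics <- function(table, features, learner = rf_learner(),
                             folds = 10L, seed = 1L) {
  y <- table$activity
  stopifnot(all(y %in% c("active", "inactive")),
            length(unique(y)) == 2L, nrow(table) >= folds)
  miss <- setdiff(features, names(table))
  if (length(miss)) stop("missing feature column(s): ",
                         paste(miss, collapse = ", "))
  x <- as.matrix(table[, features, drop = FALSE])
  f <- stratified_folds(y, folds, derive_seed(seed, 0L))
  score <- numeric(nrow(x))
  for (k in unique(f)) {
    tr <- f != k
    model <- learner$fit(x[tr, , drop = FALSE], y[tr],
                         derive_seed(seed, k))
    score[!tr] <- learner$predict_prob(model, x[!tr, , drop = FALSE])
  }
  pred <- ifelse(score >= 0.5, "active", "inactive")
  tp <- sum(pred == "active" & y == "active")
  fn <- sum(pred == "inactive" & y == "active")
  fp <- sum(pred == "active" & y == "inactive")
  tn <- sum(pred == "inactive" & y == "inactive")
  metrics_from_confusion(tp, fn, fp, tn, auc = rank_auc(score, y == "active"))
}

#' Train a panel (ensemble) of per-set classifiers
#'
#' One classifier per training set, all sharing a single feature list;
#' per-set cross-validated metrics are recorded. Sets with a single class
#' are skipped with a warning (the ensemble shrinks).
#'
#' @param sets list of descriptor tables (the training sets).
#' @param features shared feature list (e.g. a PCAD selection).
#' @param learner a learner (default [rf_learner()]).
#' @param seed master seed.
#' @param folds folds for the recorded CV metrics (default 10).
#' @param cv whether to compute per-set CV metrics (default TRUE).
#' @return an object of class `trained_panel` with members, features and a
#'   metrics data.frame.
#' @export
train_panel <- function(sets, features, learner = rf_learner(), seed = 1L,
                        folds = 10L, cv = TRUE) {
  stopifnot(length(sets) >= 1L)
  members <- list()
  metrics <- list()
  for (s in seq_along(sets)) {
    tab <- sets[[s]]
    y <- tab$activity
    if (length(unique(y[y %in% c("active", "inactive")])) < 2L) {
      warning("training set ", s, " has a single class; skipped")
      next
    }
    x <- as.matrix(tab[, features, drop = FALSE])
    model <- learner$fit(x, y, derive_seed(seed, 1000L + s))
    members[[length(members) + 1L]] <- model
    if (cv) {
      mm <- crossval_metrics(tab, features, learner, folds,
                             seed = derive_seed(seed, 2000L + s))
      metrics[[length(metrics) + 1L]] <-
        data.frame(set = s, t(unclass(mm)))
    }
  }
  if (!length(members)) stop("no trainable sets (all single-class)")
  structure(list(members = members,
                 features = features,
                 predict_prob = learner$predict_prob,
                 learner = learner$name,
                 seed = seed,
                 metrics = if (length(metrics)) do.call(rbind, metrics)
                           else NULL),
            class = "trained_panel")
}

#' @export
print.trained_panel <- function(x, ...) {
  cat(sprintf("<trained_panel: %d members, %d features, %s>\n",
              length(x$members), length(x$features), x$learner))
  invisible(x)
}

#' Screen a test table by panel voting
#'
#' Each ensemble member casts a hard vote (predicted probability of the
#' active class >= 0.5); a compound is selected when it collects at least
#' `threshold` votes (default 10, the consensus rule "selected by 10 or
#' more training sets"). `threshold = "fractional"` uses
#' `ceiling(0.71 * ensemble size)` for other panel sizes.
#'
#' @param panel a [train_panel()] result.
#' @param test descriptor table containing the panel's feature columns.
#' @param threshold integer vote threshold or `"fractional"`.
#' @return an object of class `panel_result`: data.frame `votes` (id,
#'   votes, selected) plus the full per-member vote matrix.
#' @export
panel_screen <- function(panel, test, threshold = 10L) {
  miss <- setdiff(panel$features, names(test))
  if (length(miss)) stop("test table lacks feature column(s): ",
                         paste(miss, collapse = ", "))
  E <- length(panel$members)
  t_eff <- if (identical(threshold, "fractional")) {
    as.integer(ceiling(0.71 * E))
  } else as.integer(threshold)
  x <- as.matrix(test[, panel$features, drop = FALSE])
  vote_mat <- vapply(panel$members, function(m) {
    as.integer(panel$predict_prob(m, x) >= 0.5)
  }, integer(nrow(x)))
  vote_mat <- matrix(vote_mat, nrow = nrow(x))
  v <- as.integer(rowSums(vote_mat))
  structure(list(
    votes = data.frame(id = test$id, votes = v, selected = v >= t_eff,
                       stringsAsFactors = FALSE),
    vote_matrix = vote_mat,
    threshold = t_eff,
    ensemble_size = E), class = "panel_result")
}

#' @export
print.panel_result <- function(x, ...) {
  cat(sprintf("<panel_result: %d compounds, %d selected (>= %d of %d votes)>\n",
              nrow(x$votes), sum(x$votes$selected), x$threshold,
              x$ensemble_size))
  invisible(x)
}

#' Write panel votes / per-set metrics as CSV
#' @param result a `panel_result` (or `trained_panel` for metrics).
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_panel_csv <- function(result, path) {
  write.csv(result$votes, path, row.names = FALSE)
  invisible(path)
}
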