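CLASSIFIER_FAMILIES <- c("svm_linear", "svm_rbf", "svm_sigmoid", "linear_svc",
                         "lda", "decision_tree", "random_forest")

#' Enumerate non-empty feature subsets
#'
#' All `2^b - 1` non-empty subsets of `b` features, in deterministic order:
#' by subset size, then lexicographically within a size (positions in the
#' input order).
#'
#' @param feature_names character vector, `1 <= length <= 20`.
#' @return list of character vectors.
#' @export
enumerate_feature_subsets <- function(feature_names) {
  b <- length(feature_names)
  if (b < 1L) stop("empty feature list")
  if (b > 20L) stop("too many features to enumerate exhaustively")
  out <- list()
  for (size in seq_len(b)) {
    cmb <- combn(b, size)
    out <- c(out, lapply(seq_len(ncol(cmb)),
                         function(j) feature_names[cmb[, j]]))
  }
  out
}

#' Stratified cross-validation folds
#'
#' Partitions the rows into `k` test folds. With `grouping = "none"` the folds
#' are stratified by difficulty so every class appears in every training set;
#' with `grouping = "subject"` whole subjects are assigned to folds, which
#' prevents subject-identity leakage between train and test.
#'
#' @param data data.frame with `difficulty` (and `subject_id` when grouping).
#' @param k number of folds (default 5).
#' @param seed integer seed; identical seeds give identical folds.
#' @param grouping `"none"` (default) or `"subject"`.
#' @return list of `k` lists with integer `train` and `test` row indices; the
#'   test sets partition `seq_len(nrow(data))`.
#' @export
make_folds <- function(data, k = 5L, seed = 1L,
                       grouping = c("none", "subject")) {
  grouping <- match.arg(grouping)
  n <- nrow(data)
  if (k < 2L) stop("k must be >= 2")
  if (k > n) stop("more folds than rows")
  fold_of <- integer(n)
  with_seed(seed, {
    if (grouping == "none") {
      # deal class-ordered rows into folds in one continuing cycle: each class
      # is split as evenly as possible AND fold totals differ by at most one
      # (exactly n/k rows per test fold when k divides n)
      pool <- unlist(lapply(split(seq_len(n), data$difficulty), sample),
                     use.names = FALSE)
      fold_of[pool] <- rep_len(seq_len(k), n)
    } else {
      subj <- unique(data$subject_id)
      subj_fold <- setNames(rep_len(seq_len(k), length(subj)), sample(subj))
      fold_of <- unname(subj_fold[data$subject_id])
    }
  })
  lapply(seq_len(k), function(f) {
    list(train = which(fold_of != f), test = which(fold_of == f))
  })
}

# median-heuristic RBF bandwidth: gamma = 1 / (2 * median pairwise sq.dist)
median_gamma <- function(x) {
  d2 <- as.numeric(stats::dist(x))^2
  m <- median(d2[d2 > 0])
  if (!is.finite(m) || m <= 0) return(1 / ncol(x))
  1 / (2 * m)
}

# fit one classifier family on standardized-or-raw training data, return a
# prediction closure. Margin-based and LDA families standardize with the
# training-fold statistics; tree families use raw features.
fit_classifier <- function(family, x_train, y_train, seed = 1L) {
  scale_based <- family %in% c("svm_linear", "svm_rbf", "svm_sigmoid",
                               "linear_svc", "lda")
  ctr <- 0; scl <- 1
  if (scale_based) {
    ctr <- colMeans(x_train)
    scl <- apply(x_train, 2L, sd)
    scl[scl == 0 | !is.finite(scl)] <- 1
    x_train <- sweep(sweep(x_train, 2L, ctr), 2L, scl, "/")
  }
  prep <- function(x) {
    if (scale_based) sweep(sweep(x, 2L, ctr), 2L, scl, "/") else x
  }
  lv <- levels(y_train)
  model <- switch(
    family,
    svm_linear = e1071::svm(x_train, y_train, kernel = "linear", cost = 1,
                            scale = FALSE),
    svm_rbf = e1071::svm(x_train, y_train, kernel = "radial",
                         gamma = median_gamma(x_train), cost = 1,
                         scale = FALSE),
    svm_sigmoid = e1071::svm(x_train, y_train, kernel = "sigmoid", cost = 1,
                             scale = FALSE),
    linear_svc = { # one-vs-rest linear SVMs, predict by max decision value
      lapply(lv, function(cl) {
        yy <- factor(ifelse(y_train == cl, cl, "rest"), levels = c(cl, "rest"))
        e1071::svm(x_train, yy, kernel = "linear", cost = 1, scale = FALSE)
      })
    },
    lda = MASS::lda(x_train, grouping = y_train),
    decision_tree = {
      df <- data.frame(x_train, y = y_train)
      rpart::rpart(y ~ ., data = df, method = "class",
                   control = rpart::rpart.control(minsplit = 2L,
                                                  minbucket = 1L,
                                                  cp = 0, xval = 0L))
    },
    random_forest = ranger::ranger(
      x = as.data.frame(x_train), y = y_train, num.trees = 100L,
      num.threads = 1L, seed = seed),
    stop("unknown classifier family: ", family)
  )
  function(x_test) {
    x_test <- prep(x_test)
    switch(
      family,
      svm_linear = , svm_rbf = , svm_sigmoid = predict(model, x_test),
      linear_svc = {
        dv <- vapply(model, function(m) {
          d <- attr(predict(m, x_test, decision.values = TRUE),
                    "decision.values")
          # orient so larger = more like the positive (first) class
          if (grepl("^rest/", colnames(d)[1L])) -d[, 1L] else d[, 1L]
        }, numeric(nrow(x_test)))
        dv <- matrix(dv, nrow = nrow(x_test))
        factor(lv[max.col(dv, ties.method = "first")], levels = lv)
      },
      lda = predict(model, x_test)$class,
      decision_tree = predict(model, data.frame(x_test), type = "class"),
      random_forest = predict(model, data = as.data.frame(x_test),
                              num.threads = 1L)$predictions
    )
  }
}

# per-class precision/recall and macro summaries from a pooled confusion
# matrix (rows = truth, cols = predicted)
confusion_metrics <- function(cm) {
  tp <- diag(cm)
  prec <- ifelse(colSums(cm) > 0, tp / colSums(cm), 0)
  rec <- ifelse(rowSums(cm) > 0, tp / rowSums(cm), 0)
  macro_p <- mean(prec)
  macro_r <- mean(rec)
  f1_hm <- if (macro_p + macro_r > 0) {
    2 * macro_p * macro_r / (macro_p + macro_r)
  } else 0
  per_class_f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  list(per_class_precision = prec, per_class_recall = rec,
       macro_precision = macro_p, macro_recall = macro_r,
       macro_f1 = f1_hm, macro_f1_per_class = mean(per_class_f1))
}

#' Cross-validated evaluation of one classifier on one feature subset
#'
#' Stratified k-fold cross-validation; per-fold test predictions are pooled
#' into a single confusion matrix from which per-class precision and recall
#' are computed. Macro precision/recall are unweighted class means and the
#' reported F1 is their harmonic mean (a macro average of per-class F1 scores
#' is emitted alongside). Fold-averaged macro F1 is also reported.
#'
#' @param features feature table with a `difficulty` column.
#' @param family one of `svm_linear`, `svm_rbf`, `svm_sigmoid`, `linear_svc`,
#'   `lda`, `decision_tree`, `random_forest`.
#' @param subset character vector of feature columns to use.
#' @param k folds (default 5).
#' @param seed fold/forest seed.
#' @param grouping passed to [make_folds()].
#' @return one-row data.frame (`model_report`): family, subset, per-class
#'   precision/recall, macro precision/recall, `macro_f1`,
#'   `macro_f1_per_class`, `macro_f1_fold_mean`, `n`.
#' @export
evaluate_model <- function(features, family, subset, k = 5L, seed = 1L,
                           grouping = c("none", "subject")) {
  grouping <- match.arg(grouping)
  stopifnot(family %in% CLASSIFIER_FAMILIES,
            all(subset %in% names(features)), length(subset) > 0L)
  y <- factor(features$difficulty, levels = DIFFICULTY_LEVELS)
  if (any(table(y) < k)) stop("need at least k rows per class")
  x <- as.matrix(features[, subset, drop = FALSE])
  folds <- make_folds(features, k = k, seed = seed, grouping = grouping)
  pred <- factor(rep(NA_character_, length(y)), levels = levels(y))
  fold_f1 <- numeric(length(folds))
  for (i in seq_along(folds)) {
    fl <- folds[[i]]
    if (length(unique(y[fl$train])) < 3L) {
      stop("a class is absent from a training fold")
    }
    predict_fun <- fit_classifier(family, x[fl$train, , drop = FALSE],
                                  y[fl$train], seed = seed + i)
    pred[fl$test] <- predict_fun(x[fl$test, , drop = FALSE])
    fold_f1[i] <- confusion_metrics(table(y[fl$test], pred[fl$test]))$macro_f1
  }
  met <- confusion_metrics(table(y, pred))
  data.frame(family = family, subset = paste(subset, collapse = "+"),
             n_features = length(subset),
             prec_low = met$per_class_precision[["low"]],
             prec_medium = met$per_class_precision[["medium"]],
             prec_high = met$per_class_precision[["high"]],
             rec_low = met$per_class_recall[["low"]],
             rec_medium = met$per_class_recall[["medium"]],
             rec_high = met$per_class_recall[["high"]],
             macro_precision = met$macro_precision,
             macro_recall = met$macro_recall,
             macro_f1 = met$macro_f1,
             macro_f1_per_class = met$macro_f1_per_class,
             macro_f1_fold_mean = mean(fold_f1),
             n = length(y),
             stringsAsFactors = FALSE)
}

#' Exhaustive wrapper feature selection
#'
#' Evaluates every classifier family on every non-empty subset of the feature
#' set (7 families x 127 subsets = 889 evaluations for the default seven
#' features) and ranks the reports by pooled macro F1, breaking ties by fewer
#' features and then by subset order.
#'
#' @param features feature table from [extract_feature_table()].
#' @param families classifier families to include (default all seven).
#' @param feature_names candidate features (default the seven).
#' @param k,seed,grouping passed to [evaluate_model()].
#' @return object of class `wrapper_search`: `reports` (ranked data.frame with
#'   a `rank` column), `k`, `seed`, `grouping`.
#' @export
wrapper_search <- function(features, families = CLASSIFIER_FAMILIES,
                           feature_names = FEATURE_NAMES, k = 5L, seed = 1L,
                           grouping = c("none", "subject")) {
  grouping <- match.arg(grouping)
  stopifnot(length(unique(features$difficulty)) >= 2L)
  subsets <- enumerate_feature_subsets(feature_names)
  subset_order <- seq_along(subsets)
  grid <- expand.grid(si = subset_order, family = families,
                      stringsAsFactors = FALSE)
  reports <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    rep_i <- evaluate_model(features, grid$family[i],
                            subsets[[grid$si[i]]], k = k, seed = seed,
                            grouping = grouping)
    rep_i$subset_order <- grid$si[i]
    reports[[i]] <- rep_i
  }
  reports <- do.call(rbind, reports)
  ord <- order(-reports$macro_f1, reports$n_features, reports$subset_order)
  reports <- reports[ord, , drop = FALSE]
  reports$rank <- seq_len(nrow(reports))
  rownames(reports) <- NULL
  structure(list(reports = reports, k = k, seed = seed, grouping = grouping),
            class = "wrapper_search")
}

#' @export
print.wrapper_search <- function(x, n = 10L, ...) {
  cat(sprintf("<wrapper_search> %d evaluations (%d-fold CV, seed %d)\n",
              nrow(x$reports), x$k, x$seed))
  cat(sprintf("top %d by macro F1 (pooled confusion matrix):\n", n))
  cols <- c("rank", "family", "subset", "prec_low", "prec_medium",
            "prec_high", "macro_precision", "macro_recall", "macro_f1")
  top <- head(x$reports[, cols], n)
  for (cc in cols[4:9]) top[[cc]] <- round(top[[cc]], 2)
  print(top, row.names = FALSE)
  invisible(x)
}
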