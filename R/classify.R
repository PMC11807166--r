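# Final-stage KNN classifier and the evaluation machinery: confusion
# matrix, accuracy, per-class and macro precision/recall/F1, and the
# Wilcoxon rank-sum harness for comparing repeated feature-selection runs.

#' K-nearest-neighbor prediction
#'
#' Labels each query row by majority vote among its `k` Euclidean-nearest
#' training rows. Vote ties are broken by the smaller mean neighbor
#' distance, then by the lowest class index (factor level order), so
#' predictions are deterministic.
#'
#' @param train_x numeric matrix of training rows.
#' @param train_y class labels, one per training row.
#' @param query_x numeric matrix in the same feature space.
#' @param k neighbor count, `1 <= k <= nrow(train_x)`.
#' @return factor of predicted labels with the training levels.
#' @export
knn_predict <- function(train_x, train_y, query_x, k = 5L) {
  train_x <- as.matrix(train_x)
  query_x <- as.matrix(query_x)
  train_y <- factor(train_y)
  if (ncol(train_x) != ncol(query_x)) {
    stop("invalid input: train and query feature spaces differ (",
         ncol(train_x), " vs ", ncol(query_x), " columns)", call. = FALSE)
  }
  if (k < 1L || k > nrow(train_x)) {
    stop("invalid argument: k must lie in [1, n_train]", call. = FALSE)
  }
  # squared Euclidean cross-distances, queries in rows
  d2 <- outer(rowSums(query_x^2), rowSums(train_x^2), "+") -
    2 * query_x %*% t(train_x)
  d2[d2 < 0] <- 0
  lev <- levels(train_y)
  pred <- character(nrow(query_x))
  for (i in seq_len(nrow(query_x))) {
    nb <- order(d2[i, ])[seq_len(k)]   # stable order: index breaks distance ties
    votes <- table(factor(train_y[nb], levels = lev))
    top <- which(votes == max(votes))
    if (length(top) > 1L) {
      mean_d <- vapply(top, function(cl) {
        mean(d2[i, nb[as.integer(train_y[nb]) == cl]])
      }, numeric(1))
      top <- top[order(mean_d, top)][1L]
    }
    pred[i] <- lev[top]
  }
  factor(pred, levels = lev)
}

#' Classification report
#'
#' Confusion matrix (true classes in rows, predicted in columns),
#' accuracy, one-vs-rest precision/recall/F1 per class and their macro
#' (unweighted) averages. A class with zero predicted (or actual)
#' positives gets precision (recall) 0 with a warning, the standard safe
#' convention.
#'
#' @param true_labels,predicted_labels equal-length label vectors.
#' @return object of class `classification_report`: `confusion`,
#'   `accuracy`, `per_class` (data.frame with precision, recall, f1,
#'   support per class) and `macro` (list of averaged metrics).
#' @export
evaluate <- function(true_labels, predicted_labels) {
  if (length(true_labels) == 0L) {
    stop("invalid input: empty label vectors", call. = FALSE)
  }
  if (length(true_labels) != length(predicted_labels)) {
    stop("invalid input: label vectors differ in length", call. = FALSE)
  }
  lev <- sort(unique(c(as.character(true_labels),
                       as.character(predicted_labels))))
  tr <- factor(as.character(true_labels), levels = lev)
  pr <- factor(as.character(predicted_labels), levels = lev)
  confusion <- table(true = tr, predicted = pr)
  total <- length(tr)
  accuracy <- sum(diag(confusion)) / total

  per_class <- data.frame(class = lev, precision = NA_real_,
                          recall = NA_real_, f1 = NA_real_,
                          support = NA_integer_, stringsAsFactors = FALSE)
  for (i in seq_along(lev)) {
    tp <- confusion[i, i]
    fp <- sum(confusion[, i]) - tp
    fn <- sum(confusion[i, ]) - tp
    if (tp + fp == 0) {
      warning("class '", lev[i], "': no predicted positives; precision set to 0",
              call. = FALSE)
      precision <- 0
    } else precision <- tp / (tp + fp)
    if (tp + fn == 0) {
      warning("class '", lev[i], "': no actual positives; recall set to 0",
              call. = FALSE)
      recall <- 0
    } else recall <- tp / (tp + fn)
    f1 <- if (precision + recall == 0) 0 else
      2 * precision * recall / (precision + recall)
    per_class[i, c("precision", "recall", "f1")] <- c(precision, recall, f1)
    per_class$support[i] <- as.integer(sum(confusion[i, ]))
  }
  structure(
    list(confusion = confusion, accuracy = accuracy, per_class = per_class,
         macro = list(precision = mean(per_class$precision),
                      recall = mean(per_class$recall),
                      f1 = mean(per_class$f1))),
    class = "classification_report"
  )
}

#' @export
print.classification_report <- function(x, ...) {
  cat("<classification_report> accuracy ",
      sprintf("%.4f", x$accuracy), "\n", sep = "")
  print(x$confusion)
  df <- x$per_class
  df[, 2:4] <- round(df[, 2:4], 4)
  print(df, row.names = FALSE)
  cat(sprintf("macro: precision %.4f  recall %.4f  F1 %.4f\n",
              x$macro$precision, x$macro$recall, x$macro$f1))
  invisible(x)
}

#' Train-and-evaluate KNN on a feature subset
#'
#' Fits KNN on the train split restricted to `selected` features and
#' reports metrics on `eval_split`. Features are standardized by
#' train-split mean/sd by default.
#'
#' @param ds a split [feature_dataset()].
#' @param selected 1-based feature indices (default: all features).
#' @param k neighbor count (default 5).
#' @param eval_split split to score on (default `"test"`).
#' @param standardize standardize by train statistics first.
#' @return a `classification_report`.
#' @export
knn_classify <- function(ds, selected = seq_len(ncol(ds$x)), k = 5L,
                         eval_split = "test", standardize = TRUE) {
  tr <- split_rows(ds, "train")
  ev <- split_rows(ds, eval_split)
  tx <- tr$x[, selected, drop = FALSE]
  ex <- ev$x[, selected, drop = FALSE]
  if (standardize) {
    mu <- colMeans(tx)
    sdv <- apply(tx, 2L, stats::sd)
    sdv[sdv == 0] <- 1
    tx <- sweep(sweep(tx, 2L, mu), 2L, sdv, "/")
    ex <- sweep(sweep(ex, 2L, mu), 2L, sdv, "/")
  }
  pred <- knn_predict(tx, tr$labels, ex, k)
  evaluate(as.character(ev$labels), as.character(pred))
}

#' Wilcoxon rank-sum comparison of repeated runs
#'
#' Two-sided rank-sum (Mann-Whitney) test on two samples of run
#' accuracies, the standard harness for asking whether two feature
#' selectors differ over repeated executions. Exact when both samples
#' have at most 8 runs and no ties; midranks with the normal
#' approximation (continuity-corrected) otherwise. The verdict uses a
#' 0.05 significance level.
#'
#' @param accuracies_a,accuracies_b numeric vectors with >= 2 runs each.
#' @param level significance level for the verdict (default 0.05).
#' @return object of class `rank_sum_test`: `statistic` (Mann-Whitney W
#'   for the first sample), `p_value`, `significant`, `method`.
#' @export
wilcoxon_rank_sum <- function(accuracies_a, accuracies_b, level = 0.05) {
  if (length(accuracies_a) < 2L || length(accuracies_b) < 2L) {
    stop("invalid input: both samples need at least 2 runs", call. = FALSE)
  }
  pooled <- c(accuracies_a, accuracies_b)
  if (length(unique(pooled)) == 1L) {
    stop("degenerate test: all values tied across both samples", call. = FALSE)
  }
  exact <- !any(duplicated(pooled)) &&
    max(length(accuracies_a), length(accuracies_b)) <= 8L
  ht <- suppressWarnings(
    stats::wilcox.test(accuracies_a, accuracies_b, exact = exact,
                       correct = TRUE)
  )
  structure(
    list(statistic = unname(ht$statistic), p_value = ht$p.value,
         significant = ht$p.value < level, level = level,
         method = if (exact) "exact" else "normal approximation, midranks"),
    class = "rank_sum_test"
  )
}

#' @export
print.rank_sum_test <- function(x, ...) {
  cat("<rank_sum_test> W = ", x$statistic, ", p = ",
      format(x$p_value, digits = 4), " (", x$method, ")\n",
      if (x$significant) "significant" else "not significant",
      " difference at level ", x$level, "\n", sep = "")
  invisible(x)
}
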