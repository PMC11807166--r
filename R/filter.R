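# mRMR filter scoring: relevance by one-way ANOVA F statistic, redundancy
# by mean absolute Pearson correlation with the already-selected set,
# greedy maximization of the quotient.

# Finite stand-in for an infinite F (zero within-class variance with a
# nonzero class effect): keeps perfectly separating features rankable.
F_CAP <- 1e12

#' One-way ANOVA F statistic of a feature against class labels
#'
#' Ratio of the between-class mean square to the within-class mean square.
#' Large values indicate a column whose class-conditional means are well
#' separated relative to the within-class spread.
#'
#' Conventions for degenerate inputs: a constant column has no class
#' effect and returns 0; a column with zero within-class variance but a
#' real class effect would have an infinite F and is capped at a large
#' finite constant (1e12) so that ranking still works.
#'
#' @param column numeric vector, one value per sample.
#' @param labels class labels, one per sample; at least 2 classes with at
#'   least 2 samples each.
#' @return nonnegative F statistic.
#' @export
f_statistic <- function(column, labels) {
  labels <- factor(labels)
  labels <- droplevels(labels)
  if (length(column) != length(labels)) {
    stop("column and labels differ in length", call. = FALSE)
  }
  if (nlevels(labels) < 2L) {
    stop("insufficient data: need at least 2 classes", call. = FALSE)
  }
  cnt <- table(labels)
  if (any(cnt < 2L)) {
    stop("insufficient data: every class needs at least 2 samples",
         call. = FALSE)
  }
  grand <- mean(column)
  means <- tapply(column, labels, mean)
  ssb <- sum(cnt * (means - grand)^2)
  ssw <- sum((column - means[as.integer(labels)])^2)
  df_b <- nlevels(labels) - 1L
  df_w <- length(column) - nlevels(labels)
  msb <- ssb / df_b
  msw <- ssw / df_w
  if (msb <= 0) return(0)
  if (msw <= 0) return(F_CAP)
  min(msb / msw, F_CAP)
}

#' Pearson product-moment correlation
#'
#' Standard Pearson correlation, with the convention that a constant
#' vector (zero variance) correlates 0 with anything: a constant feature
#' carries neither relevance nor redundancy signal.
#'
#' @param a,b numeric vectors of equal length >= 2.
#' @return correlation in \[-1, 1\].
#' @export
pearson_correlation <- function(a, b) {
  if (length(a) != length(b)) stop("vectors differ in length", call. = FALSE)
  if (length(a) < 2L) stop("need at least 2 observations", call. = FALSE)
  if (stats::sd(a) == 0 || stats::sd(b) == 0) return(0)
  stats::cor(a, b)
}

#' Greedy mRMR score vector
#'
#' Scores every feature by minimum-redundancy maximum-relevance with a
#' quotient objective. The first pick is the feature with the largest
#' relevance (one-way F statistic against the class labels) and its score
#' is that relevance. At iteration i > 1 every remaining feature f gets
#'
#'   score_i(f) = F(f, target) / mean(|corr(f, s)| for selected s)
#'
#' the maximizer is appended to the selection order and its score at the
#' moment of selection is recorded. Ties are broken by the lowest feature
#' index. If a feature is uncorrelated with everything selected so far the
#' denominator is floored at `epsilon` so that "high relevance, zero
#' redundancy" remains the best possible case.
#'
#' @param ds a [feature_dataset()].
#' @param split which rows to score on; defaults to the train split when a
#'   split assignment is present (test rows never enter feature scoring),
#'   otherwise all rows.
#' @param epsilon floor for the mean absolute correlation denominator.
#' @return object of class `filter_scores`: list with `scores`
#'   (per-feature mRMR score, in feature order), `selection_order`
#'   (greedy pick order, 1-based feature indices) and `relevance`
#'   (per-feature F statistic).
#' @export
mrmr_score_vector <- function(ds, split = NULL, epsilon = 1e-12) {
  stopifnot(inherits(ds, "feature_dataset"))
  d <- ncol(ds$x)
  if (d < 2L) stop("invalid input: need at least 2 features", call. = FALSE)
  if (is.null(split) && !is.null(ds$split)) split <- "train"
  if (is.null(split)) {
    x <- ds$x
    labels <- ds$labels
  } else {
    rows <- split_rows(ds, split)
    x <- rows$x
    labels <- rows$labels
  }

  relevance <- vapply(seq_len(d), function(j) f_statistic(x[, j], labels),
                      numeric(1))
  cmat <- abs(suppressWarnings(stats::cor(x)))
  cmat[!is.finite(cmat)] <- 0  # constant columns: zero redundancy signal

  selected <- integer(0)
  remaining <- seq_len(d)
  scores <- numeric(d)
  # which.max returns the first (lowest-index) maximizer: deterministic ties
  first <- remaining[which.max(relevance)]
  scores[first] <- relevance[first]
  selected <- first
  remaining <- setdiff(remaining, first)
  while (length(remaining) > 0L) {
    denom <- colMeans(cmat[selected, remaining, drop = FALSE])
    cand <- relevance[remaining] / pmax(denom, epsilon)
    pick <- remaining[which.max(cand)]
    scores[pick] <- cand[which.max(cand)]
    selected <- c(selected, pick)
    remaining <- setdiff(remaining, pick)
  }
  structure(list(scores = scores, selection_order = selected,
                 relevance = relevance),
            class = "filter_scores")
}

#' @export
print.filter_scores <- function(x, ...) {
  cat("<filter_scores> ", length(x$scores), " features; top picks: ",
      paste(utils::head(x$selection_order, 5L) - 1L, collapse = ", "),
      "\n", sep = "")
  invisible(x)
}
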