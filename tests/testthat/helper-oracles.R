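# Independent oracles, deliberately written along different code paths
# than the implementation they check.

# One-way ANOVA F via R's linear-model machinery.
oracle_f <- function(column, labels) {
  fit <- stats::anova(stats::lm(column ~ factor(labels)))
  fit[["F value"]][1L]
}

# Exhaustive greedy mRMR: plain loops, relevance from oracle_f,
# redundancy from stats::cor, same degenerate-input conventions as the
# contract (F cap 1e12, constant columns score 0, epsilon floor,
# lowest-index ties).
oracle_mrmr <- function(x, labels, epsilon = 1e-12, cap = 1e12) {
  d <- ncol(x)
  rel <- numeric(d)
  for (j in seq_len(d)) {
    if (stats::sd(x[, j]) == 0) {
      rel[j] <- 0
    } else {
      fj <- oracle_f(x[, j], labels)
      rel[j] <- if (!is.finite(fj)) cap else min(max(fj, 0), cap)
    }
  }
  order_sel <- integer(0)
  scores <- numeric(d)
  remaining <- seq_len(d)
  for (i in seq_len(d)) {
    best_val <- -Inf
    best_j <- NA_integer_
    for (j in remaining) {
      if (i == 1L) {
        val <- rel[j]
      } else {
        cors <- numeric(length(order_sel))
        for (m in seq_along(order_sel)) {
          s <- order_sel[m]
          cors[m] <- if (stats::sd(x[, j]) == 0 || stats::sd(x[, s]) == 0) 0
                     else abs(stats::cor(x[, j], x[, s]))
        }
        val <- rel[j] / max(mean(cors), epsilon)
      }
      if (val > best_val) {  # strict: first (lowest-index) maximizer wins
        best_val <- val
        best_j <- j
      }
    }
    order_sel <- c(order_sel, best_j)
    scores[best_j] <- best_val
    remaining <- setdiff(remaining, best_j)
  }
  list(selection_order = order_sel, scores = scores, relevance = rel)
}

# Brute-force KNN: per-query distance loop, sort, majority vote.
oracle_knn <- function(train_x, train_y, query_x, k) {
  train_y <- as.character(train_y)
  out <- character(nrow(query_x))
  for (i in seq_len(nrow(query_x))) {
    dist <- numeric(nrow(train_x))
    for (j in seq_len(nrow(train_x))) {
      dist[j] <- sqrt(sum((query_x[i, ] - train_x[j, ])^2))
    }
    nb <- train_y[order(dist)[seq_len(k)]]
    tab <- sort(table(nb), decreasing = TRUE)
    out[i] <- names(tab)[1L]
  }
  out
}

# Counting oracle for classification metrics: per-class loops over the
# raw label vectors, no confusion matrix.
oracle_report <- function(true, pred) {
  classes <- sort(unique(c(true, pred)))
  prec <- rec <- f1 <- numeric(length(classes))
  for (i in seq_along(classes)) {
    cl <- classes[i]
    tp <- sum(true == cl & pred == cl)
    fp <- sum(true != cl & pred == cl)
    fn <- sum(true == cl & pred != cl)
    prec[i] <- if (tp + fp == 0) 0 else tp / (tp + fp)
    rec[i] <- if (tp + fn == 0) 0 else tp / (tp + fn)
    f1[i] <- if (prec[i] + rec[i] == 0) 0 else
      2 * prec[i] * rec[i] / (prec[i] + rec[i])
  }
  list(accuracy = mean(true == pred), precision = prec, recall = rec,
       f1 = f1, macro_f1 = mean(f1))
}

# Exact two-sided rank-sum p-value by enumerating every assignment of the
# pooled ranks to the first sample (no ties assumed).
oracle_ranksum_p <- function(a, b) {
  n1 <- length(a)
  pooled <- c(a, b)
  ranks <- rank(pooled)
  w_obs <- sum(ranks[seq_len(n1)]) - n1 * (n1 + 1) / 2  # Mann-Whitney U
  combos <- utils::combn(length(pooled), n1)
  w_all <- apply(combos, 2L, function(idx) {
    sum(ranks[idx]) - n1 * (n1 + 1) / 2
  })
  p_le <- mean(w_all <= w_obs)
  p_ge <- mean(w_all >= w_obs)
  min(1, 2 * min(p_le, p_ge))
}

# Small planted dataset used across tests.
make_planted <- function(seed, n = 120, k = 3, n_inf = 4, n_red = 2,
                         n_noise = 18, sep = 5) {
  split_dataset(
    generate_dataset(synthetic_spec(
      n_samples = n, n_classes = k, n_informative = n_inf,
      n_redundant = n_red, n_noise = n_noise, class_separation = sep,
      seed = seed)),
    seed = seed)
}

# Random unstructured dataset for oracle-equivalence property tests.
random_dataset <- function(seed) {
  set.seed(seed)
  n <- sample(10:50, 1)
  d <- sample(2:8, 1)
  k <- sample(2:3, 1)
  labels <- rep(paste0("c", seq_len(k)), length.out = n)
  x <- matrix(rnorm(n * d), n, d)
  # plant mild signal in a random subset of columns so relevance varies
  for (j in sample(d, sample(0:d, 1))) {
    x[, j] <- x[, j] + as.integer(factor(labels)) * runif(1, 0, 2)
  }
  feature_dataset(x, labels)
}
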