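test_that("knn_predict matches a brute-force neighbor search", {
  # 6 hand-placed 2-D points, 2 classes, k = 3
  train_x <- rbind(c(0, 0), c(1, 0), c(0, 1), c(5, 5), c(6, 5), c(5, 6))
  train_y <- rep(c("a", "b"), each = 3)
  query <- rbind(c(0.2, 0.2), c(5.5, 5.5), c(2.4, 2.4), c(-1, -1))
  pred <- knn_predict(train_x, train_y, query, k = 3)
  expect_identical(as.character(pred),
                   oracle_knn(train_x, train_y, query, 3))

  # zero distance wins at k = 1
  expect_identical(as.character(knn_predict(train_x, train_y,
                                            train_x[4, , drop = FALSE], 1)),
                   "b")
  # k = n_train: the globally most frequent label everywhere
  train_y2 <- c("a", "a", "a", "b", "b", "a")
  pred_all <- knn_predict(train_x, train_y2, query, k = 6)
  expect_true(all(pred_all == "a"))
  expect_error(knn_predict(train_x, train_y, query, k = 7), "k must")
  expect_error(knn_predict(train_x, train_y, query[, 1, drop = FALSE], 3),
               "feature spaces")
})

test_that("knn_predict at k = 1 reproduces the training labels", {
  set.seed(4)
  x <- matrix(rnorm(40), 20, 2)
  y <- rep(c("a", "b"), 10)
  expect_identical(as.character(knn_predict(x, y, x, 1)), y)
})

test_that("knn vote ties break by mean neighbor distance then class order", {
  # query equidistant from one "a" and one far-but-tied... construct a
  # 2-vote tie at k = 2: nearer neighbor is class b
  train_x <- rbind(c(1, 0), c(2, 0))
  train_y <- c("b", "a")
  pred <- knn_predict(train_x, train_y, rbind(c(0, 0)), k = 2)
  expect_identical(as.character(pred), "b")
  # equal distances: lowest class index (alphabetical level) wins
  train_x2 <- rbind(c(1, 0), c(-1, 0))
  pred2 <- knn_predict(train_x2, c("b", "a"), rbind(c(0, 0)), k = 2)
  expect_identical(as.character(pred2), "a")
})

test_that("evaluate reproduces the binary worked example exactly", {
  # TP=3, FP=1, FN=2, TN=4 for class "pos"
  true <- c(rep("pos", 5), rep("neg", 5))
  pred <- c("pos", "pos", "pos", "neg", "neg",
            "pos", "neg", "neg", "neg", "neg")
  rep_ <- evaluate(true, pred)
  pos <- rep_$per_class[rep_$per_class$class == "pos", ]
  expect_equal(pos$precision, 0.75)
  expect_equal(pos$recall, 0.6)
  expect_equal(pos$f1, 2 / 3)
  expect_equal(rep_$accuracy, 0.7)
  expect_equal(sum(rep_$confusion), 10)
})

test_that("perfect predictions give a diagonal confusion matrix", {
  true <- rep(c("x", "y", "z"), each = 4)
  rep_ <- evaluate(true, true)
  expect_equal(rep_$accuracy, 1)
  expect_true(all(rep_$per_class$f1 == 1))
  expect_equal(sum(rep_$confusion) - sum(diag(rep_$confusion)), 0)
})

test_that("macro F1 is invariant under class relabeling", {
  set.seed(9)
  true <- sample(c("a", "b", "c"), 30, replace = TRUE)
  pred <- sample(c("a", "b", "c"), 30, replace = TRUE)
  map <- c(a = "z", b = "x", c = "y")
  r1 <- suppressWarnings(evaluate(true, pred))
  r2 <- suppressWarnings(evaluate(map[true], map[pred]))
  expect_equal(r1$macro$f1, r2$macro$f1)
  expect_equal(r1$accuracy, r2$accuracy)
})

test_that("evaluate matches the counting oracle on exhaustive small cases", {
  classes <- c("a", "b", "c")
  for (len in 1:3) {
    grid <- do.call(expand.grid, c(rep(list(classes), 2 * len),
                                   stringsAsFactors = FALSE))
    for (i in seq_len(nrow(grid))) {
      true <- as.character(grid[i, 1:len])
      pred <- as.character(grid[i, (len + 1):(2 * len)])
      got <- suppressWarnings(evaluate(true, pred))
      want <- oracle_report(true, pred)
      expect_equal(got$accuracy, want$accuracy)
      expect_equal(got$per_class$precision, want$precision)
      expect_equal(got$per_class$recall, want$recall)
      expect_equal(got$per_class$f1, want$f1)
    }
  }
  expect_error(evaluate(character(0), character(0)), "empty")
  expect_error(evaluate(c("a", "b"), "a"), "length")
})

test_that("rank-sum harness agrees with exact permutation enumeration", {
  # identical samples: no evidence of a difference
  a <- c(0.91, 0.93, 0.95, 0.97)
  r <- wilcoxon_rank_sum(a, a)
  expect_gte(r$p_value, 0.05)
  expect_false(r$significant)

  # completely separated small samples: exact tail probability
  lo <- c(0.80, 0.81, 0.82, 0.83)
  hi <- c(0.90, 0.91, 0.92, 0.93)
  r2 <- wilcoxon_rank_sum(lo, hi)
  expect_equal(r2$p_value, oracle_ranksum_p(lo, hi))
  expect_equal(r2$p_value, 2 / choose(8, 4))
  expect_true(r2$significant)

  # random tie-free small samples against the enumeration oracle
  set.seed(10)
  for (i in 1:5) {
    x <- round(runif(5), 6)
    y <- round(runif(6) + 0.2, 6)
    expect_equal(wilcoxon_rank_sum(x, y)$p_value, oracle_ranksum_p(x, y))
  }

  # rank statistic is shift-invariant
  r3 <- wilcoxon_rank_sum(lo + 5, hi + 5)
  expect_equal(r3$statistic, r2$statistic)
  expect_equal(r3$p_value, r2$p_value)

  expect_error(wilcoxon_rank_sum(rep(1, 5), rep(1, 5)), "degenerate")
  expect_error(wilcoxon_rank_sum(1, c(1, 2)), "2 runs")
})

test_that("separated 15 vs 15 samples are declared significant", {
  set.seed(11)
  a <- rnorm(15, 0.95, 0.005)
  b <- rnorm(15, 0.90, 0.005)
  r <- wilcoxon_rank_sum(a, b)
  expect_lt(r$p_value, 0.05)
  expect_true(r$significant)
})

test_that("knn_classify evaluates a feature subset end to end", {
  ds <- make_planted(21)
  rep_sel <- knn_classify(ds, which(ds$feature_roles == "informative"))
  expect_s3_class(rep_sel, "classification_report")
  expect_gte(rep_sel$accuracy, 0.9)
  # accuracy equals the diagonal mean identity
  expect_equal(rep_sel$accuracy,
               sum(diag(rep_sel$confusion)) / sum(rep_sel$confusion))
})
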