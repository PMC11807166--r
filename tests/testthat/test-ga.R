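# Builds a tiny dataset where wrapper-mode KNN accuracy is known exactly:
# two clusters at -5 and +5 on the two signal columns (5 train points
# each), `pad` all-zero padding columns, and a val split whose points sit
# on the clusters; `n_wrong` val points carry the opposite label.
two_cluster_ds <- function(pad = 0, n_wrong = 0, n_val = 10) {
  centers <- rep(c(-5, 5), each = 5)
  train_x <- cbind(centers, centers)
  train_y <- rep(c("a", "b"), each = 5)
  val_center <- rep(c(-5, 5), length.out = n_val)
  val_x <- cbind(val_center, val_center)
  val_y <- ifelse(val_center < 0, "a", "b")
  if (n_wrong > 0) val_y[seq_len(n_wrong)] <- ifelse(
    val_y[seq_len(n_wrong)] == "a", "b", "a")
  x <- rbind(train_x, val_x)
  if (pad > 0) x <- cbind(x, matrix(0, nrow(x), pad))
  feature_dataset(x, c(train_y, val_y),
                  split = rep(c("train", "val"), c(10, n_val)))
}

test_that("initial population has varied subset sizes and is repairable", {
  cfg <- ga_config(population_size = 4, seed = 1)
  pop1 <- agafs:::with_seed(1, initialize_population(10, cfg))
  pop2 <- agafs:::with_seed(1, initialize_population(10, cfg))
  expect_identical(pop1, pop2)
  expect_true(all(vapply(pop1, sum, numeric(1)) >= 1))
  # d = 1: repair forces the only gene on
  pop <- agafs:::with_seed(2, initialize_population(
    1, ga_config(population_size = 6)))
  expect_true(all(vapply(pop, identical, logical(1), y = 1L)))
  # mixed-Bernoulli construction spreads popcounts widely
  big <- agafs:::with_seed(3, initialize_population(
    100, ga_config(population_size = 1000)))
  expect_gt(stats::sd(vapply(big, sum, numeric(1))), 15)
})

test_that("chromosome_score is the mean score over selected genes", {
  sc <- c(2, 9, 4)
  expect_equal(chromosome_score(c(0, 1, 0), sc), 9)
  expect_equal(chromosome_score(c(1, 1, 1), sc), 5)
  expect_equal(chromosome_score(c(1, 0, 1), sc), 3)
  expect_error(chromosome_score(c(0, 0, 0), sc), "empty")
})

test_that("wrapper fitness follows alpha * acc + (1 - alpha) * sparsity", {
  cfg <- ga_config(fitness_mode = "wrapper", alpha = 0.99, knn_k = 5)
  # acc = 1, all genes selected: sparsity 0 -> fitness alpha
  ds <- two_cluster_ds()
  expect_equal(fitness(c(1, 1), ds, NULL, cfg), 0.99)
  # acc = 0 (all val labels flipped), 1 of 100 genes selected
  ds0 <- two_cluster_ds(pad = 98, n_wrong = 10)
  genes <- c(1, rep(0, 99))
  expect_equal(fitness(genes, ds0, NULL, cfg), 0.01 * 99 / 100)
  # acc = 0.9, d = 10, 2 genes selected -> 0.99*0.9 + 0.01*0.8 = 0.899
  ds9 <- two_cluster_ds(pad = 8, n_wrong = 1)
  expect_equal(fitness(c(1, 1, rep(0, 8)), ds9, NULL, cfg), 0.899)
  # alpha = 0.99 is the shipped default
  expect_equal(ga_config()$alpha, 0.99)
  expect_error(fitness(c(1, 1), feature_dataset(matrix(1:4, 2), c("a", "b")),
                       NULL, cfg), "split")
})

test_that("filter fitness is bounded in [0, 1]", {
  set.seed(5)
  scores <- structure(list(scores = runif(12, 0, 50)), class = "filter_scores")
  cfg <- ga_config(fitness_mode = "filter")
  for (i in 1:50) {
    genes <- rbinom(12, 1, 0.5)
    if (sum(genes) == 0) genes[1] <- 1L
    f <- fitness(genes, NULL, scores, cfg)
    expect_gte(f, 0)
    expect_lte(f, 1)
  }
})

test_that("roulette selection frequencies match fitness proportions", {
  expect_identical(agafs:::with_seed(1, roulette_select(7)), 1L)
  expect_error(roulette_select(numeric(0)), "empty")
  expect_error(roulette_select(c(1, Inf)), "finite")
  # equal fitnesses: uniform within chi-square tolerance
  draws <- agafs:::with_seed(2, roulette_select(rep(2.5, 4), n = 1e5))
  counts <- tabulate(draws, 4)
  chisq <- sum((counts - 25000)^2 / 25000)
  expect_lt(chisq, stats::qchisq(0.999, df = 3))
  # fitnesses (1, 3): P(first) = 0.25 within 3 binomial sd
  draws <- agafs:::with_seed(3, roulette_select(c(1, 3), n = 1e5))
  p1 <- mean(draws == 1L)
  expect_lt(abs(p1 - 0.25), 3 * sqrt(0.25 * 0.75 / 1e5))
  # negative fitnesses are shifted onto a valid wheel: with eps = 1 the
  # weights become (1, 4), so both members are selectable at 1:4 odds
  draws <- agafs:::with_seed(4, roulette_select(c(-2, 1), n = 1e4, eps = 1))
  expect_setequal(unique(draws), c(1L, 2L))
  expect_lt(abs(mean(draws == 1L) - 0.2), 4 * sqrt(0.2 * 0.8 / 1e4))
})

test_that("crossover swaps per gene and conserves per-position values", {
  p1 <- c(1L, 1L, 0L, 0L, 1L)
  p2 <- c(1L, 0L, 1L, 0L, 0L)
  kids <- agafs:::with_seed(1, crossover(p1, p2, 0))
  expect_identical(kids, list(p1, p2))
  kids <- agafs:::with_seed(1, crossover(p1, p2, 1))
  expect_identical(kids, list(p2, p1))
  # per-position conservation for any probability (parents share gene 1,
  # so repair never triggers)
  for (seed in 1:20) {
    prob <- runif(1)
    kids <- agafs:::with_seed(seed, crossover(p1, p2, prob))
    for (j in seq_along(p1)) {
      expect_setequal(c(kids[[1]][j], kids[[2]][j]), c(p1[j], p2[j]))
    }
  }
  expect_error(crossover(c(1, 0), c(1, 0, 1), 0.5), "length")
})

test_that("k-point crossover also conserves per-position values", {
  p1 <- rep(c(1L, 0L), 10)
  p2 <- rep(c(1L, 1L, 0L, 0L), 5)
  for (seed in 1:10) {
    kids <- agafs:::with_seed(seed, crossover(p1, p2, 1, type = "kpoint",
                                              n_points = 3))
    for (j in seq_along(p1)) {
      expect_setequal(c(kids[[1]][j], kids[[2]][j]), c(p1[j], p2[j]))
    }
  }
})

test_that("the mutation schedule interpolates linearly between its endpoints", {
  cfg <- ga_config()  # min 0.01, max 0.04 over 60 iterations
  expect_equal(mutation_prob_at(0, cfg), 0.01)
  expect_equal(mutation_prob_at(59, cfg), 0.04)
  cfg5 <- ga_config(max_iterations = 5)
  expect_equal(mutation_prob_at(2, cfg5), (0.01 + 0.04) / 2)
  expect_equal(mutation_prob_at(0, ga_config(max_iterations = 1)), 0.01)
  expect_error(mutation_prob_at(60, cfg), "iteration")
  expect_error(mutation_prob_at(-1, cfg), "iteration")
})

test_that("mutation flips at the requested rate", {
  genes <- rep(c(1L, 0L), 10)
  expect_identical(agafs:::with_seed(1, mutate(genes, 0)), genes)
  expect_identical(agafs:::with_seed(1, mutate(genes, 1)), rep(c(0L, 1L), 10))
  big <- rep(0L, 1e5)
  flipped <- agafs:::with_seed(2, mutate(big, 0.04))
  rate <- mean(flipped != big)
  expect_lt(abs(rate - 0.04), 3 * sqrt(0.04 * 0.96 / 1e5))
})

test_that("run_ga on a single feature returns the only feasible solution", {
  lab <- rep(c("a", "b"), each = 10)
  ds <- feature_dataset(matrix(rnorm(20), 20, 1), lab)
  res <- run_ga(ds, ga_config(max_iterations = 3, population_size = 4))
  expect_identical(res$best_chromosome, 1L)
  expect_identical(res$selected_indices, 1L)
})

test_that("run_ga trajectory is monotone and seed-deterministic", {
  ds <- make_planted(11)
  cfg <- ga_config(max_iterations = 15, population_size = 8, seed = 42)
  res1 <- run_ga(ds, cfg)
  res2 <- run_ga(ds, cfg)
  expect_identical(res1[setdiff(names(res1), "config")],
                   res2[setdiff(names(res2), "config")])
  expect_true(all(diff(res1$trajectory) >= 0))
  expect_equal(res1$best_fitness, res1$trajectory[length(res1$trajectory)])
  expect_identical(res1$selected_indices, which(res1$best_chromosome == 1L))
  expect_identical(res1$evaluations, 15L * 8L)
  # wrapper mode is deterministic too
  cfgw <- ga_config(max_iterations = 8, population_size = 6,
                    fitness_mode = "wrapper", seed = 9)
  resw1 <- run_ga(ds, cfgw)
  resw2 <- run_ga(ds, cfgw)
  expect_identical(resw1$best_chromosome, resw2$best_chromosome)
  expect_true(all(diff(resw1$trajectory) >= 0))
})

test_that("a pure-noise extension cannot improve the best filter fitness", {
  for (seed in 1:5) {
    ds <- make_planted(seed)
    cfg <- ga_config(max_iterations = 10, population_size = 8, seed = seed)
    res <- run_ga(ds, cfg)
    x_ext <- cbind(ds$x, noise = agafs:::with_seed(seed + 100,
                                                   rnorm(nrow(ds$x))))
    ds_ext <- feature_dataset(x_ext, ds$labels, split = ds$split)
    sc_ext <- mrmr_score_vector(ds_ext)
    base <- fitness(c(res$best_chromosome, 0L), ds_ext, sc_ext, cfg)
    extended <- fitness(c(res$best_chromosome, 1L), ds_ext, sc_ext, cfg)
    expect_lte(extended, base)
  }
})
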