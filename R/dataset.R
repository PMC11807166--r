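#' Labeled feature matrix container
#'
#' Bundles a numeric sample-by-feature matrix with one class label per row,
#' optional per-column roles (for synthetic benchmarks) and an optional
#' train/val/test split assignment.
#'
#' @param x numeric matrix, samples in rows, features in columns. Column
#'   names default to `f0..f{d-1}`.
#' @param labels vector of class labels, one per row of `x`; coerced to
#'   factor. At least two distinct classes are required.
#' @param feature_roles optional character vector, one of
#'   `"informative"`, `"redundant"`, `"noise"` per column.
#' @param split optional factor/character with levels `train`, `val`,
#'   `test`, one per row.
#' @param redundant_source optional integer vector naming, for each
#'   redundant column, the informative column it copies (parallel to the
#'   redundant entries of `feature_roles`).
#' @return an object of class `feature_dataset`: a list with elements
#'   `x`, `labels`, `feature_roles`, `split`, `redundant_source`.
#' @export
feature_dataset <- function(x, labels, feature_roles = NULL, split = NULL,
                            redundant_source = NULL) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (anyNA(x) || any(!is.finite(x))) {
    bad <- which(!is.finite(x), arr.ind = TRUE)[1L, ]
    stop("feature matrix contains a missing/non-finite value at row ",
         bad[1L], ", column ", bad[2L], call. = FALSE)
  }
  if (length(labels) != nrow(x)) {
    stop("length(labels) [", length(labels), "] != nrow(x) [", nrow(x), "]",
         call. = FALSE)
  }
  labels <- factor(labels)
  if (nlevels(labels) < 2L) {
    stop("labels must contain at least 2 classes", call. = FALSE)
  }
  if (is.null(colnames(x))) {
    colnames(x) <- paste0("f", seq_len(ncol(x)) - 1L)
  }
  if (!is.null(feature_roles)) {
    feature_roles <- as.character(feature_roles)
    stopifnot(length(feature_roles) == ncol(x),
              all(feature_roles %in% c("informative", "redundant", "noise")))
  }
  if (!is.null(split)) {
    split <- factor(as.character(split), levels = c("train", "val", "test"))
    if (anyNA(split) || length(split) != nrow(x)) {
      stop("split must tag every row as train, val or test", call. = FALSE)
    }
  }
  structure(
    list(x = x, labels = labels, feature_roles = feature_roles,
         split = split, redundant_source = redundant_source),
    class = "feature_dataset"
  )
}

#' @export
print.feature_dataset <- function(x, ...) {
  cat("<feature_dataset> ", nrow(x$x), " samples x ", ncol(x$x),
      " features, ", nlevels(x$labels), " classes\n", sep = "")
  if (!is.null(x$feature_roles)) {
    cat("  roles: ", paste(names(table(x$feature_roles)),
                           table(x$feature_roles),
                           sep = "=", collapse = ", "), "\n", sep = "")
  }
  if (!is.null(x$split)) {
    cat("  split: ", paste(names(table(x$split)), table(x$split),
                           sep = "=", collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Number of features of a dataset
#' @param ds a `feature_dataset`.
#' @return integer feature count.
#' @export
n_features <- function(ds) ncol(ds$x)

#' Subset a dataset to one split
#'
#' @param ds a `feature_dataset` with populated split assignment.
#' @param split one of `"train"`, `"val"`, `"test"`.
#' @return list with `x` (matrix) and `labels` (factor) for the rows
#'   tagged with `split`.
#' @export
split_rows <- function(ds, split = c("train", "val", "test")) {
  split <- match.arg(split)
  if (is.null(ds$split)) {
    stop("dataset has no split assignment; call split_dataset() first",
         call. = FALSE)
  }
  keep <- ds$split == split
  if (!any(keep)) {
    stop("dataset has no '", split, "' rows", call. = FALSE)
  }
  list(x = ds$x[keep, , drop = FALSE], labels = droplevels(ds$labels[keep]))
}

# Run `expr` under a temporary RNG state seeded with `seed`; the caller's
# global RNG stream is untouched.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Specification of a synthetic deep-feature benchmark
#'
#' Describes a labeled Gaussian feature matrix with planted structure:
#' class-informative columns, near-duplicate redundant copies of them, and
#' pure-noise columns. The defaults are the package's reference study
#' conditions: 300 samples, 3 classes, 64 features of which 8 are
#' informative at class separation 5 (in units of the within-class
#' standard deviation), 8 are redundant copies, and 48 are noise.
#'
#' @param n_samples positive sample count.
#' @param n_classes number of classes, at least 2.
#' @param n_informative number of class-informative columns (>= 1 unless
#'   `class_separation` is 0).
#' @param n_redundant number of near-duplicate copies of informative
#'   columns.
#' @param n_noise number of class-independent N(0,1) columns.
#' @param class_separation Euclidean distance between any two class mean
#'   vectors over each block of informative columns, in units of the
#'   within-class standard deviation (which is 1).
#' @param redundancy_noise_sd standard deviation of the Gaussian jitter
#'   added to a redundant copy.
#' @param class_weights optional positive weights, one per class, for
#'   unbalanced class sizes; defaults to balanced.
#' @param seed integer seed; generation is fully deterministic given the
#'   spec.
#' @return an object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_samples = 300L, n_classes = 3L,
                           n_informative = 8L, n_redundant = 8L,
                           n_noise = 48L, class_separation = 5,
                           redundancy_noise_sd = 0.1,
                           class_weights = NULL, seed = 1L) {
  n_samples <- as.integer(n_samples)
  n_classes <- as.integer(n_classes)
  n_informative <- as.integer(n_informative)
  n_redundant <- as.integer(n_redundant)
  n_noise <- as.integer(n_noise)
  if (n_samples < 1L) stop("invalid spec: n_samples must be >= 1", call. = FALSE)
  if (n_classes < 2L) stop("invalid spec: n_classes must be >= 2", call. = FALSE)
  if (n_informative < 0L || n_redundant < 0L || n_noise < 0L) {
    stop("invalid spec: feature counts must be nonnegative", call. = FALSE)
  }
  if (n_informative == 0L && class_separation > 0) {
    stop("invalid spec: class_separation > 0 requires n_informative >= 1",
         call. = FALSE)
  }
  if (n_informative == 0L && n_redundant > 0L) {
    stop("invalid spec: redundant columns need informative sources",
         call. = FALSE)
  }
  if (class_separation < 0 || redundancy_noise_sd < 0) {
    stop("invalid spec: separation and jitter sd must be nonnegative",
         call. = FALSE)
  }
  if (!is.null(class_weights)) {
    stopifnot(length(class_weights) == n_classes, all(class_weights > 0))
  }
  structure(
    list(n_samples = n_samples, n_classes = n_classes,
         n_informative = n_informative, n_redundant = n_redundant,
         n_noise = n_noise, class_separation = class_separation,
         redundancy_noise_sd = redundancy_noise_sd,
         class_weights = class_weights, seed = as.integer(seed)),
    class = "synthetic_spec"
  )
}

# Vertices of a regular simplex: k points in k-1 dimensions with unit
# pairwise Euclidean distance. Built by projecting the centered unit
# vectors e_1..e_k onto an orthonormal basis of the hyperplane
# orthogonal to 1, so the construction is deterministic.
simplex_vertices <- function(k) {
  if (k == 1L) return(matrix(0, 1L, 1L))
  q <- qr.Q(qr(cbind(rep(1, k), diag(k))))[, 2:k, drop = FALSE]
  diag(k) %*% q / sqrt(2)
}

#' Generate a synthetic labeled feature matrix
#'
#' Class means for the informative columns are vertices of a regular
#' simplex with pairwise distance `class_separation`; the simplex lives in
#' `n_classes - 1` dimensions and its coordinates are tiled cyclically
#' across the informative columns, so every informative column carries
#' class signal and each block of `n_classes - 1` consecutive informative
#' columns jointly encodes the full simplex. Within-class noise is N(0,1).
#' Redundant column j copies informative column `(j - 1) %% n_informative + 1`
#' plus N(0, `redundancy_noise_sd`^2) jitter. Noise columns are N(0,1),
#' independent of the class.
#'
#' @param spec a [synthetic_spec()].
#' @return a [feature_dataset()] with `feature_roles` and
#'   `redundant_source` populated; deterministic for a fixed spec.
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  k <- spec$n_classes
  d <- spec$n_informative + spec$n_redundant + spec$n_noise
  if (d < 1L) stop("invalid spec: at least one feature is required", call. = FALSE)

  w <- spec$class_weights
  if (is.null(w)) w <- rep(1, k)
  counts <- largest_remainder(spec$n_samples * w / sum(w), spec$n_samples)
  if (any(counts == 0L)) {
    stop("invalid spec: every class needs at least one sample", call. = FALSE)
  }
  labels <- factor(rep(paste0("class", seq_len(k)), counts),
                   levels = paste0("class", seq_len(k)))
  n <- spec$n_samples

  with_seed(spec$seed, {
    x <- matrix(0, n, d)
    if (spec$n_informative > 0L) {
      S <- simplex_vertices(k) * spec$class_separation
      for (j in seq_len(spec$n_informative)) {
        coord <- (j - 1L) %% ncol(S) + 1L
        mu <- S[as.integer(labels), coord]
        x[, j] <- mu + stats::rnorm(n)
      }
    }
    redundant_source <- NULL
    if (spec$n_redundant > 0L) {
      redundant_source <- integer(spec$n_redundant)
      for (j in seq_len(spec$n_redundant)) {
        src <- (j - 1L) %% spec$n_informative + 1L
        redundant_source[j] <- src
        x[, spec$n_informative + j] <-
          x[, src] + stats::rnorm(n, sd = spec$redundancy_noise_sd)
      }
    }
    if (spec$n_noise > 0L) {
      x[, spec$n_informative + spec$n_redundant + seq_len(spec$n_noise)] <-
        stats::rnorm(n * spec$n_noise)
    }
    roles <- rep(c("informative", "redundant", "noise"),
                 c(spec$n_informative, spec$n_redundant, spec$n_noise))
    feature_dataset(x, labels, feature_roles = roles,
                    redundant_source = redundant_source)
  })
}

# Integer allocation by the largest-remainder method: rounds `target`
# (nonnegative reals) to integers summing to `total`, each within 1 of
# its exact share.
largest_remainder <- function(target, total) {
  base <- floor(target)
  rem <- target - base
  short <- as.integer(round(total - sum(base)))
  if (short > 0L) {
    take <- order(rem, decreasing = TRUE)[seq_len(short)]
    base[take] <- base[take] + 1
  }
  as.integer(base)
}

#' Stratified train/val/test split
#'
#' Assigns every row to one of `train`, `val`, `test`, stratified by
#' class: within each class the rows are shuffled and allocated to the
#' three splits by the largest-remainder method, so per-class counts are
#' within one row of the exact proportions. The default fractions
#' (70/10/20) mirror a 70% train, 10% validation, 20% test design.
#'
#' @param ds a [feature_dataset()].
#' @param fractions three nonnegative reals `(train, val, test)` summing
#'   to 1.
#' @param seed integer seed for the within-class shuffle.
#' @return the dataset with `split` populated.
#' @export
split_dataset <- function(ds, fractions = c(train = 0.7, val = 0.1, test = 0.2),
                          seed = 1L) {
  stopifnot(inherits(ds, "feature_dataset"))
  if (length(fractions) != 3L || any(fractions < 0)) {
    stop("invalid argument: fractions must be 3 nonnegative reals", call. = FALSE)
  }
  if (abs(sum(fractions) - 1) > 1e-8) {
    stop("invalid argument: fractions must sum to 1 (got ",
         sum(fractions), ")", call. = FALSE)
  }
  n <- nrow(ds$x)
  if (any(fractions > 0 & fractions * n < 1)) {
    stop("invalid argument: each nonzero fraction must yield at least one row",
         call. = FALSE)
  }
  tags <- c("train", "val", "test")
  assignment <- character(n)
  with_seed(seed, {
    for (cl in levels(ds$labels)) {
      idx <- which(ds$labels == cl)
      idx <- idx[sample.int(length(idx))]
      counts <- largest_remainder(fractions * length(idx), length(idx))
      assignment[idx] <- rep(tags, counts)
    }
  })
  ds$split <- factor(assignment, levels = tags)
  ds
}
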