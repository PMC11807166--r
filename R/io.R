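# Delimited-text interchange, configuration files and the end-to-end
# pipeline driver (score -> select -> classify) with a reproducibility
# manifest.

#' Write a dataset as delimited text
#'
#' One header row; feature columns named `f0..f{d-1}`; final column
#' `label`; optional `split` column when a split assignment exists. An
#' optional sidecar records per-feature roles and redundant sources.
#'
#' @param ds a [feature_dataset()].
#' @param path output CSV path.
#' @param roles_path optional sidecar CSV path (`feature,role,source`).
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(ds, path, roles_path = NULL) {
  stopifnot(inherits(ds, "feature_dataset"))
  df <- as.data.frame(ds$x)
  names(df) <- paste0("f", seq_len(ncol(ds$x)) - 1L)
  df$label <- as.character(ds$labels)
  if (!is.null(ds$split)) df$split <- as.character(ds$split)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  if (!is.null(roles_path) && !is.null(ds$feature_roles)) {
    src <- rep(NA_integer_, ncol(ds$x))
    if (!is.null(ds$redundant_source)) {
      src[ds$feature_roles == "redundant"] <- ds$redundant_source - 1L
    }
    utils::write.csv(
      data.frame(feature = names(df)[seq_len(ncol(ds$x))],
                 role = ds$feature_roles, source = src),
      roles_path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Read a dataset from delimited text
#'
#' Expects a header row, numeric feature columns, a `label` column, and
#' optionally a `split` column (train/val/test). Missing or non-numeric
#' feature cells are rejected with the offending row and column named.
#'
#' @param path CSV path.
#' @param roles_path optional roles sidecar written by
#'   [write_feature_table()].
#' @return a [feature_dataset()].
#' @export
read_feature_table <- function(path, roles_path = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"label" %in% names(df)) {
    stop("parse error in '", path, "': no 'label' column", call. = FALSE)
  }
  labels <- df$label
  split <- NULL
  if ("split" %in% names(df)) split <- df$split
  feat <- df[, setdiff(names(df), c("label", "split")), drop = FALSE]
  if (ncol(feat) == 0L) {
    stop("parse error in '", path, "': no feature columns", call. = FALSE)
  }
  for (j in seq_along(feat)) {
    v <- feat[[j]]
    if (is.character(v)) {
      vn <- suppressWarnings(as.numeric(v))
      bad <- which(is.na(vn) & !is.na(v))
      if (length(bad) > 0L) {
        stop("parse error in '", path, "': non-numeric value '", v[bad[1L]],
             "' at row ", bad[1L], ", column '", names(feat)[j], "'",
             call. = FALSE)
      }
      feat[[j]] <- vn
    }
    if (anyNA(feat[[j]])) {
      stop("parse error in '", path, "': missing value at row ",
           which(is.na(feat[[j]]))[1L], ", column '", names(feat)[j], "'",
           call. = FALSE)
    }
  }
  roles <- NULL
  redundant_source <- NULL
  if (!is.null(roles_path)) {
    rdf <- utils::read.csv(roles_path, stringsAsFactors = FALSE)
    roles <- rdf$role
    if ("source" %in% names(rdf) && any(roles == "redundant")) {
      redundant_source <- rdf$source[roles == "redundant"] + 1L
    }
  }
  feature_dataset(as.matrix(feat), labels, feature_roles = roles,
                  split = split, redundant_source = redundant_source)
}

#' Write a filter score table
#'
#' Delimited text with one row per feature: 0-based feature index,
#' relevance (F statistic), mRMR score, and greedy selection rank.
#'
#' @param scores a `filter_scores` object.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_score_table <- function(scores, path) {
  stopifnot(inherits(scores, "filter_scores"))
  d <- length(scores$scores)
  rank <- integer(d)
  rank[scores$selection_order] <- seq_len(d)
  utils::write.csv(
    data.frame(feature = seq_len(d) - 1L, relevance = scores$relevance,
               mrmr_score = scores$scores, selection_rank = rank),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a GA configuration from a flat YAML file
#'
#' Keys mirror the [ga_config()] arguments (`population_size`,
#' `max_iterations`, `crossover_prob`, `min_mutation_prob`,
#' `max_mutation_prob`, `alpha`, `fitness_mode`, `knn_k`, `seed`, and the
#' optional `crossover_type`, `n_crossover_points`, `standardize`,
#' `epsilon`). Unknown keys are rejected.
#'
#' @param path YAML file path.
#' @return a validated `ga_config`.
#' @export
read_ga_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  allowed <- setdiff(names(formals(ga_config)), "")
  unknown <- setdiff(names(cfg), allowed)
  if (length(unknown) > 0L) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(ga_config, cfg)
}

#' Run the full pipeline: score, select, classify
#'
#' Executes the three stages with a shared seed, writing every stage
#' output plus a manifest into `out_dir`. The configuration is either a
#' YAML file or an equivalent list with entries:
#' \describe{
#'   \item{dataset}{path to a feature CSV, or}
#'   \item{synth}{a list of [synthetic_spec()] arguments;}
#'   \item{split}{optional list `train`/`val`/`test` fractions and `seed`
#'     (applied when the dataset carries no split column);}
#'   \item{ga}{list of [ga_config()] arguments;}
#'   \item{knn_k}{neighbor count for the final classifier (default 5);}
#'   \item{out_dir}{output directory (may also be given as the function
#'     argument).}
#' }
#' The whole configuration is validated before any stage runs. Input
#' files are never modified; all outputs (dataset echo, scores.csv,
#' result.json, report.json, manifest.json) go to the run directory.
#'
#' @param config YAML path or list as described.
#' @param out_dir output directory; overrides the config entry.
#' @return the manifest, invisibly, as a list.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  if (is.null(out_dir)) out_dir <- config$out_dir
  if (is.null(out_dir)) stop("out_dir is required", call. = FALSE)

  # validate everything up front: a bad config must fail before any stage
  ga_cfg <- do.call(ga_config, if (is.null(config$ga)) list() else config$ga)
  knn_k <- if (is.null(config$knn_k)) 5L else as.integer(config$knn_k)
  if (knn_k < 1L) stop("invalid config: knn_k must be >= 1", call. = FALSE)
  if (is.null(config$dataset) && is.null(config$synth)) {
    stop("config needs either 'dataset' (path) or 'synth' (spec)",
         call. = FALSE)
  }
  spec <- NULL
  if (!is.null(config$synth)) spec <- do.call(synthetic_spec, config$synth)

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(dataset = file.path(out_dir, "dataset.csv"),
                scores = file.path(out_dir, "scores.csv"),
                result = file.path(out_dir, "result.json"),
                report = file.path(out_dir, "report.json"),
                manifest = file.path(out_dir, "manifest.json"))

  input_digest <- NULL
  if (!is.null(spec)) {
    ds <- generate_dataset(spec)
  } else {
    ds <- read_feature_table(config$dataset)
    input_digest <- unname(tools::md5sum(config$dataset))
  }
  if (is.null(ds$split)) {
    sp <- config$split
    fractions <- c(train = 0.7, val = 0.1, test = 0.2)
    split_seed <- ga_cfg$seed
    if (!is.null(sp)) {
      if (!is.null(sp$train)) {
        fractions <- c(train = sp$train, val = sp$val, test = sp$test)
      }
      if (!is.null(sp$seed)) split_seed <- as.integer(sp$seed)
    }
    ds <- split_dataset(ds, fractions, seed = split_seed)
  }
  write_feature_table(ds, paths$dataset)
  if (is.null(input_digest)) input_digest <- unname(tools::md5sum(paths$dataset))

  res <- run_ga(ds, ga_cfg)
  write_score_table(res$scores, paths$scores)
  jsonlite::write_json(
    list(config = unclass(ga_cfg),
         selected_indices = res$selected_indices - 1L,
         n_selected = length(res$selected_indices),
         best_fitness = res$best_fitness, trajectory = res$trajectory,
         evaluations = res$evaluations, seed = ga_cfg$seed),
    paths$result, auto_unbox = TRUE, digits = NA)

  report <- knn_classify(ds, res$selected_indices, k = knn_k,
                         standardize = ga_cfg$standardize)
  jsonlite::write_json(
    list(confusion = as.vector(t(report$confusion)),
         classes = rownames(report$confusion),
         accuracy = report$accuracy,
         per_class = report$per_class, macro = report$macro),
    paths$report, auto_unbox = TRUE, digits = NA)

  manifest <- list(
    package_version = as.character(utils::packageVersion("agafs")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = list(ga = unclass(ga_cfg), knn_k = knn_k,
                  synth = if (is.null(spec)) NULL else unclass(spec)),
    seeds = list(ga = ga_cfg$seed,
                 synth = if (is.null(spec)) NULL else spec$seed),
    input_digest = input_digest,
    outputs = lapply(paths[c("dataset", "scores", "result", "report")],
                     function(p) list(path = basename(p),
                                      md5 = unname(tools::md5sum(p)))),
    summary = list(n_selected = length(res$selected_indices),
                   n_features = length(res$best_chromosome),
                   best_fitness = res$best_fitness,
                   test_accuracy = report$accuracy)
  )
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(manifest)
}
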