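#' Run configuration for the end-to-end pipeline
#'
#' @param mode `"batch_run"` (classify all test samples together) or
#'   `"single_run"` (one test sample per run).
#' @param k_neighbors Neighbours for the similarity graph (default 5).
#' @param dan A [dan_config()]; its seed is overridden from `seed`.
#' @param gcn A [gcn_config()]; its seed is overridden from `seed`.
#' @param pseudocount Pseudocount for the log10 transform.
#' @param latent_layer Hidden layer whose representation feeds the graph;
#'   default the second hidden layer, the model's transferable latent code.
#' @param seed Master seed; all stage seeds derive from it.
#' @return A `run_config` list.
#' @export
run_config <- function(mode = c("batch_run", "single_run"),
                       k_neighbors = 5L,
                       dan = dan_config(),
                       gcn = gcn_config(),
                       pseudocount = 1e-5,
                       latent_layer = 2L,
                       seed = 1L) {
  mode <- match.arg(mode)
  dan$seed <- derive_seed(seed, 101L)
  gcn$seed <- derive_seed(seed, 202L)
  structure(list(mode = mode, k_neighbors = as.integer(k_neighbors),
                 dan = dan, gcn = gcn, pseudocount = pseudocount,
                 latent_layer = as.integer(latent_layer),
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Classify a batch of test samples
#'
#' Executes the full method: feature alignment, log10 + train-statistics
#' z-score normalization, MK-MMD-regularized adaptation training (train
#' cohorts as source, test samples as target), latent extraction, kNN graph
#' construction over all samples, semi-supervised GCN training on the
#' labelled train nodes, and prediction for every node. Test labels, if
#' present, are ignored throughout.
#'
#' @param train A labelled `abundance_matrix`.
#' @param test An `abundance_matrix`; labels (if any) are never read.
#' @param config A [run_config()].
#' @param outdir Optional directory; when given, predictions, the graph edge
#'   list, normalization statistics and a JSON run manifest are written.
#' @return A `microgcn_fit` with the per-node `result` plus every
#'   intermediate artifact (`stats`, `dan`, `graph`, `gcn`, normalized
#'   `features`, aligned raw inputs).
#' @export
run_batch <- function(train, test, config = run_config(), outdir = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("[", name, "] ", conditionMessage(e), call. = FALSE))
  }
  if (anyNA(train$label))
    stop("[input] all training samples must be labelled")

  al <- stage("align", align_features(train, test))
  train <- al$train; test <- al$test

  norm <- stage("normalize", {
    logged <- log10_transform(train, config$pseudocount)
    stats <- zscore_fit(logged, config$pseudocount)
    list(stats = stats,
         Xs = suppressWarnings(zscore_apply(logged, stats)),
         Xt = normalize_with(test, stats))
  })

  dan <- stage("adaptation", {
    if (config$dan$lambda_penalty > 0 && nrow(norm$Xt) == 1L)
      warning("single-sample target domain: the MK-MMD estimate is ",
              "degenerate (one target point); consider lambda_penalty = 0")
    train_dan(domain_pair(norm$Xs, train$label, norm$Xt), config$dan)
  })

  graph <- stage("graph", {
    ls <- extract_latent(dan, norm$Xs, config$latent_layer)
    lt <- extract_latent(dan, norm$Xt, config$latent_layer)
    build_graph(ls, lt, k = config$k_neighbors,
                train_ids = train$sample_ids, test_ids = test$sample_ids)
  })

  n_train <- nrow(norm$Xs)
  mask <- c(rep(TRUE, n_train), rep(FALSE, nrow(norm$Xt)))
  features <- rbind(norm$Xs, norm$Xt)
  gcn <- stage("gcn", {
    train_gcn(graph, features, c(train$label, rep(NA, nrow(norm$Xt))),
              mask, config$gcn)
  })

  fit <- structure(list(result = gcn$result, stats = norm$stats, dan = dan,
                        graph = graph, gcn = gcn, features = features,
                        train = train, test = test, train_mask = mask,
                        config = config),
                   class = "microgcn_fit")
  if (!is.null(outdir)) write_run_artifacts(fit, outdir)
  fit
}

#' Classify a single test sample
#'
#' Same computation as [run_batch()] with a one-node target domain; batch
#' mode with a test set of size 1 and single mode on that sample are the
#' same run and produce identical predictions under identical seeds.
#'
#' @param train A labelled `abundance_matrix`.
#' @param one_sample An `abundance_matrix` with exactly one sample.
#' @param config A [run_config()].
#' @param outdir Optional artifact directory.
#' @return A `microgcn_fit`; the single prediction is the non-train row of
#'   `$result`.
#' @export
run_single <- function(train, one_sample, config = run_config(mode = "single_run"),
                       outdir = NULL) {
  if (length(one_sample$sample_ids) != 1L)
    stop("single_run takes exactly one test sample, got ",
         length(one_sample$sample_ids))
  run_batch(train, one_sample, config, outdir)
}

#' @export
print.microgcn_fit <- function(x, ...) {
  n_te <- sum(!x$result$is_train)
  cat("microgcn_fit: ", sum(x$result$is_train), " train + ", n_te,
      " test nodes, k = ", x$config$k_neighbors, "\n", sep = "")
  cat("  test predictions: ",
      sum(x$result$predicted_label[!x$result$is_train] == "disease"),
      " disease / ",
      sum(x$result$predicted_label[!x$result$is_train] == "health"),
      " health\n", sep = "")
  invisible(x)
}

write_run_artifacts <- function(fit, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  res <- fit$result
  res$split <- ifelse(res$is_train, "train", "test")
  utils::write.table(
    res[, c("node_id", "prob_disease", "prob_health", "predicted_label", "split")],
    file.path(outdir, "predictions.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  write_edges(fit$graph, file.path(outdir, "edges.tsv"))
  write_norm_stats(fit$stats, file.path(outdir, "norm_stats.tsv"))
  manifest <- list(mode = fit$config$mode, seed = fit$config$seed,
                   k_neighbors = fit$config$k_neighbors,
                   pseudocount = fit$config$pseudocount,
                   latent_layer = fit$config$latent_layer,
                   dan = unclass(fit$config$dan),
                   gcn = unclass(fit$config$gcn),
                   n_train = sum(fit$train_mask),
                   n_test = sum(!fit$train_mask))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(outdir)
}

#' Re-run a pipeline from a written manifest
#'
#' The manifest fully determines a run: replaying it against the same inputs
#' reproduces the outputs.
#'
#' @param manifest_path Path to `manifest.json` from a previous run.
#' @param train,test The same inputs used originally.
#' @param outdir Optional artifact directory.
#' @return A `microgcn_fit`.
#' @export
replay_run <- function(manifest_path, train, test, outdir = NULL) {
  m <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  cfg <- run_config(mode = m$mode, k_neighbors = m$k_neighbors,
                    dan = do.call(dan_config, m$dan[names(m$dan) != "seed"]),
                    gcn = do.call(gcn_config, m$gcn[names(m$gcn) != "seed"]),
                    pseudocount = m$pseudocount,
                    latent_layer = m$latent_layer, seed = m$seed)
  run_batch(train, test, cfg, outdir)
}

#' Read a run configuration from a YAML file
#'
#' The file may set any of `mode`, `k_neighbors`, `pseudocount`,
#' `latent_layer`, `seed`, and nested `dan:` / `gcn:` blocks whose keys
#' mirror [dan_config()] and [gcn_config()] arguments; omitted fields keep
#' their defaults.
#'
#' @param path Path to a YAML file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  dan <- do.call(dan_config, y$dan %||% list())
  gcn <- do.call(gcn_config, y$gcn %||% list())
  run_config(mode = y$mode %||% "batch_run",
             k_neighbors = y$k_neighbors %||% 5L,
             dan = dan, gcn = gcn,
             pseudocount = y$pseudocount %||% 1e-5,
             latent_layer = y$latent_layer %||% 2L,
             seed = y$seed %||% 1L)
}

#' Write a run configuration as YAML
#'
#' @param config A [run_config()].
#' @param path Output path.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(list(mode = config$mode,
                        k_neighbors = config$k_neighbors,
                        pseudocount = config$pseudocount,
                        latent_layer = config$latent_layer,
                        seed = config$seed,
                        dan = unclass(config$dan),
                        gcn = unclass(config$gcn)), path)
  invisible(path)
}
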