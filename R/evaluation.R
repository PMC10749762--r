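#' Area under the ROC curve (Mann-Whitney form)
#'
#' Computed as the rank-based Mann-Whitney concordance:
#' (concordant positive-negative pairs + 0.5 * tied pairs) / (n_pos * n_neg).
#'
#' @param scores Per-sample disease scores (higher = more disease-like).
#' @param labels Binary labels: 1/`"disease"` positive, 0/`"health"` negative.
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(scores, labels) {
  y <- encode_labels(labels) - 1L           # 1 = disease
  if (length(scores) != length(y)) stop("scores and labels differ in length")
  n_pos <- sum(y == 1L); n_neg <- sum(y == 0L)
  if (n_pos == 0L || n_neg == 0L) stop("both classes must be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[y == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Margin of error for a mean over repeated experiments
#'
#' Half-width of the t-based confidence interval:
#' `t(1 - alpha/2, n - 1) * s / sqrt(n)` with `s` the sample standard
#' deviation (n - 1 denominator).
#'
#' @param values Numeric vector of per-repeat statistics (length >= 2).
#' @param alpha Complement of the confidence level (default 0.05 for 95%).
#' @return Non-negative scalar.
#' @export
margin_of_error <- function(values, alpha = 0.05) {
  n <- length(values)
  if (n < 2L) stop("need at least 2 values")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  stats::qt(1 - alpha / 2, df = n - 1L) * stats::sd(values) / sqrt(n)
}

#' Evaluation configuration
#'
#' @param n_folds Folds per repeat (default 10).
#' @param n_repeats Number of repeats (default 10).
#' @param alpha Confidence-interval complement for the margin of error.
#' @param seed Base seed; each repeat derives its own fold seed from it.
#' @return An `eval_config` list.
#' @export
eval_config <- function(n_folds = 10L, n_repeats = 10L, alpha = 0.05,
                        seed = 1L) {
  if (n_folds < 2L) stop("n_folds must be >= 2")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  structure(list(n_folds = as.integer(n_folds),
                 n_repeats = as.integer(n_repeats),
                 alpha = alpha, seed = as.integer(seed)),
            class = "eval_config")
}

# Stratified fold assignment: within each class, samples are shuffled and
# dealt to folds round-robin, so fold class counts differ from exact
# proportionality by at most 1.
stratified_folds <- function(labels, n_folds, seed) {
  y <- encode_labels(labels)
  fold <- integer(length(y))
  with_seed(seed, {
    for (cls in sort(unique(y))) {
      idx <- which(y == cls)
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- rep_len(seq_len(n_folds), length(idx))
    }
  })
  fold
}

#' Repeated stratified k-fold cross-validation
#'
#' Each repeat partitions the samples into stratified folds; every sample is
#' held out exactly once per repeat, and the repeat's AUC is computed over
#' the pooled out-of-fold disease scores. The mean AUC and its
#' [margin_of_error()] are reported across repeats.
#'
#' @param dataset A labelled `abundance_matrix`.
#' @param config An [eval_config()].
#' @param classifier Function `(train, test, seed)` returning per-sample
#'   disease scores for the test `abundance_matrix`; defaults to the full
#'   adaptation + graph-convolution pipeline via [run_batch()].
#' @param ... Passed to the default classifier's [run_config()].
#' @return A `cv_result` list: `per_repeat_auc`, `mean_auc`,
#'   `margin_of_error`, `config`.
#' @export
stratified_kfold <- function(dataset, config = eval_config(),
                             classifier = pipeline_classifier(...), ...) {
  y <- dataset$label
  if (anyNA(y)) stop("all samples must be labelled for cross-validation")
  counts <- table(encode_labels(y))
  if (length(counts) < 2L || any(counts < config$n_folds))
    stop("each class needs at least n_folds = ", config$n_folds, " members")
  per_repeat <- numeric(config$n_repeats)
  for (r in seq_len(config$n_repeats)) {
    rseed <- derive_seed(config$seed, r)
    fold <- stratified_folds(y, config$n_folds, rseed)
    scores <- numeric(length(y))
    for (f in seq_len(config$n_folds)) {
      te <- fold == f
      scores[te] <- classifier(subset_samples(dataset, !te),
                               subset_samples(dataset, te),
                               derive_seed(rseed, f))
    }
    per_repeat[r] <- auc(scores, y)
  }
  structure(list(per_repeat_auc = per_repeat,
                 mean_auc = mean(per_repeat),
                 margin_of_error = if (config$n_repeats >= 2L)
                   margin_of_error(per_repeat, config$alpha) else NA_real_,
                 config = config),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("cv_result: mean AUC %.4f (margin of error %.4f) over %d repeats\n",
              x$mean_auc, x$margin_of_error, length(x$per_repeat_auc)))
  invisible(x)
}

#' Default cross-validation classifier: the full pipeline
#'
#' Returns a closure suitable for [stratified_kfold()] that runs
#' [run_batch()] with test labels blinded and reports `prob_disease`.
#'
#' @param ... Overrides forwarded to [run_config()].
#' @return A function `(train, test, seed) -> numeric scores`.
#' @export
pipeline_classifier <- function(...) {
  args <- list(...)
  function(train, test, seed) {
    cfg <- do.call(run_config, utils::modifyList(args, list(seed = seed)))
    blind <- abundance_matrix(test$values, test$sample_ids, test$taxa,
                              cohort = test$cohort)
    res <- run_batch(train, blind, cfg)$result
    res$prob_disease[!res$is_train]
  }
}

#' Leave-one-study-out evaluation
#'
#' Removes one cohort from training, treats it as the unlabelled target
#' domain for adaptation and as the unlabelled test nodes of the graph, and
#' scores the trained model against the held-out cohort's true labels.
#'
#' @param cohorts A list of labelled `abundance_matrix` objects (or a single
#'   multi-cohort matrix, split on its `cohort` field).
#' @param held_out Cohort identifier to hold out.
#' @param config A [run_config()]; its seed controls the whole run.
#' @return A list with `auc`, the pipeline `fit`, and the held-out
#'   `result` rows.
#' @export
loso <- function(cohorts, held_out, config = run_config()) {
  if (inherits(cohorts, "abundance_matrix"))
    cohorts <- split_cohorts(cohorts)
  ids <- vapply(cohorts, function(m) unique(m$cohort)[1L], character(1L))
  if (!held_out %in% ids)
    stop("unknown cohort ID '", held_out, "'; have: ",
         paste(ids, collapse = ", "))
  test <- cohorts[[which(ids == held_out)]]
  train_list <- cohorts[ids != held_out]
  if (length(train_list) == 0L) stop("need at least 2 cohorts")
  merge2 <- function(x, y) {
    al <- align_features(x, y)
    bind_samples(al$train, al$test)
  }
  train <- Reduce(merge2, train_list)
  blind <- abundance_matrix(test$values, test$sample_ids, test$taxa,
                            cohort = test$cohort)
  fit <- run_batch(train, blind, config)
  res <- fit$result[!fit$result$is_train, ]
  list(auc = auc(res$prob_disease, test$label), fit = fit, result = res)
}

#' Split a multi-cohort abundance matrix by cohort
#'
#' @param m An `abundance_matrix`.
#' @return A named list of per-cohort `abundance_matrix` objects.
#' @export
split_cohorts <- function(m) {
  ids <- unique(m$cohort)
  stats::setNames(lapply(ids, function(cid) subset_samples(m, m$cohort == cid)),
                  ids)
}
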