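#' Rank species by single-feature classification AUC
#'
#' For each taxon the graph-plus-GCN pipeline is re-run with that taxon's
#' (normalized) abundance as the only node feature: the similarity graph is
#' rebuilt from the single feature, the GCN is trained on the labelled
#' samples, and the AUC of its disease probabilities against the training
#' labels is recorded. Species are ranked by descending AUC; exact ties are
#' ordered lexicographically by taxon name so ranks are a strict
#' permutation of 1..n_taxa.
#'
#' @param train A labelled `abundance_matrix`.
#' @param k_neighbors Neighbours for the per-taxon graph.
#' @param gcn A [gcn_config()]; the default uses a narrow network (width 16,
#'   100 epochs) since a one-dimensional feature needs little capacity.
#' @param pseudocount Pseudocount for the log10 transform.
#' @param seed Master seed; each taxon derives its own training seed.
#' @return A data.frame with columns `taxon`, `auc`, `rank`, sorted by rank.
#' @export
rank_species_by_auc <- function(train, k_neighbors = 5L,
                                gcn = gcn_config(hidden_width = 16L,
                                                 epochs = 100L),
                                pseudocount = 1e-5, seed = 1L) {
  if (anyNA(train$label)) stop("all training samples must be labelled")
  if (length(unique(train$label)) < 2L) stop("need both classes in training data")
  logged <- log10_transform(train, pseudocount)
  aucs <- vapply(seq_along(train$taxa), function(j) {
    x <- logged[, j, drop = FALSE]
    stats_j <- zscore_fit(x, pseudocount)
    feat <- suppressWarnings(zscore_apply(x, stats_j))
    graph <- knn_edges(pairwise_euclidean(feat), k = k_neighbors,
                       node_order = train$sample_ids)
    cfg <- gcn
    cfg$seed <- derive_seed(seed, j)
    fit <- train_gcn(graph, feat, train$label,
                     rep(TRUE, length(train$label)), cfg)
    auc(fit$result$prob_disease, train$label)
  }, numeric(1L))
  ord <- order(-aucs, train$taxa)
  data.frame(taxon = train$taxa[ord], auc = aucs[ord],
             rank = seq_along(ord), row.names = NULL,
             stringsAsFactors = FALSE)
}

increasing_rules <- c("Min2Max", "Min2Median", "Middle2Max")
decreasing_rules <- c("Max2Median", "Max2Min", "Middle2Min")

#' Which two modification rules apply to a biomarker in a sample
#'
#' A biomarker holding the sample's maximum abundance admits the two Max
#' rules, the minimum the two Min rules, and any in-between abundance the
#' two Middle rules. For a constant abundance vector (max = min) the Max
#' rules are chosen; every modification is then a no-op anyway.
#'
#' @param sample_abundances Named numeric vector of raw abundances.
#' @param taxon Name of the biomarker.
#' @return Character vector of the two applicable rule names.
#' @export
applicable_rules <- function(sample_abundances, taxon) {
  if (!taxon %in% names(sample_abundances))
    stop("taxon '", taxon, "' not present in sample")
  v <- sample_abundances[[taxon]]
  if (v == max(sample_abundances)) c("Max2Median", "Max2Min")
  else if (v == min(sample_abundances)) c("Min2Max", "Min2Median")
  else c("Middle2Max", "Middle2Min")
}

#' Apply one abundance-modification rule
#'
#' Replaces the biomarker's raw abundance with the sample's maximum, median
#' or minimum species abundance according to the rule; all other taxa are
#' untouched. Modification acts on raw relative abundances; normalization
#' with the frozen training statistics is re-applied downstream before the
#' model is consulted.
#'
#' @param sample_abundances Named numeric vector of raw abundances.
#' @param taxon Biomarker name.
#' @param rule One of the six rule names.
#' @return The modified abundance vector.
#' @export
modify_abundance <- function(sample_abundances, taxon, rule) {
  rules <- c("Max2Median", "Max2Min", "Middle2Max", "Middle2Min",
             "Min2Max", "Min2Median")
  if (!rule %in% rules) stop("unknown rule '", rule, "'")
  if (!rule %in% applicable_rules(sample_abundances, taxon))
    stop("rule '", rule, "' is not applicable to taxon '", taxon,
         "' in this sample")
  target <- switch(sub(".*2", "", rule),
                   Max = max(sample_abundances),
                   Median = stats::median(sample_abundances),
                   Min = min(sample_abundances))
  out <- sample_abundances
  out[[taxon]] <- target
  out
}

# P(health) for one node after swapping in a (possibly modified) raw
# abundance row; graph topology and trained weights held fixed.
node_health_prob <- function(fit, node_index, raw_row) {
  feat <- fit$features
  feat[node_index, ] <- normalize_with(matrix(raw_row, nrow = 1L), fit$stats)
  probs <- softmax_rows(gcn_forward(fit$graph, feat, fit$gcn$weights))
  probs[node_index, 1L]
}

#' Contribution value of one modification for one sample
#'
#' The absolute difference between the model's predicted probability of
#' being healthy before and after modifying the biomarker's raw abundance,
#' annotated with the direction of the change (toward disease if P(health)
#' decreased, toward health if it increased). Only the queried node's
#' feature changes; the graph topology stays fixed.
#'
#' @param fit A `microgcn_fit` from [run_batch()].
#' @param sample_id ID of a training sample.
#' @param taxon Biomarker name.
#' @param rule An applicable modification rule.
#' @return A list with `value` (in `[0, 1]`), `direction`
#'   (`"toward_disease"`, `"toward_health"` or `"none"`), `p_before`,
#'   `p_after`.
#' @export
contribution_value <- function(fit, sample_id, taxon, rule) {
  i <- match(sample_id, fit$graph$node_order)
  if (is.na(i)) stop("unknown sample '", sample_id, "'")
  raw <- fit$train$values[match(sample_id, fit$train$sample_ids), ]
  p0 <- node_health_prob(fit, i, raw)
  p1 <- node_health_prob(fit, i, modify_abundance(raw, taxon, rule))
  list(value = abs(p0 - p1),
       direction = if (p1 < p0) "toward_disease"
                   else if (p1 > p0) "toward_health" else "none",
       p_before = p0, p_after = p1)
}

#' Contribution scores of biomarkers to host disease status
#'
#' For every correctly predicted training sample, the biomarker's two
#' applicable rules are applied and each outcome accrues to one of four
#' contribution types: an abundance-increasing rule (Min2Max, Min2Median,
#' Middle2Max) that lowers P(health) accrues to `Increase2Disease` and one
#' that raises it to `Increase2Health`; symmetrically the decreasing rules
#' (Max2Median, Max2Min, Middle2Min) feed `Decrease2Disease` /
#' `Decrease2Health`. Per type, the score is the mean per-sample
#' contribution value over the n correctly predicted samples (samples
#' contributing 0 stay in the denominator; when both rules of a sample hit
#' the same type their values are averaged so every score stays in [0, 1]).
#'
#' @param fit A `microgcn_fit` from [run_batch()].
#' @param biomarkers Character vector of taxa to score.
#' @return A data.frame of class `contribution_report`: one row per
#'   biomarker with the four scores and `n_samples_used`; per-sample values
#'   are stored in `attr(, "per_sample")` as one n x 4 matrix per biomarker.
#' @export
contribution_scores <- function(fit, biomarkers) {
  res <- fit$result
  tr <- which(res$is_train)
  truth <- fit$train$label[match(res$node_id[tr], fit$train$sample_ids)]
  correct <- tr[res$predicted_label[tr] == truth]
  if (length(correct) == 0L)
    stop("no correctly predicted training samples")
  types <- c("Increase2Disease", "Increase2Health",
             "Decrease2Disease", "Decrease2Health")
  probs0 <- softmax_rows(gcn_forward(fit$graph, fit$features, fit$gcn$weights))

  per_sample <- list()
  rows <- lapply(biomarkers, function(tx) {
    C <- matrix(0, length(correct), length(types),
                dimnames = list(res$node_id[correct], types))
    for (s in seq_along(correct)) {
      i <- correct[s]
      sid <- res$node_id[i]
      raw <- fit$train$values[match(sid, fit$train$sample_ids), ]
      p0 <- probs0[i, 1L]
      acc <- stats::setNames(rep(0, 4L), types)
      cnt <- stats::setNames(rep(0L, 4L), types)
      for (rule in applicable_rules(raw, tx)) {
        p1 <- node_health_prob(fit, i, modify_abundance(raw, tx, rule))
        dir <- if (p1 < p0) "Disease" else if (p1 > p0) "Health" else NA
        if (is.na(dir)) next
        kind <- if (rule %in% increasing_rules) "Increase" else "Decrease"
        ty <- paste0(kind, "2", dir)
        acc[ty] <- acc[ty] + abs(p0 - p1)
        cnt[ty] <- cnt[ty] + 1L
      }
      C[s, ] <- ifelse(cnt > 0L, acc / pmax(cnt, 1L), 0)
    }
    per_sample[[tx]] <<- C
    c(colMeans(C), n_samples_used = length(correct))
  })
  out <- data.frame(taxon = biomarkers, do.call(rbind, rows),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "per_sample") <- per_sample
  class(out) <- c("contribution_report", "data.frame")
  out
}

#' Write a biomarker ranking or contribution report as TSV
#'
#' @param report A data.frame from [rank_species_by_auc()] or
#'   [contribution_scores()].
#' @param path Output path.
#' @export
write_report <- function(report, path) {
  utils::write.table(as.data.frame(report), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
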