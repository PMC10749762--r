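#' Configuration for the graph convolutional classifier
#'
#' @param n_layers Number of graph-convolution layers (default 2).
#' @param hidden_width Width of each convolution layer's output.
#' @param epochs Full-batch training epochs.
#' @param learning_rate Adam step size.
#' @param dropout_rate Dropout probability applied to the input and to each
#'   hidden representation during training only; in `[0, 1)`.
#' @param seed Integer seed for initialization and dropout masks.
#' @return A `gcn_config` list.
#' @export
gcn_config <- function(n_layers = 2L, hidden_width = 64L, epochs = 200L,
                       learning_rate = 0.01, dropout_rate = 0.5, seed = 1L) {
  if (n_layers < 1L) stop("n_layers must be >= 1")
  if (dropout_rate < 0 || dropout_rate >= 1) stop("dropout_rate must be in [0, 1)")
  structure(list(n_layers = as.integer(n_layers),
                 hidden_width = as.integer(hidden_width),
                 epochs = as.integer(epochs),
                 learning_rate = learning_rate,
                 dropout_rate = dropout_rate,
                 seed = as.integer(seed)),
            class = "gcn_config")
}

#' Forward pass of the graph convolutional network
#'
#' Each convolution layer propagates node features through the
#' symmetric-normalized adjacency with self-loops:
#' `H(l+1) = ReLU(S H(l) W(l))` with `S = D^{-1/2}(A + I)D^{-1/2}`; a final
#' linear head maps the last hidden representation to 2 class logits.
#' Dropout is disabled, so the pass is deterministic given the weights.
#'
#' @param graph A `similarity_graph`.
#' @param node_features Matrix with `graph$n` rows.
#' @param weights A `gcn_weights` list (`conv` weight matrices, `head` W/b).
#' @return An n x 2 logits matrix (columns health, disease).
#' @export
gcn_forward <- function(graph, node_features, weights) {
  X <- as.matrix(node_features)
  if (nrow(X) != graph$n)
    stop("node_features has ", nrow(X), " rows but graph has ", graph$n, " nodes")
  if (ncol(X) != nrow(weights$conv[[1L]]))
    stop("feature dimension does not match model weights")
  S <- graph$norm_operator
  H <- X
  for (W in weights$conv) H <- relu(S %*% H %*% W)
  sweep(H %*% weights$head$W, 2L, weights$head$b, "+")
}

#' Train the GCN on labelled nodes only
#'
#' All nodes (labelled and unlabelled) participate in every convolution, but
#' the cross-entropy loss is computed over the nodes marked in `train_mask`
#' only, so test-node labels can never influence the fitted weights.
#'
#' @param graph A `similarity_graph`.
#' @param node_features Matrix with one row per node.
#' @param labels Per-node labels (`"disease"`/`"health"`/`NA` or 1/0/NA);
#'   only entries where `train_mask` is TRUE are read.
#' @param train_mask Logical vector marking the labelled training nodes;
#'   must cover at least one node of each class.
#' @param config A [gcn_config()].
#' @return A `gcn_model` with `weights`, `config`, `training_log`, and the
#'   [classification_result()] of the final model on all nodes.
#' @export
train_gcn <- function(graph, node_features, labels, train_mask,
                      config = gcn_config()) {
  X <- as.matrix(node_features)
  n <- graph$n
  stopifnot(nrow(X) == n, length(train_mask) == n)
  midx <- which(train_mask)
  y <- encode_labels(labels[midx])
  if (length(unique(y)) < 2L)
    stop("train_mask must cover at least one node of each class")
  S <- graph$norm_operator
  L <- config$n_layers
  dims <- c(ncol(X), rep(config$hidden_width, L))

  params <- with_seed(config$seed, {
    p <- list()
    for (l in seq_len(L)) p[[paste0("W", l)]] <- init_weight(dims[l], dims[l + 1L])
    p$Whead <- init_weight(dims[L + 1L], 2L)
    p$bhead <- matrix(0, 1L, 2L)
    p
  })
  opt <- adam_init(params)
  keep <- 1 - config$dropout_rate
  log_loss <- numeric(config$epochs)

  # one seeded RNG stream drives every epoch's dropout masks
  run <- with_seed(derive_seed(config$seed, 1L), {
    for (epoch in seq_len(config$epochs)) {
      masks <- vector("list", L + 1L)
      Hs <- list(X); Zs <- list(); SHs <- list()
      H <- X
      for (l in seq_len(L)) {
        if (keep < 1) {
          masks[[l]] <- matrix(stats::runif(length(H)) < keep, nrow(H)) / keep
          H <- H * masks[[l]]
        }
        SH <- S %*% H
        Z <- SH %*% params[[paste0("W", l)]]
        Hs[[l]] <- H; SHs[[l]] <- SH; Zs[[l]] <- Z
        H <- relu(Z)
      }
      if (keep < 1) {
        masks[[L + 1L]] <- matrix(stats::runif(length(H)) < keep, nrow(H)) / keep
        H <- H * masks[[L + 1L]]
      }
      Hlast <- H
      logits <- sweep(Hlast %*% params$Whead, 2L, params$bhead, "+")
      probs <- softmax_rows(logits)
      loss <- cross_entropy(probs[midx, , drop = FALSE], y)
      if (!is.finite(loss)) stop("non-finite loss at epoch ", epoch)
      log_loss[epoch] <- loss

      dlogits <- matrix(0, n, 2L)
      dlogits[midx, ] <- probs[midx, , drop = FALSE]
      dlogits[cbind(midx, y)] <- dlogits[cbind(midx, y)] - 1
      dlogits <- dlogits / length(midx)

      grads <- list()
      grads$Whead <- crossprod(Hlast, dlogits)
      grads$bhead <- matrix(colSums(dlogits), 1L)
      dH <- tcrossprod(dlogits, params$Whead)
      if (keep < 1) dH <- dH * masks[[L + 1L]]
      for (l in rev(seq_len(L))) {
        dZ <- dH * (Zs[[l]] > 0)
        grads[[paste0("W", l)]] <- crossprod(SHs[[l]], dZ)
        if (l > 1L) {
          dH <- crossprod(S, dZ) %*% t(params[[paste0("W", l)]])
          if (keep < 1) dH <- dH * masks[[l]]
        }
      }
      step <- adam_step(params, grads, opt, config$learning_rate)
      params <- step$params; opt <- step$state
    }
    list(params = params, log_loss = log_loss)
  })
  params <- run$params

  weights <- structure(
    list(conv = lapply(seq_len(L), function(l) params[[paste0("W", l)]]),
         head = list(W = params$Whead, b = params$bhead)),
    class = "gcn_weights")
  model <- structure(list(weights = weights, config = config,
                          training_log = data.frame(
                            epoch = seq_len(config$epochs),
                            loss = run$log_loss)),
                     class = "gcn_model")
  model$result <- predict_gcn(model, graph, X, train_mask = train_mask)
  model
}

#' Predict class probabilities for every node
#'
#' Softmax over the two logits; ties at probability 0.5 predict `health`
#' (the conservative default, documented and deterministic).
#'
#' @param model A `gcn_model` (or bare `gcn_weights`).
#' @param graph A `similarity_graph`.
#' @param node_features Matrix with one row per node.
#' @param train_mask Optional logical vector recorded in the result.
#' @return A `classification_result` data.frame with columns `node_id`,
#'   `prob_health`, `prob_disease`, `predicted_label`, `is_train`.
#' @export
predict_gcn <- function(model, graph, node_features, train_mask = NULL) {
  weights <- if (inherits(model, "gcn_model")) model$weights else model
  if (!inherits(weights, "gcn_weights")) stop("not a trained GCN model")
  logits <- gcn_forward(graph, node_features, weights)
  probs <- softmax_rows(logits)
  classification_result(graph$node_order, probs,
                        train_mask %||% rep(NA, graph$n))
}

#' Assemble a per-node classification result
#'
#' @param node_ids Node identifiers.
#' @param probs n x 2 matrix of (health, disease) probabilities.
#' @param is_train Logical (or NA) per node.
#' @return A data.frame of class `classification_result`.
#' @export
classification_result <- function(node_ids, probs, is_train) {
  out <- data.frame(node_id = node_ids,
                    prob_health = probs[, 1L],
                    prob_disease = probs[, 2L],
                    predicted_label = ifelse(probs[, 2L] > probs[, 1L],
                                             "disease", "health"),
                    is_train = is_train,
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("classification_result", "data.frame")
  out
}
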