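#' Configuration for the deep adaptation network
#'
#' A fully connected classifier whose hidden representations are regularized
#' to minimize MK-MMD between the labelled source domain (training cohorts)
#' and the unlabelled target domain (test cohort), so that the latent
#' features used for graph construction transfer across studies.
#'
#' @param layer_sizes Widths of the three hidden ReLU layers.
#' @param lambda_penalty Non-negative weight of the MK-MMD adaptation term;
#'   `0` disables adaptation and reduces training to a plain classifier.
#' @param regularized_layers Hidden-layer indices (subset of 1:3) at which
#'   the MK-MMD penalty is applied; default the last hidden layer.
#' @param kernel_bandwidth_multipliers Passed to the MK-MMD kernel mixture.
#' @param epochs Full-batch training epochs.
#' @param learning_rate Adam step size.
#' @param weight_decay L2 penalty on the weight matrices; keeps the latent
#'   space from memorizing the source cohort before alignment.
#' @param seed Integer seed controlling weight initialization.
#' @return A `dan_config` list.
#' @export
dan_config <- function(layer_sizes = c(256L, 128L, 64L),
                       lambda_penalty = 1.0,
                       regularized_layers = 3L,
                       kernel_bandwidth_multipliers = c(0.25, 0.5, 1, 2, 4),
                       epochs = 200L,
                       learning_rate = 0.01,
                       weight_decay = 1e-3,
                       seed = 1L) {
  if (lambda_penalty < 0) stop("lambda_penalty must be >= 0")
  if (length(layer_sizes) != 3L)
    stop("the adaptation network uses exactly 3 hidden layers")
  if (!all(regularized_layers %in% seq_along(layer_sizes)))
    stop("regularized_layers must be a subset of 1:", length(layer_sizes))
  structure(list(layer_sizes = as.integer(layer_sizes),
                 lambda_penalty = lambda_penalty,
                 regularized_layers = as.integer(regularized_layers),
                 kernel_bandwidth_multipliers = kernel_bandwidth_multipliers,
                 epochs = as.integer(epochs),
                 learning_rate = learning_rate,
                 weight_decay = weight_decay,
                 seed = as.integer(seed)),
            class = "dan_config")
}

#' Bundle source and target domains for adaptation training
#'
#' @param source_x Normalized feature matrix of labelled training samples.
#' @param source_y Labels for `source_x`: `"disease"`/`"health"` (or 1/0).
#' @param target_x Normalized feature matrix of unlabelled test samples; the
#'   target enters training only through the MK-MMD penalty, never the
#'   classification loss.
#' @return A `domain_pair` list.
#' @export
domain_pair <- function(source_x, source_y, target_x) {
  source_x <- as.matrix(source_x); target_x <- as.matrix(target_x)
  y <- encode_labels(source_y)
  if (ncol(source_x) != ncol(target_x))
    stop("source and target feature dimensions differ")
  if (length(y) != nrow(source_x))
    stop("source_y length does not match source_x rows")
  if (length(unique(y)) < 2L)
    stop("source domain must contain both classes")
  structure(list(source_x = source_x, source_y = y, target_x = target_x),
            class = "domain_pair")
}

# Map labels to integer class indices: 1 = health, 2 = disease.
encode_labels <- function(y) {
  if (is.character(y) || is.factor(y)) {
    y <- as.character(y)
    bad <- !y %in% c("disease", "health")
    if (any(bad)) stop("labels must be 'disease' or 'health'")
    ifelse(y == "disease", 2L, 1L)
  } else {
    if (!all(y %in% c(0, 1))) stop("numeric labels must be 0 (health) or 1 (disease)")
    as.integer(y) + 1L
  }
}

#' Train the deep adaptation network
#'
#' Minimizes mean cross-entropy on the labelled source samples plus
#' `lambda_penalty` times the MK-MMD between source and target hidden
#' representations at the configured layers. Optimization is full-batch Adam
#' for a fixed number of epochs; with an identical seed and inputs the run
#' is bitwise reproducible.
#'
#' @param pair A [domain_pair()].
#' @param config A [dan_config()].
#' @return A `dan_model` with per-layer `weights`/`biases`, a 2-class
#'   `output_head`, the `config`, and a per-epoch `training_log`
#'   (cross-entropy and MMD components).
#' @export
train_dan <- function(pair, config = dan_config()) {
  stopifnot(inherits(pair, "domain_pair"), inherits(config, "dan_config"))
  Xs <- pair$source_x; Xt <- pair$target_x; y <- pair$source_y
  dims <- c(ncol(Xs), config$layer_sizes, 2L)
  L <- length(config$layer_sizes)            # hidden layer count

  params <- with_seed(config$seed, {
    p <- list()
    for (l in seq_len(L + 1L)) {
      p[[paste0("W", l)]] <- init_weight(dims[l], dims[l + 1L])
      p[[paste0("b", l)]] <- matrix(0, 1L, dims[l + 1L])
    }
    p
  })
  opt <- adam_init(params)
  use_mmd <- config$lambda_penalty > 0
  log_ce <- log_mmd <- numeric(config$epochs)

  for (epoch in seq_len(config$epochs)) {
    # forward: source (and target only when the penalty is active)
    hs <- list(Xs); zs <- list()
    for (l in seq_len(L)) {
      zs[[l]] <- sweep(hs[[l]] %*% params[[paste0("W", l)]], 2L,
                       params[[paste0("b", l)]], "+")
      hs[[l + 1L]] <- relu(zs[[l]])
    }
    logits <- sweep(hs[[L + 1L]] %*% params[[paste0("W", L + 1L)]], 2L,
                    params[[paste0("b", L + 1L)]], "+")
    probs <- softmax_rows(logits)
    ce <- cross_entropy(probs, y)

    # progressive penalty: lambda ramps from 0 to its configured value so the
    # latent space is shaped by the classification loss before alignment
    lam <- config$lambda_penalty *
      (2 / (1 + exp(-10 * epoch / config$epochs)) - 1)
    mmd_total <- 0
    mmd_grads_s <- vector("list", L)     # d(MMD)/d(hs[[l+1]])
    mmd_grads_t <- vector("list", L)
    ht <- NULL
    if (use_mmd) {
      ht <- list(Xt)
      for (l in seq_len(L))
        ht[[l + 1L]] <- relu(sweep(ht[[l]] %*% params[[paste0("W", l)]], 2L,
                                   params[[paste0("b", l)]], "+"))
      for (l in config$regularized_layers) {
        mc <- mmd_core(hs[[l + 1L]], ht[[l + 1L]],
                       config$kernel_bandwidth_multipliers, grad = TRUE)
        mmd_total <- mmd_total + mc$value
        mmd_grads_s[[l]] <- mc$grad_a
        mmd_grads_t[[l]] <- mc$grad_b
      }
    }
    loss <- ce + lam * mmd_total
    if (!is.finite(loss))
      stop("non-finite loss at epoch ", epoch)
    log_ce[epoch] <- ce; log_mmd[epoch] <- mmd_total

    # backward
    ns <- nrow(Xs)
    grads <- lapply(params, function(p) p * 0)
    dlogits <- probs
    dlogits[cbind(seq_len(ns), y)] <- dlogits[cbind(seq_len(ns), y)] - 1
    dlogits <- dlogits / ns
    grads[[paste0("W", L + 1L)]] <- crossprod(hs[[L + 1L]], dlogits)
    grads[[paste0("b", L + 1L)]] <- matrix(colSums(dlogits), 1L)
    dh_s <- tcrossprod(dlogits, params[[paste0("W", L + 1L)]])
    dh_t <- NULL
    for (l in rev(seq_len(L))) {
      if (use_mmd && !is.null(mmd_grads_s[[l]])) {
        dh_s <- dh_s + lam * mmd_grads_s[[l]]
        dh_t <- if (is.null(dh_t)) lam * mmd_grads_t[[l]]
                else dh_t + lam * mmd_grads_t[[l]]
      }
      dz_s <- dh_s * (zs[[l]] > 0)
      grads[[paste0("W", l)]] <- grads[[paste0("W", l)]] +
        crossprod(hs[[l]], dz_s)
      grads[[paste0("b", l)]] <- grads[[paste0("b", l)]] +
        matrix(colSums(dz_s), 1L)
      if (!is.null(dh_t)) {
        dz_t <- dh_t * (ht[[l + 1L]] > 0)
        grads[[paste0("W", l)]] <- grads[[paste0("W", l)]] +
          crossprod(ht[[l]], dz_t)
        grads[[paste0("b", l)]] <- grads[[paste0("b", l)]] +
          matrix(colSums(dz_t), 1L)
        if (l > 1L) dh_t <- tcrossprod(dz_t, params[[paste0("W", l)]])
      }
      if (l > 1L) dh_s <- tcrossprod(dz_s, params[[paste0("W", l)]])
    }

    if (config$weight_decay > 0)
      for (nm in grep("^W", names(params), value = TRUE))
        grads[[nm]] <- grads[[nm]] + config$weight_decay * params[[nm]]
    step <- adam_step(params, grads, opt, config$learning_rate)
    params <- step$params; opt <- step$state
  }

  structure(list(
    weights = lapply(seq_len(L), function(l) params[[paste0("W", l)]]),
    biases = lapply(seq_len(L), function(l) params[[paste0("b", l)]]),
    output_head = list(W = params[[paste0("W", L + 1L)]],
                       b = params[[paste0("b", L + 1L)]]),
    config = config,
    training_log = data.frame(epoch = seq_len(config$epochs),
                              ce_loss = log_ce, mmd = log_mmd)),
    class = "dan_model")
}

#' Extract latent features from a trained adaptation network
#'
#' Applies the ReLU recursion h(l+1) = ReLU(h(l) W(l) + b(l)) with h(0) = x
#' and returns the representation at the requested hidden layer. These latent
#' features feed the Euclidean distances of the similarity graph.
#'
#' @param model A `dan_model`.
#' @param x Feature matrix with the model's input dimension.
#' @param layer Hidden-layer index in 1:3 (default: last hidden layer).
#' @return The latent feature matrix (all entries >= 0, one row per sample).
#' @export
extract_latent <- function(model, x, layer = length(model$weights)) {
  stopifnot(inherits(model, "dan_model"))
  x <- as.matrix(x)
  if (!layer %in% seq_along(model$weights))
    stop("layer must be in 1:", length(model$weights))
  if (ncol(x) != nrow(model$weights[[1L]]))
    stop("input dimension (", ncol(x), ") does not match model (",
         nrow(model$weights[[1L]]), ")")
  h <- x
  for (l in seq_len(layer))
    h <- relu(sweep(h %*% model$weights[[l]], 2L, model$biases[[l]], "+"))
  h
}

#' Class probabilities from the adaptation network's own head
#'
#' @param model A `dan_model`.
#' @param x Feature matrix.
#' @return Matrix with columns `health`, `disease`.
#' @export
predict_dan <- function(model, x) {
  h <- extract_latent(model, x, length(model$weights))
  logits <- sweep(h %*% model$output_head$W, 2L, model$output_head$b, "+")
  p <- softmax_rows(logits)
  colnames(p) <- c("health", "disease")
  p
}
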