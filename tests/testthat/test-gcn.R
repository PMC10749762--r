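path_graph <- function() {
  # 3-node path 1-2-3
  knn_edges(pairwise_euclidean(matrix(c(0, 1, 2), 3, 1)), k = 1)
}

toy_weights <- function(conv, headW, headb = matrix(0, 1, 2)) {
  structure(list(conv = conv, head = list(W = headW, b = headb)),
            class = "gcn_weights")
}

test_that("all-zero weights give logits 0 and probabilities one half", {
  g <- path_graph()
  w <- toy_weights(list(matrix(0, 2, 3)), matrix(0, 3, 2))
  X <- matrix(rnorm(6), 3, 2)
  logits <- gcn_forward(g, X, w)
  expect_equal(logits, matrix(0, 3, 2))
  res <- predict_gcn(w, g, X)
  expect_equal(res$prob_health, rep(0.5, 3))
  expect_equal(res$predicted_label, rep("health", 3))  # tie rule
})

test_that("forward pass equals the hand-evaluated convolution on a path graph", {
  g <- path_graph()
  expect_equal(g$adjacency, matrix(c(0, 1, 0, 1, 0, 1, 0, 1, 0), 3, 3))
  X <- matrix(c(1, -1, 2), 3, 1)
  W1 <- matrix(1.5, 1, 1)
  hW <- matrix(c(2, -1), 1, 2)
  w <- toy_weights(list(W1), hW, matrix(c(0.1, -0.2), 1, 2))
  # direct evaluation of the definition
  S <- oracle_norm_operator(g$adjacency)
  H1 <- pmax(S %*% X %*% W1, 0)
  manual <- cbind(H1 * 2 + 0.1, H1 * -1 - 0.2)
  expect_equal(gcn_forward(g, X, w), manual, tolerance = 1e-12)
})

test_that("with only self-loops the GCN reduces to a per-node MLP", {
  n <- 6
  g <- structure(list(n = n, adjacency = matrix(0, n, n),
                      adjacency_with_self = diag(n),
                      norm_operator = diag(n),
                      node_order = as.character(1:n), k = 0L),
                 class = "similarity_graph")
  withr::with_seed(31, {
    X <- matrix(rnorm(n * 3), n, 3)
    w <- toy_weights(list(matrix(rnorm(12), 3, 4), matrix(rnorm(16), 4, 4)),
                     matrix(rnorm(8), 4, 2), matrix(rnorm(2), 1, 2))
    perm <- sample(n)
  })
  expect_equal(gcn_forward(g, X, w), oracle_mlp_forward(X, w),
               tolerance = 1e-12)
  # isolated nodes: permuting node order permutes outputs identically
  expect_equal(gcn_forward(g, X[perm, ], w), gcn_forward(g, X, w)[perm, ],
               tolerance = 1e-12)
})

test_that("node-permutation equivariance holds for connected graphs", {
  withr::with_seed(32, {
    x <- matrix(rnorm(30), 10, 3)
    feats <- matrix(rnorm(20), 10, 2)
    w <- toy_weights(list(matrix(rnorm(8), 2, 4)), matrix(rnorm(8), 4, 2))
    perm <- sample(10)
  })
  g <- knn_edges(pairwise_euclidean(x), k = 3)
  gp <- knn_edges(pairwise_euclidean(x[perm, ]), k = 3)
  expect_equal(gcn_forward(gp, feats[perm, ], w),
               gcn_forward(g, feats, w)[perm, ], tolerance = 1e-12)
})

sep_cliques <- function() {
  # two tight clusters, linearly separable features, one class per cluster
  withr::with_seed(33, {
    x <- rbind(matrix(rnorm(20, 0, 0.1), 10, 2),
               matrix(rnorm(20, 5, 0.1), 10, 2))
  })
  list(graph = knn_edges(pairwise_euclidean(x), k = 3),
       features = x,
       labels = rep(c("health", "disease"), each = 10))
}

test_that("the GCN fits separable cliques to training accuracy 1", {
  s <- sep_cliques()
  fit <- train_gcn(s$graph, s$features, s$labels, rep(TRUE, 20),
                   gcn_config(hidden_width = 8L, epochs = 80L))
  expect_equal(fit$result$predicted_label, s$labels)
  expect_equal(fit$result$prob_health + fit$result$prob_disease,
               rep(1, 20), tolerance = 1e-9)
})

test_that("labels of unmasked nodes never reach the loss (leakage guard)", {
  s <- sep_cliques()
  mask <- rep(c(TRUE, FALSE), 10)
  labs1 <- s$labels
  labs2 <- s$labels
  labs2[!mask] <- ifelse(labs2[!mask] == "disease", "health", "disease")
  cfg <- gcn_config(hidden_width = 8L, epochs = 40L)
  f1 <- train_gcn(s$graph, s$features, labs1, mask, cfg)
  f2 <- train_gcn(s$graph, s$features, labs2, mask, cfg)
  expect_identical(f1$weights, f2$weights)
  expect_identical(f1$result, f2$result)
})

test_that("unlabelled node features participate in the convolution", {
  s <- sep_cliques()
  mask <- rep(c(TRUE, FALSE), 10)
  cfg <- gcn_config(hidden_width = 8L, epochs = 40L)
  f1 <- train_gcn(s$graph, s$features, s$labels, mask, cfg)
  zeroed <- s$features
  zeroed[!mask, ] <- 0
  f2 <- train_gcn(s$graph, zeroed, s$labels, mask, cfg)
  expect_false(isTRUE(all.equal(f1$result$prob_disease[!mask],
                                f2$result$prob_disease[!mask])))
})

test_that("training validates the mask and reproduces under a shared seed", {
  s <- sep_cliques()
  expect_error(train_gcn(s$graph, s$features, rep("disease", 20),
                         rep(TRUE, 20)), "each class")
  cfg <- gcn_config(hidden_width = 8L, epochs = 30L)
  f1 <- train_gcn(s$graph, s$features, s$labels, rep(TRUE, 20), cfg)
  f2 <- train_gcn(s$graph, s$features, s$labels, rep(TRUE, 20), cfg)
  expect_identical(f1$weights, f2$weights)
})

test_that("predicted probabilities follow the softmax closed form", {
  g <- path_graph()
  # craft weights so node logits are known: zero conv, bias-only head
  w <- toy_weights(list(matrix(0, 1, 1)), matrix(0, 1, 2),
                   matrix(c(2, 0), 1, 2))
  res <- predict_gcn(w, g, matrix(0, 3, 1))
  expect_equal(res$prob_health, rep(1 / (1 + exp(-2)), 3), tolerance = 1e-9)
  expect_equal(res$predicted_label, rep("health", 3))
  expect_error(predict_gcn(list(), g, matrix(0, 3, 1)), "not a trained")
})
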