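# Independent oracles used across the suite. Each is a deliberately naive
# implementation (double loops, enumeration) kept separate from the package's
# code paths.

# AUC by brute-force pair counting: concordant + 0.5 * tied over pos x neg.
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (q in neg)
    total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  total / (length(pos) * length(neg))
}

# Euclidean distances by explicit double loop.
oracle_euclidean <- function(x) {
  n <- nrow(x)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    d[i, j] <- sqrt(sum((x[i, ] - x[j, ])^2))
  d
}

# Union-symmetrized kNN adjacency by enumeration, ties by node index.
oracle_knn_union <- function(d, k) {
  n <- nrow(d)
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    cand <- setdiff(seq_len(n), i)
    ord <- cand[order(d[i, cand], cand)]
    A[i, ord[seq_len(k)]] <- 1
  }
  pmax(A, t(A))
}

# Symmetric-normalized operator computed directly from its definition.
oracle_norm_operator <- function(A) {
  At <- A + diag(nrow(A))
  Dm <- diag(1 / sqrt(rowSums(At)))
  Dm %*% At %*% Dm
}

# Student-t upper quantile via numerical integration of the density plus
# root finding; independent of stats::qt.
oracle_t_quantile <- function(p, df) {
  dens <- function(x) gamma((df + 1) / 2) / (sqrt(df * pi) * gamma(df / 2)) *
    (1 + x^2 / df)^(-(df + 1) / 2)
  cdf <- function(q) 0.5 + stats::integrate(dens, 0, q,
                                            rel.tol = 1e-12)$value * sign(q)
  stats::uniroot(function(q) cdf(q) - p, c(0, 1000),
                 tol = 1e-10)$root
}

# Plain MLP forward pass mirroring GCN weights with an identity operator.
oracle_mlp_forward <- function(X, weights) {
  H <- X
  for (W in weights$conv) { H <- H %*% W; H[H < 0] <- 0 }
  sweep(H %*% weights$head$W, 2L, weights$head$b, "+")
}

# Permutation null for the MMD statistic: shuffle pooled rows.
mmd_permutation_null <- function(a, b, n_perm = 200, seed = 42) {
  pooled <- rbind(a, b)
  n <- nrow(a)
  withr::with_seed(seed, replicate(n_perm, {
    idx <- sample.int(nrow(pooled))
    mk_mmd(pooled[idx[seq_len(n)], , drop = FALSE],
           pooled[idx[-seq_len(n)], , drop = FALSE])
  }))
}

# Small labelled abundance matrix with one informative taxon.
tiny_dataset <- function(n = 30, p = 8, effect = 2, seed = 1) {
  withr::with_seed(seed, {
    lab <- rep(c("disease", "health"), length.out = n)
    logab <- matrix(rnorm(n * p), n, p)
    logab[lab == "disease", 1] <- logab[lab == "disease", 1] + effect
    ab <- exp(logab)
    ab <- ab / rowSums(ab)
    abundance_matrix(ab, sprintf("s%02d", seq_len(n)),
                     sprintf("sp_%02d", seq_len(p)), label = lab)
  })
}

# Fast configs for module-level pipeline tests.
fast_dan <- function(...) dan_config(layer_sizes = c(32L, 16L, 8L),
                                     epochs = 60L, ...)
fast_gcn <- function(...) gcn_config(hidden_width = 16L, epochs = 60L, ...)
fast_run <- function(seed = 1L, ...) run_config(dan = fast_dan(),
                                                gcn = fast_gcn(),
                                                seed = seed, ...)
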