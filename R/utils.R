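# Internal numerical helpers shared by the DAN and GCN trainers.

relu <- function(x) {
  x[x < 0] <- 0
  x
}

# Row-wise softmax with the usual max-shift for stability.
softmax_rows <- function(logits) {
  z <- logits - apply(logits, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

# Mean cross-entropy of one-hot targets given class probabilities.
# `probs` is n x 2, `y` is an integer vector of column indices (1-based).
cross_entropy <- function(probs, y) {
  p <- probs[cbind(seq_along(y), y)]
  -mean(log(pmax(p, 1e-300)))
}

# He-style initial weights drawn from the current RNG state.
init_weight <- function(fan_in, fan_out) {
  matrix(stats::rnorm(fan_in * fan_out, sd = sqrt(2 / fan_in)),
         nrow = fan_in, ncol = fan_out)
}

# Minimal Adam optimizer state over a named list of parameter matrices.
adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    mhat <- state$m[[nm]] / (1 - beta1^t)
    vhat <- state$v[[nm]] / (1 - beta2^t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

# Derive a child seed below 2^31 from a base seed and a stream index.
derive_seed <- function(seed, index) {
  (as.integer(seed) %% 1000003L) * 2039L + as.integer(index) * 7919L
}

`%||%` <- function(a, b) if (is.null(a)) b else a
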