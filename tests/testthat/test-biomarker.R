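test_that("rule applicability follows the biomarker's within-sample rank", {
  v <- c(a = 0.7, b = 0.2, c = 0.1)
  expect_setequal(applicable_rules(v, "a"), c("Max2Median", "Max2Min"))
  expect_setequal(applicable_rules(v, "c"), c("Min2Max", "Min2Median"))
  expect_setequal(applicable_rules(v, "b"), c("Middle2Max", "Middle2Min"))
  expect_error(applicable_rules(v, "z"), "not present")
})

test_that("abundance modification substitutes the sample statistic", {
  v <- c(a = 0.7, b = 0.2, c = 0.1)
  expect_equal(modify_abundance(v, "a", "Max2Min"),
               c(a = 0.1, b = 0.2, c = 0.1))
  expect_equal(modify_abundance(v, "a", "Max2Median"),
               c(a = 0.2, b = 0.2, c = 0.1))
  expect_equal(modify_abundance(v, "c", "Min2Max"),
               c(a = 0.7, b = 0.2, c = 0.7))
  expect_equal(modify_abundance(v, "b", "Middle2Min"),
               c(a = 0.7, b = 0.1, c = 0.1))
  expect_error(modify_abundance(v, "b", "Max2Min"), "not applicable")
  expect_error(modify_abundance(v, "a", "Sideways"), "unknown rule")
  # degenerate constant vector: every modification is the identity
  u <- c(a = 0.25, b = 0.25, c = 0.25, d = 0.25)
  expect_equal(modify_abundance(u, "a", applicable_rules(u, "a")[1]), u)
})

small_fit <- function(seed = 51) {
  tr <- tiny_dataset(n = 24, p = 6, seed = seed)
  te <- tiny_dataset(n = 8, p = 6, seed = seed + 1)
  blind <- abundance_matrix(te$values, paste0("t", 1:8), te$taxa)
  run_batch(tr, blind, fast_run(seed = seed, k_neighbors = 3))
}

test_that("contribution values are probability differences with direction", {
  fit <- small_fit()
  sid <- fit$train$sample_ids[1]
  raw <- fit$train$values[1, ]
  tx <- names(raw)[which.max(raw)]
  cv <- contribution_value(fit, sid, tx, "Max2Min")
  expect_equal(cv$value, abs(cv$p_before - cv$p_after), tolerance = 1e-12)
  expect_true(cv$direction %in% c("toward_disease", "toward_health", "none"))
  if (cv$direction == "toward_disease") expect_lt(cv$p_after, cv$p_before)
  if (cv$direction == "toward_health") expect_gt(cv$p_after, cv$p_before)

  # a modification that leaves the abundance unchanged has value 0:
  # replace the max by the max via a crafted sample with max == median
  expect_error(contribution_value(fit, "missing", tx, "Max2Min"), "unknown")
})

test_that("identity modifications contribute exactly zero", {
  fit <- small_fit(seed = 52)
  # constant raw row is impossible in compositional data, but a taxon whose
  # abundance already equals the sample minimum modified Min2Min-style:
  # Min2Median when median == min is an identity
  raw <- fit$train$values[2, ]
  p0 <- microgcn:::node_health_prob(fit, 2, raw)
  p1 <- microgcn:::node_health_prob(fit, 2, raw)  # unchanged row
  expect_identical(p0, p1)
})

test_that("contribution scores aggregate per-sample values consistently", {
  fit <- small_fit(seed = 53)
  marks <- fit$train$taxa[1:2]
  rep <- contribution_scores(fit, marks)
  types <- c("Increase2Disease", "Increase2Health",
             "Decrease2Disease", "Decrease2Health")
  expect_true(all(as.matrix(rep[, types]) >= 0))
  expect_true(all(as.matrix(rep[, types]) <= 1))
  per <- attr(rep, "per_sample")
  for (i in seq_along(marks)) {
    expect_equal(unname(unlist(rep[i, types])),
                 unname(colMeans(per[[marks[i]]])), tolerance = 1e-12)
    expect_equal(nrow(per[[marks[i]]]), rep$n_samples_used[i])
  }
})

test_that("modification never alters the graph topology", {
  fit <- small_fit(seed = 54)
  A_before <- fit$graph$adjacency
  invisible(contribution_scores(fit, fit$train$taxa[1]))
  expect_identical(fit$graph$adjacency, A_before)
})

test_that("single-feature AUC ranking recovers a perfectly separating taxon", {
  withr::with_seed(55, {
    n <- 30
    lab <- rep(c("disease", "health"), each = 15)
    ab <- matrix(runif(n * 5, 0.01, 0.2), n, 5)
    # taxon P separates classes perfectly; others are noise
    ab[, 3] <- ifelse(lab == "disease", runif(n, 0.5, 0.9), runif(n, 0.001, 0.01))
    ab <- ab / rowSums(ab)
  })
  m <- abundance_matrix(ab, sprintf("s%02d", 1:30), c("a", "b", "P", "c", "d"),
                        label = lab)
  rk <- rank_species_by_auc(m, k_neighbors = 3,
                            gcn = gcn_config(hidden_width = 8L, epochs = 60L))
  expect_equal(rk$taxon[1], "P")
  expect_gte(rk$auc[1], 0.95)
  expect_equal(rk$rank, 1:5)
})

test_that("duplicated taxa receive identical AUCs and adjacent ranks", {
  m <- tiny_dataset(n = 24, p = 4, seed = 56)
  vals <- cbind(m$values, m$values[, 1])
  dup <- abundance_matrix(vals, m$sample_ids, c(m$taxa, "sp_00_copy"),
                          label = m$label)
  rk <- rank_species_by_auc(dup, k_neighbors = 3,
                            gcn = gcn_config(hidden_width = 8L, epochs = 40L),
                            seed = 1)
  a1 <- rk$auc[rk$taxon == "sp_01"]
  a2 <- rk$auc[rk$taxon == "sp_00_copy"]
  expect_equal(a1, a2, tolerance = 1e-12)
  r <- sort(c(rk$rank[rk$taxon == "sp_01"], rk$rank[rk$taxon == "sp_00_copy"]))
  expect_equal(r[2] - r[1], 1)
  # name order breaks the tie: sp_00_copy sorts before sp_01
  expect_lt(rk$rank[rk$taxon == "sp_00_copy"], rk$rank[rk$taxon == "sp_01"])
})

test_that("a constant taxon scores at chance level", {
  aucs <- sapply(1:10, function(s) {
    m <- tiny_dataset(n = 24, p = 3, effect = 0, seed = 60 + s)
    vals <- cbind(m$values, 0.05)
    mc <- abundance_matrix(vals, m$sample_ids, c(m$taxa, "sp_const"),
                           label = m$label)
    rk <- rank_species_by_auc(mc, k_neighbors = 3,
                              gcn = gcn_config(hidden_width = 4L, epochs = 30L),
                              seed = s)
    rk$auc[rk$taxon == "sp_const"]
  })
  expect_gte(median(aucs), 0.4)
  expect_lte(median(aucs), 0.6)
})
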