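test_that("abundance tables round-trip through TSV in both orientations", {
  m <- abundance_matrix(matrix(c(0.5, 0.2, 0.5, 0.8), 2, 2),
                        c("s1", "s2"), c("taxA", "taxB"))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_abundance_table(m, path)
  back <- read_abundance_table(path)
  expect_identical(back$sample_ids, m$sample_ids)
  expect_identical(back$taxa, m$taxa)
  expect_equal(back$values, m$values)

  # samples-in-columns: 3 taxa x 2 samples reads as the manual transpose
  tall <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("taxon\ts1\ts2",
               "taxA\t0.1\t0.4",
               "taxB\t0.2\t0.5",
               "taxC\t0.7\t0.1"), tall)
  wide <- read_abundance_table(tall, orientation = "samples-in-columns")
  expect_equal(dim(wide$values), c(2L, 3L))
  expect_equal(unname(wide$values),
               matrix(c(0.1, 0.4, 0.2, 0.5, 0.7, 0.1), 2, 3),
               ignore_attr = TRUE)
  expect_identical(wide$sample_ids, c("s1", "s2"))
})

test_that("malformed tables are rejected with informative errors", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("id\ttaxA\ttaxA", "s1\t0.5\t0.5"), path)
  expect_error(read_abundance_table(path), "duplicate taxa")

  writeLines(c("id\ttaxA\ttaxB", "s1\t0.5\t-0.1"), path)
  expect_error(read_abundance_table(path), "negative")

  writeLines(c("id\ttaxA\ttaxB", "s1\t0.5\toops"), path)
  expect_error(read_abundance_table(path), "taxB")

  expect_error(abundance_matrix(matrix(1, 2, 1), c("a", "a"), "t"),
               "duplicate sample")
})

test_that("align_features unions taxa with zero fill and stays idempotent", {
  tr <- abundance_matrix(matrix(c(1, 2, 3, 4), 2, 2), c("s1", "s2"),
                         c("a", "b"))
  te <- abundance_matrix(matrix(c(5, 6, 7, 8), 2, 2), c("t1", "t2"),
                         c("b", "c"))
  al <- align_features(tr, te)
  expect_identical(al$train$taxa, c("a", "b", "c"))
  expect_identical(al$test$taxa, c("a", "b", "c"))
  expect_equal(unname(al$test$values[, 1]), c(0, 0))   # taxon a absent in test
  expect_equal(unname(al$train$values[, 3]), c(0, 0))  # taxon c absent in train
  expect_equal(unname(al$train$values[, 1:2]), unname(tr$values))

  al2 <- align_features(al$train, al$test)
  expect_equal(al2$train$values, al$train$values)
  expect_equal(al2$test$values, al$test$values)

  # identical taxon sets: values preserved up to column ordering
  te2 <- abundance_matrix(matrix(c(9, 9, 1, 1), 2, 2), c("t1", "t2"),
                          c("b", "a"))
  al3 <- align_features(tr, te2)
  expect_equal(al3$test$values[, "a"], c(t1 = 1, t2 = 1))

  # disjoint taxon sets still union, with a warning
  td <- abundance_matrix(matrix(1, 1, 1), "t1", "zzz")
  expect_warning(al4 <- align_features(tr, td), "no taxa")
  expect_identical(al4$train$taxa, c("a", "b", "zzz"))
})

test_that("log10 transform applies the pseudocount to every cell", {
  m <- matrix(c(0, 0.001, 1, 0.5), 2, 2)
  out <- log10_transform(m, 1e-5)
  expect_equal(out[1, 1], -5)
  expect_equal(out[2, 1], log10(0.00101))
  expect_error(log10_transform(m, 0), "pseudocount")
  expect_error(log10_transform(m, -1), "pseudocount")
})

test_that("z-score statistics use the population standard deviation", {
  x <- matrix(c(1, 2, 3, 5, 5, 5), 3, 2)
  st <- zscore_fit(x)
  expect_equal(unname(st$mean), c(2, 5))
  expect_equal(unname(st$sd), c(sqrt(2 / 3), 0))
  expect_error(zscore_fit(x[1, , drop = FALSE]), "at least 2")

  z <- suppressWarnings(zscore_apply(x, st))
  expect_equal(unname(z[, 1]), c(-1, 0, 1) * sqrt(3 / 2))
  expect_equal(unname(z[, 2]), c(0, 0, 0))   # zero-variance rule
  expect_warning(zscore_apply(x, st), "zero-variance")

  # value equal to the training mean standardizes to 0
  z0 <- suppressWarnings(zscore_apply(matrix(c(2, 5), 1, 2), st))
  expect_equal(unname(z0[1, 1]), 0)
  expect_error(zscore_apply(x[, 1, drop = FALSE], st), "dimension")
})

test_that("standardizing the fitting set yields mean 0 and population sd 1", {
  withr::with_seed(7, x <- matrix(rnorm(60, 3, 2), 12, 5))
  z <- zscore_apply(x, zscore_fit(x))
  expect_lt(max(abs(colMeans(z))), 1e-10)
  expect_lt(max(abs(sqrt(colMeans(sweep(z, 2, colMeans(z))^2)) - 1)), 1e-10)
})

test_that("training statistics never depend on the test matrix", {
  withr::with_seed(8, {
    tr <- matrix(rnorm(40), 8, 5)
    te <- matrix(rnorm(20), 4, 5)
  })
  st1 <- zscore_fit(tr)
  zscore_apply(te, st1)
  zscore_apply(te[sample(4), ], st1)
  st2 <- zscore_fit(tr)
  expect_identical(st1, st2)
})

test_that("metadata attaches labels and cohorts and round-trips", {
  m <- tiny_dataset(n = 6)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_metadata(m, path)
  meta <- read_metadata(path)
  expect_identical(meta$sample_id, m$sample_ids)
  bare <- abundance_matrix(m$values, m$sample_ids, m$taxa)
  back <- attach_metadata(bare, meta)
  expect_identical(back$label, m$label)
  expect_identical(back$cohort, m$cohort)
})

test_that("normalization statistics serialize to plain text and back", {
  m <- tiny_dataset(n = 10)
  st <- zscore_fit(log10_transform(m), 1e-5)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_norm_stats(st, path)
  back <- read_norm_stats(path)
  expect_equal(unname(back$mean), unname(st$mean))
  expect_equal(unname(back$sd), unname(st$sd))
  expect_equal(back$pseudocount, st$pseudocount)
})
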