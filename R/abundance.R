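#' Construct an abundance matrix
#'
#' The central data container: a samples-by-taxa matrix of non-negative
#' relative abundances together with per-sample cohort identifiers and
#' optional binary disease labels (`"disease"`, `"health"`, or `NA` for
#' unlabelled samples).
#'
#' @param values Numeric matrix, samples in rows, taxa in columns, all
#'   entries non-negative.
#' @param sample_ids Character vector of unique sample identifiers.
#' @param taxa Character vector of unique species names.
#' @param cohort Per-sample study identifier (recycled if length 1).
#' @param label Optional per-sample status: `"disease"`, `"health"` or `NA`.
#' @return An object of class `abundance_matrix`.
#' @export
abundance_matrix <- function(values, sample_ids, taxa,
                             cohort = "cohort1", label = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (nrow(values) != length(sample_ids))
    stop("row count (", nrow(values), ") != number of sample_ids (",
         length(sample_ids), ")")
  if (ncol(values) != length(taxa))
    stop("column count (", ncol(values), ") != number of taxa (",
         length(taxa), ")")
  if (anyDuplicated(sample_ids))
    stop("duplicate sample IDs: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  if (anyDuplicated(taxa))
    stop("duplicate taxa: ",
         paste(unique(taxa[duplicated(taxa)]), collapse = ", "))
  if (anyNA(values) || any(values < 0))
    stop("abundance values must be non-negative and non-missing")
  if (length(cohort) == 1L) cohort <- rep(cohort, nrow(values))
  if (length(cohort) != nrow(values))
    stop("cohort must have one entry per sample")
  if (is.null(label)) label <- rep(NA_character_, nrow(values))
  if (length(label) != nrow(values))
    stop("label must have one entry per sample")
  label <- as.character(label)
  bad <- !is.na(label) & !label %in% c("disease", "health")
  if (any(bad))
    stop("labels must be 'disease', 'health' or NA; got: ",
         paste(unique(label[bad]), collapse = ", "))
  dimnames(values) <- list(as.character(sample_ids), as.character(taxa))
  structure(list(values = values,
                 sample_ids = as.character(sample_ids),
                 taxa = as.character(taxa),
                 cohort = as.character(cohort),
                 label = label),
            class = "abundance_matrix")
}

#' @export
print.abundance_matrix <- function(x, ...) {
  nl <- sum(!is.na(x$label))
  cat("abundance_matrix: ", length(x$sample_ids), " samples x ",
      length(x$taxa), " taxa\n", sep = "")
  cat("  cohorts: ", paste(unique(x$cohort), collapse = ", "), "\n", sep = "")
  cat("  labelled samples: ", nl, " (",
      sum(x$label == "disease", na.rm = TRUE), " disease / ",
      sum(x$label == "health", na.rm = TRUE), " health)\n", sep = "")
  invisible(x)
}

#' Subset samples of an abundance matrix
#'
#' @param m An `abundance_matrix`.
#' @param idx Integer or logical index over samples.
#' @return An `abundance_matrix` with the selected samples.
#' @export
subset_samples <- function(m, idx) {
  abundance_matrix(m$values[idx, , drop = FALSE],
                   m$sample_ids[idx], m$taxa,
                   cohort = m$cohort[idx], label = m$label[idx])
}

#' Concatenate abundance matrices sharing a taxon set
#'
#' @param ... `abundance_matrix` objects with identical taxa.
#' @return A single `abundance_matrix`; sample order follows the arguments.
#' @export
bind_samples <- function(...) {
  ms <- list(...)
  if (length(ms) == 1L && is.list(ms[[1]]) && !inherits(ms[[1]], "abundance_matrix"))
    ms <- ms[[1]]
  taxa <- ms[[1]]$taxa
  for (m in ms)
    if (!identical(m$taxa, taxa)) stop("taxa differ; align_features() first")
  abundance_matrix(do.call(rbind, lapply(ms, `[[`, "values")),
                   unlist(lapply(ms, `[[`, "sample_ids")), taxa,
                   cohort = unlist(lapply(ms, `[[`, "cohort")),
                   label = unlist(lapply(ms, `[[`, "label")))
}

#' Read a tab-separated abundance table
#'
#' Ingests MetaPhlAn/mOTU-style species profiles. The first column (or the
#' header, for `samples-in-columns`) carries identifiers; all remaining cells
#' must be non-negative numbers.
#'
#' @param path Path to a TSV file with a header line.
#' @param orientation `"samples-in-rows"` (default) or `"samples-in-columns"`.
#' @param cohort,label Optional per-sample annotations passed through to
#'   [abundance_matrix()]; usually attached later from metadata via
#'   [attach_metadata()].
#' @return An `abundance_matrix`, always samples-in-rows.
#' @export
read_abundance_table <- function(path,
                                 orientation = c("samples-in-rows",
                                                 "samples-in-columns"),
                                 cohort = "cohort1", label = NULL) {
  orientation <- match.arg(orientation)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character")
  if (ncol(df) < 2L) stop("table must have an ID column plus data columns")
  row_ids <- df[[1L]]
  col_ids <- colnames(df)[-1L]
  cells <- as.matrix(df[, -1L, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(cells), dim = dim(cells)))
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1L, ]
    stop("non-numeric cell at row '", row_ids[bad[1L]], "', column '",
         col_ids[bad[2L]], "'")
  }
  if (any(num < 0)) {
    bad <- which(num < 0, arr.ind = TRUE)[1L, ]
    stop("negative abundance at row '", row_ids[bad[1L]], "', column '",
         col_ids[bad[2L]], "'")
  }
  if (orientation == "samples-in-rows") {
    abundance_matrix(num, sample_ids = row_ids, taxa = col_ids,
                     cohort = cohort, label = label)
  } else {
    abundance_matrix(t(num), sample_ids = col_ids, taxa = row_ids,
                     cohort = cohort, label = label)
  }
}

#' Write an abundance table as TSV (samples in rows)
#'
#' @param m An `abundance_matrix`.
#' @param path Output path.
#' @export
write_abundance_table <- function(m, path) {
  df <- data.frame(sample_id = m$sample_ids, m$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample metadata table
#'
#' Expects tab-separated columns `sample_id`, `label` (one of `disease`,
#' `health`, `unknown`) and `cohort`.
#'
#' @param path Path to the metadata TSV.
#' @return A data.frame with columns sample_id, label, cohort.
#' @export
read_metadata <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("sample_id", "label", "cohort")
  miss <- setdiff(need, colnames(df))
  if (length(miss)) stop("metadata missing columns: ",
                         paste(miss, collapse = ", "))
  bad <- !df$label %in% c("disease", "health", "unknown")
  if (any(bad)) stop("metadata labels must be disease/health/unknown; got: ",
                     paste(unique(df$label[bad]), collapse = ", "))
  df[, need]
}

#' Attach metadata labels and cohorts to an abundance matrix
#'
#' @param m An `abundance_matrix`.
#' @param meta A data.frame as returned by [read_metadata()].
#' @return The annotated `abundance_matrix`.
#' @export
attach_metadata <- function(m, meta) {
  i <- match(m$sample_ids, meta$sample_id)
  if (anyNA(i)) stop("metadata missing samples: ",
                     paste(m$sample_ids[is.na(i)], collapse = ", "))
  lab <- meta$label[i]
  lab[lab == "unknown"] <- NA_character_
  abundance_matrix(m$values, m$sample_ids, m$taxa,
                   cohort = meta$cohort[i], label = lab)
}

#' Write per-sample metadata as TSV
#'
#' @param m An `abundance_matrix`.
#' @param path Output path.
#' @export
write_metadata <- function(m, path) {
  lab <- m$label
  lab[is.na(lab)] <- "unknown"
  utils::write.table(
    data.frame(sample_id = m$sample_ids, label = lab, cohort = m$cohort,
               stringsAsFactors = FALSE),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Align the taxon spaces of two abundance matrices
#'
#' Cohorts profiled in different studies rarely share an identical species
#' list. Both matrices are projected onto the union of their taxa, sorted
#' lexicographically for determinism; taxa absent from one input are filled
#' with abundance 0. Sample order is preserved.
#'
#' @param train,test `abundance_matrix` objects.
#' @return A list with elements `train` and `test` on the common taxon set.
#' @export
align_features <- function(train, test) {
  union_taxa <- sort(union(train$taxa, test$taxa))
  if (length(union_taxa) == 0L) stop("empty taxon union")
  if (length(intersect(train$taxa, test$taxa)) == 0L)
    warning("train and test share no taxa; aligned matrices are disjoint")
  project <- function(m) {
    out <- matrix(0, nrow(m$values), length(union_taxa),
                  dimnames = list(m$sample_ids, union_taxa))
    out[, m$taxa] <- m$values
    abundance_matrix(out, m$sample_ids, union_taxa,
                     cohort = m$cohort, label = m$label)
  }
  list(train = project(train), test = project(test))
}
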