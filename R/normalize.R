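#' Log10-transform an abundance matrix
#'
#' Relative-abundance profiles are heavily right-skewed, so node features are
#' log10-transformed before z-scoring. A positive pseudocount is added to
#' every cell (not only zeros) so that zero abundances are defined and the
#' within-taxon ordering of values is preserved.
#'
#' @param m An `abundance_matrix` or a plain numeric matrix.
#' @param pseudocount Positive scalar added to all cells before `log10`.
#'   The default `1e-5` sits below the smallest nonzero abundance typical of
#'   species-level MetaPhlAn profiles.
#' @return A numeric matrix of the same shape, with dimnames preserved.
#' @export
log10_transform <- function(m, pseudocount = 1e-5) {
  if (!is.numeric(pseudocount) || length(pseudocount) != 1L ||
      !is.finite(pseudocount) || pseudocount <= 0)
    stop("pseudocount must be a positive scalar")
  v <- if (inherits(m, "abundance_matrix")) m$values else as.matrix(m)
  log10(v + pseudocount)
}

#' Fit per-taxon z-score statistics on training data
#'
#' Means and population standard deviations are computed on the
#' log-transformed *training* matrix only; test data are later standardized
#' with these frozen statistics so no test information leaks into
#' normalization.
#'
#' @param train_logged Numeric matrix of log-transformed training values
#'   (samples x taxa), at least 2 rows.
#' @param pseudocount The pseudocount used for the log transform; stored for
#'   provenance so a fitted normalization can be re-applied to raw data.
#' @return An object of class `norm_stats` with fields `mean`, `sd`
#'   (population, i.e. divisor n) and `pseudocount`.
#' @export
zscore_fit <- function(train_logged, pseudocount = 1e-5) {
  x <- as.matrix(train_logged)
  if (nrow(x) < 2L) stop("need at least 2 training samples to fit z-scores")
  mu <- colMeans(x)
  sdev <- sqrt(colMeans(sweep(x, 2L, mu)^2))
  structure(list(mean = mu, sd = sdev, pseudocount = pseudocount,
                 taxa = colnames(x)),
            class = "norm_stats")
}

#' Apply fitted z-score statistics
#'
#' Taxa whose training standard deviation is zero carry no information for
#' the classifier; their standardized value is defined as 0 and a warning
#' lists them.
#'
#' @param m_logged Numeric matrix of log-transformed values (samples x taxa).
#' @param stats A `norm_stats` object fitted on training data.
#' @return The standardized matrix.
#' @export
zscore_apply <- function(m_logged, stats) {
  x <- as.matrix(m_logged)
  if (ncol(x) != length(stats$mean))
    stop("taxon dimension (", ncol(x), ") does not match fitted stats (",
         length(stats$mean), ")")
  out <- sweep(x, 2L, stats$mean)
  zero <- stats$sd == 0
  if (any(zero)) {
    nm <- stats$taxa %||% as.character(which(zero))
    warning("zero-variance taxa standardized to 0: ",
            paste(utils::head(nm[zero], 10L), collapse = ", "),
            if (sum(zero) > 10L) ", ...")
    out[, zero] <- 0
  }
  if (any(!zero))
    out[, !zero] <- sweep(out[, !zero, drop = FALSE], 2L, stats$sd[!zero], "/")
  out
}

#' Normalize raw abundances with frozen training statistics
#'
#' Convenience wrapper: `log10_transform` with the pseudocount stored in
#' `stats`, then [zscore_apply()].
#'
#' @param m An `abundance_matrix` or numeric matrix of raw abundances.
#' @param stats A `norm_stats` object.
#' @return The normalized feature matrix.
#' @export
normalize_with <- function(m, stats) {
  suppressWarnings(zscore_apply(log10_transform(m, stats$pseudocount), stats))
}

#' Serialize normalization statistics to a plain-text key-value file
#'
#' @param stats A `norm_stats` object.
#' @param path Output path.
#' @export
write_norm_stats <- function(stats, path) {
  df <- data.frame(taxon = stats$taxa %||% seq_along(stats$mean),
                   mean = stats$mean, sd = stats$sd)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#pseudocount\t%.17g", stats$pseudocount), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read normalization statistics written by [write_norm_stats()]
#'
#' @param path Input path.
#' @return A `norm_stats` object.
#' @export
read_norm_stats <- function(path) {
  first <- readLines(path, n = 1L)
  pc <- as.numeric(strsplit(first, "\t")[[1L]][2L])
  df <- utils::read.delim(path, skip = 1L, stringsAsFactors = FALSE)
  structure(list(mean = stats::setNames(df$mean, df$taxon),
                 sd = stats::setNames(df$sd, df$taxon),
                 pseudocount = pc, taxa = df$taxon),
            class = "norm_stats")
}
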