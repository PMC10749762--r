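#' Configuration for the multi-cohort compositional data simulator
#'
#' Emulates species-level relative-abundance profiles from several study
#' cohorts: per-taxon log-normal base abundances shared by all cohorts,
#' a handful of planted disease-associated taxa whose log abundance is
#' shifted in case samples, cohort-level additive log-scale offsets that
#' mimic study/batch effects (region, diet, protocol), and compositional
#' closure (rows renormalized to sum to 1).
#'
#' @param n_taxa Number of species.
#' @param n_samples_per_cohort Samples per cohort.
#' @param n_cohorts Number of cohorts.
#' @param planted_taxa Data.frame with columns `index` (taxon index),
#'   `direction` (`"promote"`: higher in disease; `"protect"`: lower in
#'   disease) and `effect` (positive log-fold effect size, natural-log
#'   units). Default: 5 planted taxa, 3 promoters and 2 protectors, effect
#'   2 log units (~7.4-fold, typical of strong disease markers).
#' @param base_log_mean Per-taxon mean log abundance; `NULL` draws one
#'   N(0, 1) profile deterministically from `seed`.
#' @param base_log_sd Per-taxon biological variation (log scale).
#' @param domain_shift Standard deviation of the per-cohort per-taxon
#'   additive log offsets; 0 removes cohort structure.
#' @param noise_sd Extra measurement noise on the log scale.
#' @param case_fraction Fraction of disease samples per cohort.
#' @param seed Master seed; each cohort derives its own stream.
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_taxa = 100L,
                         n_samples_per_cohort = 100L,
                         n_cohorts = 3L,
                         planted_taxa = default_planted(n_taxa),
                         base_log_mean = NULL,
                         base_log_sd = 1.0,
                         domain_shift = 1.0,
                         noise_sd = 0,
                         case_fraction = 0.5,
                         seed = 1L) {
  if (nrow(planted_taxa) > 0L) {
    if (any(planted_taxa$index > n_taxa) || any(planted_taxa$index < 1L))
      stop("planted taxon indices must lie in 1:n_taxa")
    if (any(planted_taxa$effect < 0)) stop("effect sizes must be >= 0")
    if (!all(planted_taxa$direction %in% c("promote", "protect")))
      stop("directions must be 'promote' or 'protect'")
  }
  if (case_fraction <= 0 || case_fraction >= 1)
    stop("case_fraction must be in (0, 1)")
  structure(list(n_taxa = as.integer(n_taxa),
                 n_samples_per_cohort = as.integer(n_samples_per_cohort),
                 n_cohorts = as.integer(n_cohorts),
                 planted_taxa = planted_taxa,
                 base_log_mean = base_log_mean,
                 base_log_sd = base_log_sd,
                 domain_shift = domain_shift,
                 noise_sd = noise_sd,
                 case_fraction = case_fraction,
                 seed = as.integer(seed)),
            class = "synth_config")
}

#' Default planted-taxon layout: 5 markers spread across the taxon range
#'
#' @param n_taxa Number of taxa in the simulated profile.
#' @param effect Log-fold effect size shared by all planted taxa.
#' @return A data.frame with columns index, direction, effect.
#' @export
default_planted <- function(n_taxa, effect = 2.0) {
  idx <- unique(pmax(1L, round(seq(0.1, 0.9, length.out = 5L) * n_taxa)))
  data.frame(index = idx,
             direction = rep(c("promote", "protect"), length.out = length(idx)),
             effect = effect)
}

# Shared across cohorts: base log-abundance profile, drawn once from seed.
base_profile <- function(config) {
  if (!is.null(config$base_log_mean)) {
    if (length(config$base_log_mean) != config$n_taxa)
      stop("base_log_mean must have n_taxa entries")
    return(config$base_log_mean)
  }
  with_seed(derive_seed(config$seed, 0L), stats::rnorm(config$n_taxa, 0, 1))
}

#' Generate one cohort of compositional abundance data
#'
#' Per sample, log abundances are drawn from per-taxon normals around the
#' shared base profile; case samples receive the planted effects (sign set
#' by the promote/protect direction); the cohort's own additive log-scale
#' offsets are added; values are exponentiated and each row is renormalized
#' to sum to 1. The output is fully determined by `(seed, cohort_index)`.
#'
#' @param config A [synth_config()].
#' @param cohort_index Cohort number in `1:n_cohorts`.
#' @return A labelled `abundance_matrix` with cohort ID
#'   `"cohort<cohort_index>"`.
#' @export
generate_cohort <- function(config, cohort_index) {
  stopifnot(inherits(config, "synth_config"))
  if (cohort_index < 1L || cohort_index > config$n_cohorts)
    stop("cohort_index must be in 1:", config$n_cohorts)
  p <- config$n_taxa; n <- config$n_samples_per_cohort
  mu <- base_profile(config)
  with_seed(derive_seed(config$seed, cohort_index), {
    shift <- if (config$domain_shift > 0)
      stats::rnorm(p, 0, config$domain_shift) else rep(0, p)
    n_case <- round(config$case_fraction * n)
    label <- rep("health", n)
    label[sample.int(n, n_case)] <- "disease"
    logab <- matrix(stats::rnorm(n * p, 0, config$base_log_sd), n, p,
                    byrow = FALSE)
    if (config$noise_sd > 0)
      logab <- logab + matrix(stats::rnorm(n * p, 0, config$noise_sd), n, p)
    logab <- sweep(logab, 2L, mu + shift, "+")
    if (nrow(config$planted_taxa) > 0L) {
      sign <- ifelse(config$planted_taxa$direction == "promote", 1, -1)
      cases <- label == "disease"
      for (r in seq_len(nrow(config$planted_taxa))) {
        j <- config$planted_taxa$index[r]
        logab[cases, j] <- logab[cases, j] +
          sign[r] * config$planted_taxa$effect[r]
      }
    }
    ab <- exp(logab)
    ab <- ab / rowSums(ab)                  # compositional closure
    abundance_matrix(ab,
                     sample_ids = sprintf("C%d_S%03d", cohort_index, seq_len(n)),
                     taxa = sprintf("sp_%03d", seq_len(p)),
                     cohort = sprintf("cohort%d", cohort_index),
                     label = label)
  })
}

#' Generate all cohorts of a multi-domain dataset
#'
#' Cohorts share the base profile and planted effects but differ in their
#' domain-shift offsets, making the output suitable for leave-one-study-out
#' and adaptation experiments.
#'
#' @param config A [synth_config()] with `n_cohorts >= 2`.
#' @return A named list of `abundance_matrix` objects.
#' @export
generate_multidomain <- function(config) {
  if (config$n_cohorts < 2L) stop("need n_cohorts >= 2")
  stats::setNames(lapply(seq_len(config$n_cohorts),
                         function(i) generate_cohort(config, i)),
                  sprintf("cohort%d", seq_len(config$n_cohorts)))
}

#' Write the standard simulated fixture dataset as TSV files
#'
#' Emits one abundance table and one metadata table per cohort in the same
#' formats [read_abundance_table()] and [read_metadata()] consume.
#'
#' @param dir Output directory (created if needed).
#' @param config A [synth_config()]; the default is the standard 3-cohort,
#'   100-sample, 100-taxon dataset with 5 planted taxa.
#' @return The directory path, invisibly.
#' @export
write_fixture <- function(dir, config = synth_config()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (m in generate_multidomain(config)) {
    cid <- m$cohort[1L]
    write_abundance_table(m, file.path(dir, paste0(cid, "_abundance.tsv")))
    write_metadata(m, file.path(dir, paste0(cid, "_metadata.tsv")))
  }
  invisible(dir)
}
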