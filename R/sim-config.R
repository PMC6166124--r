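#' Simulation configuration
#'
#' Bundles every tunable of the synthetic-data generator.  The defaults
#' describe a desk-scale cohort with the statistical structure of a large
#' tissue panel: tens of samples, per-site editing rates drawn from a broad
#' range, beta-distributed sample-to-sample spread around the cohort mean,
#' uniform substitution sequencing error, and a mixture of plus- and
#' minus-strand genes.
#'
#' @param reference_length length of the simulated reference contig (bases).
#' @param n_genes number of non-overlapping genes placed on the contig.
#' @param minus_strand_fraction fraction of genes on the '-' strand.
#' @param n_edit_sites number of A-to-G editing sites planted inside genes
#'   (on the transcribed strand the reference base is always A).
#' @param rate_range length-2 numeric, range of true editing rates; a
#'   degenerate range (e.g. \code{c(0.23, 0.23)}) fixes the rate exactly.
#' @param per_sample_dispersion beta concentration \eqn{\kappa}: each
#'   sample's rate at a site is drawn from
#'   \eqn{Beta(\mu\kappa, (1-\mu)\kappa)} around the cohort mean \eqn{\mu}.
#'   Larger values mean less sample-to-sample spread; \code{Inf} disables
#'   the beta layer entirely (binomial-only variance).
#' @param error_rate per-base substitution error probability, spread
#'   uniformly over the three alternative bases.
#' @param read_length simulated read length (bases, ungapped).
#' @param mean_depth mean read coverage per site (Poisson across positions).
#' @param n_samples default number of samples when no explicit cohort
#'   design is given.
#' @param seed master RNG seed; identical configs (including seed) give
#'   byte-identical output.
#' @param n_snp_like number of SNP-like confounder positions (a fixed half
#'   of samples look homozygous G).
#' @param n_multi_mismatch number of confounder positions emitting A-to-C
#'   mismatches at an editing-like rate.
#' @param n_hypervariable number of hypervariable intervals with elevated
#'   mismatches of all classes.
#' @param hypervariable_width width (bases) of each hypervariable interval.
#' @param hypervariable_rate per-class mismatch rate inside hypervariable
#'   intervals.
#'
#' @return an object of class \code{sim_config} (a validated list).
#' @examples
#' cfg <- sim_config(reference_length = 5000, n_genes = 4, n_edit_sites = 10)
#' cfg$rate_range
#' @export
sim_config <- function(reference_length = 20000L,
                       n_genes = 10L,
                       minus_strand_fraction = 0.5,
                       n_edit_sites = 50L,
                       rate_range = c(0.1, 0.9),
                       per_sample_dispersion = 70,
                       error_rate = 0.001,
                       read_length = 100L,
                       mean_depth = 50,
                       n_samples = 50L,
                       seed = 1L,
                       n_snp_like = 0L,
                       n_multi_mismatch = 0L,
                       n_hypervariable = 0L,
                       hypervariable_width = 50L,
                       hypervariable_rate = 0.05) {
  cfg <- list(
    reference_length = as.integer(reference_length),
    n_genes = as.integer(n_genes),
    minus_strand_fraction = minus_strand_fraction,
    n_edit_sites = as.integer(n_edit_sites),
    rate_range = as.numeric(rate_range),
    per_sample_dispersion = per_sample_dispersion,
    error_rate = error_rate,
    read_length = as.integer(read_length),
    mean_depth = mean_depth,
    n_samples = as.integer(n_samples),
    seed = as.integer(seed),
    n_snp_like = as.integer(n_snp_like),
    n_multi_mismatch = as.integer(n_multi_mismatch),
    n_hypervariable = as.integer(n_hypervariable),
    hypervariable_width = as.integer(hypervariable_width),
    hypervariable_rate = hypervariable_rate
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  counts <- c("reference_length", "n_genes", "n_edit_sites", "read_length",
              "n_samples", "n_snp_like", "n_multi_mismatch",
              "n_hypervariable", "hypervariable_width")
  for (f in counts) {
    if (is.na(cfg[[f]]) || cfg[[f]] < 0L) {
      stop(sprintf("'%s' must be a non-negative count", f), call. = FALSE)
    }
  }
  stop_if_not_fraction(cfg$minus_strand_fraction, "minus_strand_fraction")
  stop_if_not_fraction(cfg$error_rate, "error_rate")
  stop_if_not_fraction(cfg$hypervariable_rate, "hypervariable_rate")
  if (length(cfg$rate_range) != 2L || any(cfg$rate_range < 0) ||
      any(cfg$rate_range > 1) || cfg$rate_range[1] > cfg$rate_range[2]) {
    stop("'rate_range' must be an ordered pair of fractions in [0, 1]",
         call. = FALSE)
  }
  if (cfg$per_sample_dispersion <= 0) {
    stop("'per_sample_dispersion' must be positive (Inf allowed)",
         call. = FALSE)
  }
  if (cfg$mean_depth < 0) stop("'mean_depth' must be >= 0", call. = FALSE)
  if (cfg$read_length > cfg$reference_length) {
    stop("'read_length' must not exceed 'reference_length'", call. = FALSE)
  }
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Simulation configuration\n")
  cat(sprintf("  reference: %d bp, %d genes (%.0f%% minus-strand)\n",
              x$reference_length, x$n_genes,
              100 * x$minus_strand_fraction))
  cat(sprintf("  editing:   %d sites, rates in [%.3f, %.3f], dispersion %s\n",
              x$n_edit_sites, x$rate_range[1], x$rate_range[2],
              format(x$per_sample_dispersion)))
  cat(sprintf("  reads:     length %d, mean depth %.0f, error rate %.2g\n",
              x$read_length, x$mean_depth, x$error_rate))
  cat(sprintf("  cohort:    %d samples, seed %d\n", x$n_samples, x$seed))
  invisible(x)
}
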