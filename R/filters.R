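#' Per-tissue filter cutoff profile
#'
#' A profile bundles the cutoffs applied by the cascade: the per-sample
#' support predicate (minimum editing index, consensus reads, minimal
#' coverage), the cohort-level minimum number of supporting samples, and
#' two auxiliary thresholds governing the multi-editing and consistency
#' stages.  All comparisons against cutoffs are inclusive (\code{>=}).
#'
#' @param tissue tissue label.
#' @param min_editing minimum per-sample editing index for support.
#' @param consensus_reads minimum number of alt-carrying (G) reads a
#'   sample needs for the site to count as edited there.
#' @param min_coverage minimum per-sample read coverage for support.
#' @param min_supporting_samples minimum number of supporting samples for
#'   a site to survive.
#' @param max_other_alt_fraction a sample is excluded at a site when
#'   non-G alternatives exceed this fraction of all alternative reads.
#' @param min_dominant_sample_fraction a site is dropped when fewer than
#'   this fraction of qualifying samples have G as dominant alternative.
#' @return an object of class \code{filter_profile}.
#' @export
filter_profile <- function(tissue,
                           min_editing,
                           consensus_reads,
                           min_coverage,
                           min_supporting_samples,
                           max_other_alt_fraction = 0.2,
                           min_dominant_sample_fraction = 0.8) {
  stop_if_not_fraction(min_editing, "min_editing", open = TRUE)
  for (f in c(consensus_reads, min_coverage, min_supporting_samples)) {
    if (f < 1L) stop("integer cutoffs must be >= 1", call. = FALSE)
  }
  if (max_other_alt_fraction <= 0 || max_other_alt_fraction > 1 ||
      min_dominant_sample_fraction <= 0 || min_dominant_sample_fraction > 1) {
    stop("auxiliary fractions must be in (0, 1]", call. = FALSE)
  }
  structure(list(tissue = tissue,
                 min_editing = min_editing,
                 consensus_reads = as.integer(consensus_reads),
                 min_coverage = as.integer(min_coverage),
                 min_supporting_samples = as.integer(min_supporting_samples),
                 max_other_alt_fraction = max_other_alt_fraction,
                 min_dominant_sample_fraction = min_dominant_sample_fraction),
            class = "filter_profile")
}

#' @export
print.filter_profile <- function(x, ...) {
  cat(sprintf(
    "Filter profile '%s': min_editing %.2f, consensus reads %d, min coverage %d, min supporting samples %d\n",
    x$tissue, x$min_editing, x$consensus_reads, x$min_coverage,
    x$min_supporting_samples))
  invisible(x)
}

#' Built-in per-tissue cutoff profiles
#'
#' The five cardiovascular-tissue profiles, tuned (in the original
#' analysis) for optimal A-to-G enrichment over all other mismatch classes
#' together with the number of predicted sites.
#'
#' @param tissue optional: return a single named profile.
#' @return a named list of \code{\link{filter_profile}} objects, or one
#'   profile when \code{tissue} is given.
#' @examples
#' builtin_profiles("aorta")$min_coverage
#' @export
builtin_profiles <- function(tissue = NULL) {
  profs <- list(
    aorta = filter_profile("aorta", 0.05, 2L, 15L, 70L),
    ventricular_appendage = filter_profile("ventricular_appendage",
                                           0.05, 2L, 5L, 70L),
    coronaries = filter_profile("coronaries", 0.03, 2L, 15L, 70L),
    tibial_artery = filter_profile("tibial_artery", 0.05, 2L, 5L, 70L),
    left_ventricle = filter_profile("left_ventricle", 0.03, 2L, 5L, 100L)
  )
  if (is.null(tissue)) return(profs)
  key <- gsub("[ -]", "_", tolower(tissue))
  if (!key %in% names(profs)) {
    stop(sprintf("unknown tissue '%s'; available: %s", tissue,
                 paste(names(profs), collapse = ", ")), call. = FALSE)
  }
  profs[[key]]
}

#' Per-sample support predicate
#'
#' A sample supports a site when, in that sample, coverage >=
#' \code{min_coverage}, alt (G) reads >= \code{consensus_reads} and the
#' editing index >= \code{min_editing} — all inclusive.
#'
#' @param cc candidate count matrices from the cascade (or a list with
#'   \code{ref}, \code{alt}, \code{coverage} matrices / vectors).
#' @param profile a \code{\link{filter_profile}}.
#' @return logical matrix (candidates x samples) of support flags.
#' @export
sample_supports <- function(cc, profile) {
  idx <- cc$alt / (cc$ref + cc$alt)
  supp <- cc$coverage >= profile$min_coverage &
    cc$alt >= profile$consensus_reads &
    !is.na(idx) & idx >= profile$min_editing
  supp[is.na(supp)] <- FALSE
  supp
}

#' Multi-editing per-sample exclusion
#'
#' A sample is excluded at a site when its non-G alternative reads exceed
#' \code{max_other_alt_fraction} of all alternative (non-reference) reads
#' there — provided at least \code{consensus_reads} alternative reads
#' exist (too few alternative reads to judge: the sample is kept, not
#' penalised).  Excluded samples cannot support the site.
#'
#' @inheritParams sample_supports
#' @return logical matrix (candidates x samples): TRUE = excluded.
#' @export
multi_editing_exclusions <- function(cc, profile) {
  alt_total <- cc$coverage - cc$ref
  other <- alt_total - cc$alt
  judged <- alt_total >= profile$consensus_reads
  frac <- ifelse(alt_total > 0, other / alt_total, 0)
  excl <- judged & frac > profile$max_other_alt_fraction
  excl[is.na(excl)] <- FALSE
  excl
}

#' Cross-sample consistency filter
#'
#' Among samples with at least \code{consensus_reads} alternative reads at
#' the site, the fraction whose dominant alternative base is G (the
#' candidate's alt) must reach \code{min_dominant_sample_fraction};
#' otherwise the site is inconsistently edited (e.g. some samples show
#' A-to-G while others show A-to-C) and is dropped.  Sites with no
#' qualifying sample at all are dropped: they cannot be called reliably
#' edited.  The candidate alt wins dominance ties.
#'
#' @param bcm the \code{\link{base_count_matrix}}.
#' @param cand candidate data.frame (rows aligned with \code{cc}).
#' @inheritParams sample_supports
#' @return logical vector per candidate: TRUE = kept.
#' @export
consistency_keep <- function(bcm, cand, cc, profile) {
  alt_total <- cc$coverage - cc$ref
  judged <- alt_total >= profile$consensus_reads
  # dominant alternative: candidate alt count >= every other alt count
  other_max <- matrix(0L, nrow(cand), length(bcm$samples))
  for (b in c("A", "C", "G", "T")) {
    rows <- which(cand$ref != b & cand$alt != b)
    if (length(rows)) {
      other_max[rows, ] <- pmax(other_max[rows, , drop = FALSE],
                                bcm$counts[[b]][cand$idx[rows], , drop = FALSE])
    }
  }
  dominant <- cc$alt >= other_max & cc$alt > 0L
  n_judged <- rowSums(judged)
  n_dom <- rowSums(judged & dominant)
  keep <- n_judged > 0L &
    (n_dom / pmax(n_judged, 1L)) >= profile$min_dominant_sample_fraction
  keep
}

#' Remove sites falling in blacklist intervals
#'
#' @param sites data.frame with \code{contig} and \code{pos} (0-based)
#'   columns.
#' @param blacklist a \code{GRanges}, a BED path, or NULL (no-op).
#'   Interval arithmetic is 0-based half-open: a site at position p is
#'   removed when p lies in \[start, end).
#' @return the subset of \code{sites} outside every interval.
#' @export
blacklist_filter <- function(sites, blacklist) {
  if (is.null(blacklist)) return(sites)
  if (is.character(blacklist)) blacklist <- read_bed(blacklist)
  if (length(blacklist) == 0L || nrow(sites) == 0L) return(sites)
  pr <- GenomicRanges::GRanges(sites$contig,
                               IRanges::IRanges(sites$pos + 1L, width = 1L))
  hit <- GenomicRanges::countOverlaps(
    pr, GenomicRanges::granges(blacklist), ignore.strand = TRUE) > 0L
  sites[!hit, , drop = FALSE]
}

#' Run the full staged filter cascade
#'
#' Applies, in order: candidate nomination, the multi-editing per-sample
#' exclusion, the cross-sample consistency filter, the per-tissue cutoff
#' profile (minimum supporting samples), and the hypervariable-region
#' blacklist.  The same stages are applied in parallel to candidates of
#' all 12 mismatch classes to trace the A-to-G enrichment per stage — the
#' diagnostic used to tune profile cutoffs.
#'
#' @param bcm a \code{\link{base_count_matrix}}.
#' @param profile a \code{\link{filter_profile}} or builtin tissue name.
#' @param blacklist optional blacklist (GRanges or BED path).
#' @return an object of class \code{filter_report}: list with
#'   \code{stages} (per-stage A-to-G in/out counts and enrichment),
#'   \code{sites} (final A-to-G site table with \code{mean_editing} over
#'   supporting samples and \code{n_supporting}), \code{exclusions}
#'   (per-sample exclusion matrix for surviving sites), and the profile.
#' @examples
#' sim <- simulate_cohort(sim_config(reference_length = 4000, n_genes = 4,
#'                                   n_edit_sites = 8, n_samples = 20,
#'                                   rate_range = c(0.3, 0.8), seed = 3))
#' prof <- filter_profile("demo", 0.05, 2, 5, 15)
#' run_cascade(sim$counts, prof)
#' @export
run_cascade <- function(bcm, profile, blacklist = NULL) {
  stopifnot(inherits(bcm, "base_count_matrix"))
  if (is.character(profile)) profile <- builtin_profiles(profile)
  stopifnot(inherits(profile, "filter_profile"))

  cand <- nominate_candidates(bcm, classes = "all")
  is_ag <- cand$ref == "A" & cand$alt == "G"
  cc <- candidate_counts(bcm, cand)

  stages <- data.frame(stage = character(), sites_in = integer(),
                       sites_out = integer(), ag_enrichment = numeric(),
                       stringsAsFactors = FALSE)
  note <- function(stage, keep_before, keep_after) {
    n_in <- sum(keep_before & is_ag)
    n_out <- sum(keep_after & is_ag)
    enr <- if (sum(keep_after) > 0L) sum(keep_after & is_ag) / sum(keep_after)
           else NA_real_
    stages <<- rbind(stages, data.frame(
      stage = stage, sites_in = n_in, sites_out = n_out,
      ag_enrichment = enr, stringsAsFactors = FALSE))
  }
  alive <- rep(TRUE, nrow(cand))
  note("nomination", alive, alive)

  # stage 1: multi-editing per-sample exclusions (drops samples, not sites)
  excl <- multi_editing_exclusions(cc, profile)
  note("multi_editing", alive, alive)

  # stage 2: cross-sample consistency
  keep2 <- consistency_keep(bcm, cand, cc, profile)
  note("consistency", alive, alive & keep2)
  alive <- alive & keep2

  # stage 3: per-tissue cutoffs (support predicate + minimum samples)
  supp <- sample_supports(cc, profile) & !excl
  n_supporting <- rowSums(supp)
  keep3 <- n_supporting >= profile$min_supporting_samples
  note("profile_cutoffs", alive, alive & keep3)
  alive <- alive & keep3

  # stage 4: blacklist
  surv <- cand[alive, , drop = FALSE]
  after_bl <- blacklist_filter(surv, blacklist)
  keep4 <- alive
  keep4[alive] <- rownames(surv) %in% rownames(after_bl)
  note("blacklist", alive, keep4)
  alive <- keep4

  # final A-to-G site table
  fin <- which(alive & is_ag)
  mean_editing <- vapply(fin, function(i) {
    s <- supp[i, ]
    if (!any(s)) return(NA_real_)
    mean(cc$index[i, s])
  }, numeric(1))
  sites <- data.frame(
    contig = cand$contig[fin], pos = cand$pos[fin],
    strand = cand$strand[fin], ref = cand$ref[fin], alt = cand$alt[fin],
    mean_editing = mean_editing, n_supporting = n_supporting[fin],
    stringsAsFactors = FALSE)
  rownames(sites) <- NULL
  sites$idx <- cand$idx[fin]

  structure(list(stages = stages, sites = sites,
                 exclusions = excl[fin, , drop = FALSE],
                 samples = bcm$samples, profile = profile),
            class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("Filter cascade report (profile '%s')\n", x$profile$tissue))
  st <- x$stages
  st$ag_enrichment <- round(st$ag_enrichment, 3)
  print(st, row.names = FALSE)
  cat(sprintf("Final A-to-G sites: %d\n", nrow(x$sites)))
  invisible(x)
}

#' A-to-G enrichment of surviving candidates
#'
#' Fraction of candidates surviving the cascade whose mismatch class is
#' A-to-G, out of surviving candidates of all 12 classes; \code{NA} when
#' nothing survives.  Per-stage values are in \code{report$stages}.
#'
#' @param report a \code{\link{run_cascade}} report.
#' @param stage stage name (default: last stage).
#' @return a fraction, or NA.
#' @export
ag_enrichment <- function(report, stage = NULL) {
  stopifnot(inherits(report, "filter_report"))
  st <- report$stages
  if (is.null(stage)) return(st$ag_enrichment[nrow(st)])
  row <- match(stage, st$stage)
  if (is.na(row)) stop(sprintf("unknown stage '%s'", stage), call. = FALSE)
  st$ag_enrichment[row]
}

#' Export final sites in a VCF-like format
#'
#' One record per surviving A-to-G site with INFO fields
#' \code{MEAN_EDITING} and \code{N_SUPPORTING}.  REF/ALT are reported on
#' the transcribed strand (so always A/G); the STRAND info field gives
#' the gene orientation.
#'
#' @param report a \code{\link{run_cascade}} report.
#' @param path output file.
#' @export
write_site_vcf <- function(report, path) {
  s <- report$sites
  lines <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=MEAN_EDITING,Number=1,Type=Float,Description=\"Mean editing index over supporting samples\">",
    "##INFO=<ID=N_SUPPORTING,Number=1,Type=Integer,Description=\"Number of supporting samples\">",
    "##INFO=<ID=STRAND,Number=1,Type=String,Description=\"Transcribed strand\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\tMEAN_EDITING=%.6g;N_SUPPORTING=%d;STRAND=%s",
            s$contig, s$pos + 1L, s$ref, s$alt,
            s$mean_editing, s$n_supporting, s$strand))
  writeLines(lines, path)
  invisible(path)
}

#' Export a cascade report as JSON
#'
#' @param report a \code{\link{run_cascade}} report.
#' @param path output file.
#' @export
write_filter_report <- function(report, path) {
  jsonlite::write_json(
    list(profile = unclass(report$profile),
         stages = report$stages,
         n_final_sites = nrow(report$sites),
         sites = report$sites[setdiff(names(report$sites), "idx")]),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Export final sites as TSV (1-based positions)
#'
#' @param report a \code{\link{run_cascade}} report.
#' @param path output TSV.
#' @export
write_site_table <- function(report, path) {
  s <- report$sites
  out <- data.frame(contig = s$contig, pos_1based = s$pos + 1L,
                    strand = s$strand, ref = s$ref, alt = s$alt,
                    mean_editing = s$mean_editing,
                    n_supporting = s$n_supporting)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
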