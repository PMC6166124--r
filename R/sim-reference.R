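#' Simulate a reference contig with gene annotation
#'
#' Draws a uniform-random A/C/G/T sequence and places non-overlapping gene
#' intervals on it.  Exactly \code{round(minus_strand_fraction * n_genes)}
#' genes sit on the '-' strand (which genes is random under the seed).
#'
#' Genes are laid out by splitting the contig into equal slots, one gene per
#' slot, each occupying a random ~80% sub-interval of its slot; this
#' guarantees disjointness by construction (and the test suite re-verifies
#' it with an interval sweep).
#'
#' @param config a \code{\link{sim_config}}.
#' @return a list with \code{reference} (a named character vector of length
#'   one, contig "chr1") and \code{genes} (a \code{GRanges} with strand and
#'   \code{gene_id}).
#' @examples
#' ref <- simulate_reference(sim_config(reference_length = 5000, n_genes = 4))
#' ref$genes
#' @export
simulate_reference <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  L <- config$reference_length
  n <- config$n_genes
  if (n > 0L && L < n * 50L) {
    stop(sprintf(
      "reference_length %d too small to host %d genes (need >= %d)",
      L, n, n * 50L), call. = FALSE)
  }
  set.seed(derive_seed(config$seed, 0L))
  seq_chars <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
  reference <- c(chr1 = paste(seq_chars, collapse = ""))

  if (n == 0L) {
    genes <- GenomicRanges::GRanges()
  } else {
    slot <- L %/% n
    width <- max(1L, as.integer(0.8 * slot))
    offset <- if (slot - width > 0) {
      sample.int(slot - width, n, replace = TRUE)
    } else rep(1L, n)
    start <- (seq_len(n) - 1L) * slot + offset
    n_minus <- round(config$minus_strand_fraction * n)
    strand <- rep("+", n)
    if (n_minus > 0) strand[sample.int(n, n_minus)] <- "-"
    genes <- GenomicRanges::GRanges(
      seqnames = "chr1",
      ranges = IRanges::IRanges(start = start, width = width),
      strand = strand,
      gene_id = sprintf("gene%02d", seq_len(n))
    )
  }
  list(reference = reference, genes = genes)
}

# 0-based positions covered by genes, with the owning gene's strand.
# Positions claimed by two genes on opposite strands are dropped.
genic_positions <- function(genes) {
  if (length(genes) == 0L) {
    return(data.frame(pos = integer(), strand = character()))
  }
  pos <- unlist(lapply(seq_along(genes), function(i) {
    seq(GenomicRanges::start(genes)[i], GenomicRanges::end(genes)[i])
  }))
  strand <- rep(as.character(GenomicRanges::strand(genes)),
                GenomicRanges::width(genes))
  ord <- order(pos)
  pos <- pos[ord]; strand <- strand[ord]
  dup <- pos %in% pos[duplicated(pos)]
  if (any(dup)) {
    # resolve duplicates: keep when all owners agree on strand
    keep <- !dup
    for (p in unique(pos[dup])) {
      s <- unique(strand[pos == p])
      if (length(s) == 1L) keep[which(pos == p)[1L]] <- TRUE
    }
    pos <- pos[keep]; strand <- strand[keep]
  }
  data.frame(pos = pos - 1L, strand = strand, stringsAsFactors = FALSE)
}

ref_base_at <- function(reference, pos0) {
  substring(reference[[1L]], pos0 + 1L, pos0 + 1L)
}

#' Plant ground-truth editing sites and confounders
#'
#' Chooses \code{n_edit_sites} positions inside genes whose base on the
#' transcribed strand is A (i.e. plus-strand A in '+' genes, plus-strand T
#' in '-' genes) and assigns each a true editing rate per cohort group.
#' Optional confounders emulate the failure modes the filter cascade must
#' reject: SNP-like positions (a fixed half of samples look homozygous G),
#' multi-mismatch positions (A-to-C at an editing-like rate) and
#' hypervariable intervals (elevated mismatches of all classes).
#'
#' @param reference,genes output of \code{\link{simulate_reference}}.
#' @param config a \code{\link{sim_config}}.
#' @param rate_ranges named list of length-2 rate ranges, one per cohort
#'   group.  When omitted, one rate per site is drawn from
#'   \code{config$rate_range} and shared by \code{healthy} and
#'   \code{diseased} (a null design with respect to group).  A degenerate
#'   range pins the rate exactly.
#' @return an object of class \code{sim_truth}: list with \code{sites}
#'   (data.frame: contig, pos (0-based), strand, and one \code{rate_<group>}
#'   column per group), \code{confounders} (data.frame: pos, kind, start,
#'   end), \code{error_rate} and \code{seed}.
#' @export
plant_truth <- function(reference, genes, config,
                        rate_ranges = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (length(genes) == 0L) stop("annotation is empty", call. = FALSE)
  shared_rates <- is.null(rate_ranges)
  if (shared_rates) {
    # no per-group ranges: both cohorts share one true rate per site (null
    # design with respect to group)
    rate_ranges <- list(healthy = config$rate_range,
                        diseased = config$rate_range)
  }
  set.seed(derive_seed(config$seed, 1L))
  gp <- genic_positions(genes)
  base_plus <- substring(reference[[1L]], gp$pos + 1L, gp$pos + 1L)
  # transcribed-strand base is A <=> plus-strand A on '+', T on '-'
  is_a <- (gp$strand == "+" & base_plus == "A") |
          (gp$strand == "-" & base_plus == "T")
  a_pos <- gp[is_a, , drop = FALSE]

  n_conf_sites <- config$n_snp_like + config$n_multi_mismatch
  need <- config$n_edit_sites + n_conf_sites
  if (nrow(a_pos) < need) {
    stop(sprintf(
      "only %d transcribed-strand A positions available, need %d",
      nrow(a_pos), need), call. = FALSE)
  }
  pick <- if (need > 0L) a_pos[sample.int(nrow(a_pos), need), , drop = FALSE]
          else a_pos[0, , drop = FALSE]

  sites <- pick[seq_len(config$n_edit_sites), , drop = FALSE]
  sites <- data.frame(contig = rep("chr1", nrow(sites)), pos = sites$pos,
                      strand = sites$strand, stringsAsFactors = FALSE)
  if (shared_rates) {
    rr <- config$rate_range
    shared <- if (nrow(sites)) stats::runif(nrow(sites), rr[1], rr[2])
              else numeric()
    for (g in names(rate_ranges)) sites[[paste0("rate_", g)]] <- shared
  } else {
    for (g in names(rate_ranges)) {
      rr <- rate_ranges[[g]]
      sites[[paste0("rate_", g)]] <- if (nrow(sites)) {
        stats::runif(nrow(sites), rr[1], rr[2])
      } else numeric()
    }
  }
  sites <- sites[order(sites$pos), , drop = FALSE]
  rownames(sites) <- NULL

  conf <- data.frame(pos = integer(), kind = character(),
                     start = integer(), end = integer(),
                     stringsAsFactors = FALSE)
  if (n_conf_sites > 0L) {
    cpick <- pick[config$n_edit_sites + seq_len(n_conf_sites), , drop = FALSE]
    kind <- c(rep("snp_like", config$n_snp_like),
              rep("multi_mismatch", config$n_multi_mismatch))
    conf <- data.frame(pos = cpick$pos, kind = kind,
                       start = NA_integer_, end = NA_integer_,
                       stringsAsFactors = FALSE)
  }
  if (config$n_hypervariable > 0L) {
    w <- config$hypervariable_width
    gsel <- sample(seq_along(genes), config$n_hypervariable, replace = TRUE)
    hstart <- vapply(gsel, function(i) {
      s <- GenomicRanges::start(genes)[i] - 1L
      e <- GenomicRanges::end(genes)[i] - w
      if (e <= s) s else s + sample.int(e - s, 1L)
    }, integer(1))
    conf <- rbind(conf, data.frame(
      pos = NA_integer_, kind = "hypervariable_region",
      start = hstart, end = hstart + w, stringsAsFactors = FALSE))
  }
  structure(list(sites = sites, confounders = conf,
                 error_rate = config$error_rate, seed = config$seed,
                 groups = names(rate_ranges)),
            class = "sim_truth")
}

#' @export
print.sim_truth <- function(x, ...) {
  cat(sprintf("Planted truth: %d editing sites, %d confounders (seed %d)\n",
              nrow(x$sites), nrow(x$confounders), x$seed))
  invisible(x)
}
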