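#' Tally strand-aware per-site base counts from alignments
#'
#' Runs a pileup over each sample's alignments, restricted to annotated
#' genes, and expresses the per-position A/C/G/T counts on the transcribed
#' strand: counts at positions inside '-' genes are complemented, so that
#' an A-to-G editing event always appears as a G count at an A reference
#' base regardless of gene orientation.  Positions claimed by two genes on
#' opposite strands are skipped.  Only primary mapped alignments are
#' counted and N bases are ignored (standard pileup hygiene).
#'
#' @param alignment_files character vector of SAM or BAM paths, one per
#'   sample, named by sample id (unnamed: file base names are used).
#' @param reference path to the reference FASTA, or a named character
#'   vector of sequences as produced by \code{\link{simulate_reference}}.
#' @param genes gene annotation: a \code{GRanges} with strand, or a BED
#'   file path.
#' @param min_mapq minimum mapping quality (default 20).
#' @param min_base_quality minimum base quality (default 20).
#' @return a \code{\link{base_count_matrix}} over every covered genic
#'   position.
#' @export
tally_base_counts <- function(alignment_files, reference, genes,
                              min_mapq = 20L, min_base_quality = 20L) {
  if (is.null(names(alignment_files)) || any(names(alignment_files) == "")) {
    names(alignment_files) <- sub("\\.(sam|bam)$", "",
                                  basename(alignment_files))
  }
  if (is.character(reference) && length(reference) == 1L &&
      file.exists(reference)) {
    rs <- Biostrings::readDNAStringSet(reference)
    names(rs) <- sub("\\s.*", "", names(rs))
    reference <- stats::setNames(as.character(rs), names(rs))
  }
  if (is.character(genes)) genes <- read_bed(genes, keep_strand = TRUE)
  stopifnot(methods::is(genes, "GRanges"))

  samples <- names(alignment_files)
  per_sample <- lapply(alignment_files, function(f) {
    pileup_one(f, genes, min_mapq, min_base_quality)
  })

  # union of covered positions (per contig), ordered
  all_pos <- unique(do.call(rbind, lapply(per_sample, function(p) {
    p[c("contig", "pos")]
  })))
  if (is.null(all_pos) || nrow(all_pos) == 0L) {
    sites <- data.frame(contig = character(), pos = integer(),
                        strand = character(), ref = character(),
                        stringsAsFactors = FALSE)
    empty <- matrix(0L, 0L, length(samples))
    return(base_count_matrix(
      sites, list(A = empty, C = empty, G = empty, T = empty), samples))
  }
  all_pos <- all_pos[order(all_pos$contig, all_pos$pos), , drop = FALSE]

  # gene ownership and strand per position; opposite-strand ties skipped
  pr <- GenomicRanges::GRanges(all_pos$contig,
                               IRanges::IRanges(all_pos$pos + 1L, width = 1L))
  hits <- GenomicRanges::findOverlaps(pr, genes)
  strands <- tapply(
    as.character(GenomicRanges::strand(genes))[S4Vectors::subjectHits(hits)],
    S4Vectors::queryHits(hits),
    function(s) if (length(unique(s)) == 1L) s[1L] else NA_character_)
  pos_strand <- rep(NA_character_, nrow(all_pos))
  pos_strand[as.integer(names(strands))] <- unlist(strands)
  keep <- !is.na(pos_strand)
  if (any(!keep)) {
    message(sprintf("skipped %d position(s) outside genes or with ambiguous strand",
                    sum(!keep)))
  }
  all_pos <- all_pos[keep, , drop = FALSE]
  pos_strand <- pos_strand[keep]

  missing_contigs <- setdiff(unique(all_pos$contig), names(reference))
  if (length(missing_contigs)) {
    stop(sprintf("contig(s) not in reference: %s",
                 paste(missing_contigs, collapse = ", ")), call. = FALSE)
  }
  base_plus <- substring(reference[all_pos$contig], all_pos$pos + 1L,
                         all_pos$pos + 1L)
  ref_tx <- ifelse(pos_strand == "-", comp_base(base_plus), base_plus)

  key <- paste(all_pos$contig, all_pos$pos)
  n <- nrow(all_pos)
  counts <- lapply(c(A = "A", C = "C", G = "G", T = "T"),
                   function(b) matrix(0L, n, length(samples)))
  for (j in seq_along(samples)) {
    p <- per_sample[[j]]
    if (nrow(p) == 0L) next
    row <- match(paste(p$contig, p$pos), key)
    ok <- !is.na(row)
    p <- p[ok, , drop = FALSE]; row <- row[ok]
    # complement counts onto the transcribed strand for '-' positions
    minus <- pos_strand[row] == "-"
    eff <- ifelse(minus, comp_base(p$nucleotide), p$nucleotide)
    for (b in c("A", "C", "G", "T")) {
      sel <- eff == b
      if (any(sel)) {
        counts[[b]][cbind(row[sel], j)] <-
          counts[[b]][cbind(row[sel], j)] + p$count[sel]
      }
    }
  }
  sites <- data.frame(contig = all_pos$contig, pos = all_pos$pos,
                      strand = pos_strand, ref = ref_tx,
                      stringsAsFactors = FALSE)
  base_count_matrix(sites, counts, samples)
}

# pileup one SAM/BAM, returning plus-strand nucleotide counts per position
pileup_one <- function(file, genes, min_mapq, min_base_quality) {
  bam <- file
  if (grepl("\\.sam$", file)) {
    bam <- Rsamtools::asBam(file,
                            destination = tempfile(fileext = ""),
                            overwrite = TRUE, indexDestination = TRUE)
  } else if (!file.exists(paste0(bam, ".bai"))) {
    Rsamtools::indexBam(bam)
  }
  which <- GenomicRanges::reduce(GenomicRanges::granges(genes),
                                 ignore.strand = TRUE)
  sbp <- Rsamtools::ScanBamParam(
    which = which,
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = FALSE,
                                  isNotPassingQualityControls = FALSE,
                                  isDuplicate = FALSE))
  pp <- Rsamtools::PileupParam(
    max_depth = 1000000L,
    min_base_quality = as.integer(min_base_quality),
    min_mapq = as.integer(min_mapq),
    min_nucleotide_depth = 1L,
    distinguish_strands = FALSE,
    distinguish_nucleotides = TRUE,
    include_deletions = FALSE,
    include_insertions = FALSE)
  p <- Rsamtools::pileup(bam, scanBamParam = sbp, pileupParam = pp)
  if (nrow(p) == 0L) {
    return(data.frame(contig = character(), pos = integer(),
                      nucleotide = character(), count = integer(),
                      stringsAsFactors = FALSE))
  }
  p <- p[as.character(p$nucleotide) %in% c("A", "C", "G", "T"), , drop = FALSE]
  # overlapping 'which' ranges can duplicate rows; aggregate defensively
  df <- stats::aggregate(count ~ seqnames + pos + nucleotide, data = p, sum)
  data.frame(contig = as.character(df$seqnames), pos = df$pos - 1L,
             nucleotide = as.character(df$nucleotide),
             count = as.integer(df$count), stringsAsFactors = FALSE)
}

#' Read a BED file into a GRanges
#'
#' Minimal validating BED reader (3-6 columns, 0-based half-open).  Raises
#' an error naming the first malformed line.
#'
#' @param path BED file path.
#' @param keep_strand read the 6th column as strand when present.
#' @return a \code{GRanges}.
#' @export
read_bed <- function(path, keep_strand = TRUE) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") &
                 !startsWith(lines, "track") & !startsWith(lines, "browser")]
  if (!length(lines)) return(GenomicRanges::GRanges())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    if (length(f) < 3L ||
        is.na(suppressWarnings(as.integer(f[2]))) ||
        is.na(suppressWarnings(as.integer(f[3]))) ||
        as.integer(f[2]) > as.integer(f[3])) {
      stop(sprintf("malformed BED line %d in '%s'", i, path), call. = FALSE)
    }
  }
  chrom <- vapply(fields, `[`, character(1), 1L)
  start <- as.integer(vapply(fields, `[`, character(1), 2L))
  end <- as.integer(vapply(fields, `[`, character(1), 3L))
  strand <- rep("*", length(fields))
  if (keep_strand) {
    s6 <- vapply(fields, function(f) if (length(f) >= 6L) f[6] else "*",
                 character(1))
    strand <- ifelse(s6 %in% c("+", "-"), s6, "*")
  }
  gr <- GenomicRanges::GRanges(chrom,
                               IRanges::IRanges(start + 1L, end),
                               strand = strand)
  nm <- vapply(fields, function(f) if (length(f) >= 4L) f[4] else NA_character_,
               character(1))
  if (!all(is.na(nm))) gr$name <- nm
  gr
}
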