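# Independent brute-force pileup: parse SAM text directly and count read
# bases position by position, then express counts on the transcribed
# strand per the gene annotation.  Shares no code with the package tally.
brute_force_tally <- function(sam_path, reference, genes) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  lines <- readLines(sam_path)
  lines <- lines[!startsWith(lines, "@")]
  counts <- list() # key: pos0 -> named count vector (plus strand)
  for (ln in lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    start <- as.integer(f[4])
    seq <- strsplit(f[10], "")[[1]]
    for (k in seq_along(seq)) {
      b <- seq[k]
      if (!b %in% c("A", "C", "G", "T")) next
      key <- as.character(start + k - 2L) # 0-based position
      if (is.null(counts[[key]])) {
        counts[[key]] <- c(A = 0L, C = 0L, G = 0L, T = 0L)
      }
      counts[[key]][b] <- counts[[key]][b] + 1L
    }
  }
  pos0 <- sort(as.integer(names(counts)))
  gstart <- GenomicRanges::start(genes) - 1L
  gend <- GenomicRanges::end(genes)
  gstrand <- as.character(GenomicRanges::strand(genes))
  rows <- list()
  for (p in pos0) {
    owners <- which(gstart <= p & p < gend)
    if (length(owners) == 0L) next
    s <- unique(gstrand[owners])
    if (length(s) > 1L) next # opposite-strand tie: skipped
    cnt <- counts[[as.character(p)]]
    base <- substring(reference[[1]], p + 1L, p + 1L)
    if (s == "-") {
      cnt <- c(A = cnt[["T"]], C = cnt[["G"]], G = cnt[["C"]], T = cnt[["A"]])
      base <- unname(comp[base])
    }
    rows[[length(rows) + 1L]] <- data.frame(
      pos = p, strand = s, ref = base,
      A = cnt[["A"]], C = cnt[["C"]], G = cnt[["G"]], T = cnt[["T"]],
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

# Small hand-rolled SAM writer for fixture reads: list of (pos1, seq)
write_test_sam <- function(path, ref_len, reads) {
  lines <- c("@HD\tVN:1.6\tSO:coordinate",
             sprintf("@SQ\tSN:chr1\tLN:%d", ref_len))
  reads <- reads[order(vapply(reads, `[[`, numeric(1), "pos"))]
  for (i in seq_along(reads)) {
    r <- reads[[i]]
    lines <- c(lines, sprintf(
      "r%03d\t0\tchr1\t%d\t60\t%dM\t*\t0\t0\t%s\t%s",
      i, r$pos, nchar(r$seq), r$seq, strrep("I", nchar(r$seq))))
  }
  writeLines(lines, path)
  path
}

# fabricate a base_count_matrix from per-site count specs:
# sites: data.frame(pos, strand, ref); counts: list of 4 matrices
make_bcm <- function(ref_bases, A, C, G, T, strand = NULL) {
  n <- length(ref_bases)
  if (is.null(strand)) strand <- rep("+", n)
  as_mat <- function(x) {
    m <- if (is.matrix(x)) x else matrix(x, nrow = n)
    storage.mode(m) <- "integer"
    m
  }
  A <- as_mat(A); C <- as_mat(C); G <- as_mat(G); T <- as_mat(T)
  sites <- data.frame(contig = "chr1", pos = seq_len(n) * 10L,
                      strand = strand, ref = ref_bases,
                      stringsAsFactors = FALSE)
  base_count_matrix(sites, list(A = A, C = C, G = G, T = T),
                    sprintf("S%02d", seq_len(ncol(A))))
}
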