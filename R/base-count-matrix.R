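#' Per-site, per-sample base-count matrix
#'
#' The substrate of the whole cascade: for every covered position inside an
#' annotated gene, the counts of A/C/G/T read bases expressed on the
#' transcribed strand (i.e. complemented for '-' genes), per sample.
#'
#' @param sites data.frame with columns \code{contig}, \code{pos} (0-based),
#'   \code{strand}, \code{ref} (reference base on the transcribed strand).
#' @param counts named list of four integer matrices \code{A,C,G,T}, each
#'   sites x samples.
#' @param samples character vector of sample ids (column names).
#' @return an object of class \code{base_count_matrix}.
#' @export
base_count_matrix <- function(sites, counts, samples) {
  stopifnot(is.data.frame(sites),
            all(c("contig", "pos", "strand", "ref") %in% names(sites)),
            all(c("A", "C", "G", "T") %in% names(counts)))
  ns <- nrow(sites)
  for (b in c("A", "C", "G", "T")) {
    m <- counts[[b]]
    stopifnot(is.matrix(m), nrow(m) == ns, ncol(m) == length(samples))
    if (any(m < 0)) stop("negative counts", call. = FALSE)
    colnames(counts[[b]]) <- samples
  }
  if (anyDuplicated(paste(sites$contig, sites$pos))) {
    stop("duplicate site positions per contig", call. = FALSE)
  }
  if (!all(sites$ref %in% c("A", "C", "G", "T"))) {
    stop("ref_base must be one of A,C,G,T", call. = FALSE)
  }
  structure(list(sites = sites, counts = counts,
                 samples = as.character(samples)),
            class = "base_count_matrix")
}

#' @export
print.base_count_matrix <- function(x, ...) {
  cat(sprintf("Base-count matrix: %d sites x %d samples\n",
              nrow(x$sites), length(x$samples)))
  invisible(x)
}

#' @export
dim.base_count_matrix <- function(x) c(nrow(x$sites), length(x$samples))

#' Total read coverage per site and sample
#'
#' @param x a \code{base_count_matrix}.
#' @return integer matrix of A+C+G+T counts.
#' @export
coverage_matrix <- function(x) {
  stopifnot(inherits(x, "base_count_matrix"))
  x$counts$A + x$counts$C + x$counts$G + x$counts$T
}

# restrict to a subset of site rows
subset_sites <- function(x, idx) {
  base_count_matrix(
    sites = x$sites[idx, , drop = FALSE],
    counts = lapply(x$counts, function(m) m[idx, , drop = FALSE]),
    samples = x$samples
  )
}

#' Write a base-count matrix to TSV
#'
#' One row per site; per-sample columns hold "A:C:G:T" strings.  Positions
#' are exported 1-based (column \code{pos_1based}); the internal
#' representation is 0-based half-open.
#'
#' @param x a \code{base_count_matrix}.
#' @param path output file.
#' @export
write_base_counts <- function(x, path) {
  stopifnot(inherits(x, "base_count_matrix"))
  cells <- matrix(sprintf("%d:%d:%d:%d", x$counts$A, x$counts$C,
                          x$counts$G, x$counts$T),
                  nrow = nrow(x$sites))
  colnames(cells) <- x$samples
  out <- cbind(data.frame(contig = x$sites$contig,
                          pos_1based = x$sites$pos + 1L,
                          strand = x$sites$strand,
                          ref = x$sites$ref,
                          stringsAsFactors = FALSE),
               as.data.frame(cells, stringsAsFactors = FALSE))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a base-count matrix written by \code{\link{write_base_counts}}
#'
#' @param path TSV file.
#' @return a \code{base_count_matrix}.
#' @export
read_base_counts <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  meta <- c("contig", "pos_1based", "strand", "ref")
  samples <- setdiff(names(df), meta)
  parse_col <- function(s) {
    m <- do.call(rbind, strsplit(s, ":", fixed = TRUE))
    storage.mode(m) <- "integer"
    m
  }
  parsed <- lapply(df[samples], parse_col)
  counts <- lapply(1:4, function(k) {
    m <- vapply(parsed, function(p) p[, k], integer(nrow(df)))
    matrix(m, nrow = nrow(df), dimnames = list(NULL, samples))
  })
  names(counts) <- c("A", "C", "G", "T")
  sites <- data.frame(contig = df$contig, pos = df$pos_1based - 1L,
                      strand = df$strand, ref = df$ref,
                      stringsAsFactors = FALSE)
  base_count_matrix(sites, counts, samples)
}
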