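#' Nominate candidate editing sites
#'
#' Nomination is deliberately minimal: every site whose reference base on
#' the transcribed strand is A and that shows at least one G read in at
#' least one sample becomes an A-to-G candidate.  All stringency lives in
#' the downstream filter cascade.  With \code{classes = "all"} every
#' ref-to-alt mismatch class with at least one supporting read is
#' nominated instead; this mode exists only to power the A-to-G
#' enrichment diagnostic.
#'
#' @param bcm a \code{\link{base_count_matrix}}.
#' @param classes \code{"AG"} (default) or \code{"all"} (all 12 mismatch
#'   classes, diagnostic).
#' @return data.frame of candidates with columns \code{idx} (row in
#'   \code{bcm}), \code{contig}, \code{pos}, \code{strand}, \code{ref},
#'   \code{alt}.
#' @export
nominate_candidates <- function(bcm, classes = c("AG", "all")) {
  stopifnot(inherits(bcm, "base_count_matrix"))
  classes <- match.arg(classes)
  if (nrow(bcm$sites) == 0L) stop("base-count matrix is empty", call. = FALSE)
  bases <- c("A", "C", "G", "T")
  out <- list()
  pairs <- if (classes == "AG") {
    list(c("A", "G"))
  } else {
    do.call(c, lapply(bases, function(r) {
      lapply(setdiff(bases, r), function(a) c(r, a))
    }))
  }
  for (pr in pairs) {
    r <- pr[1]; a <- pr[2]
    idx <- which(bcm$sites$ref == r & rowSums(bcm$counts[[a]]) > 0L)
    if (length(idx)) {
      out[[length(out) + 1L]] <- data.frame(
        idx = idx,
        contig = bcm$sites$contig[idx],
        pos = bcm$sites$pos[idx],
        strand = bcm$sites$strand[idx],
        ref = r, alt = a, stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(idx = integer(), contig = character(),
                      pos = integer(), strand = character(),
                      ref = character(), alt = character(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$contig, res$pos, res$alt), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# per-candidate x sample matrices used throughout the filters:
# ref count, alt count, coverage, editing index alt/(ref+alt)
candidate_counts <- function(bcm, cand) {
  refc <- altc <- matrix(0L, nrow(cand), length(bcm$samples))
  for (b in c("A", "C", "G", "T")) {
    rows <- which(cand$ref == b)
    if (length(rows)) refc[rows, ] <- bcm$counts[[b]][cand$idx[rows], , drop = FALSE]
    rows <- which(cand$alt == b)
    if (length(rows)) altc[rows, ] <- bcm$counts[[b]][cand$idx[rows], , drop = FALSE]
  }
  cov <- coverage_matrix(bcm)[cand$idx, , drop = FALSE]
  idxm <- altc / (refc + altc)
  idxm[refc + altc == 0L] <- NA_real_
  list(ref = refc, alt = altc, coverage = cov, index = idxm)
}
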