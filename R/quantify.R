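#' Editing index
#'
#' The editing level at an A-to-G site: G / (A + G) on the transcribed
#' strand.  C/T reads at the site are treated as noise, not as unedited
#' (the standard editing-index convention); pass the site's total coverage
#' as \code{a_count + g_count} callers wanting a total-coverage
#' denominator.  Undefined (NA) when A + G = 0.
#'
#' @param a_count,g_count non-negative read counts (vectorised).
#' @return fraction in \[0, 1\], or NA where A + G = 0.
#' @examples
#' editing_index(7, 3) # 0.3
#' @export
editing_index <- function(a_count, g_count) {
  if (any(a_count < 0) || any(g_count < 0)) {
    stop("counts must be non-negative", call. = FALSE)
  }
  tot <- a_count + g_count
  out <- g_count / tot
  out[tot == 0] <- NA_real_
  out
}

#' Construct an editing matrix from precomputed editing levels
#'
#' Low-level constructor for workflows that start from per-sample editing
#' levels rather than base counts (e.g. published per-site tables, or the
#' per-site cohort simulator \code{\link{simulate_editing_levels}}).
#'
#' @param E numeric matrix of editing fractions (sites x samples), NA for
#'   invalid cells.
#' @param sites optional site data.frame (defaults to anonymous sites).
#' @param samples optional data.frame with \code{sample}, \code{tissue},
#'   \code{group} columns (defaults taken from \code{colnames(E)}).
#' @return an \code{editing_matrix}.
#' @export
editing_matrix <- function(E, sites = NULL, samples = NULL) {
  E <- as.matrix(E)
  if (any(E < 0 | E > 1, na.rm = TRUE)) {
    stop("editing levels must be fractions in [0, 1]", call. = FALSE)
  }
  if (is.null(sites)) {
    sites <- data.frame(contig = "site", pos = seq_len(nrow(E)) - 1L,
                        strand = "+", ref = "A", stringsAsFactors = FALSE)
  }
  if (is.null(samples)) {
    ids <- colnames(E)
    if (is.null(ids)) ids <- sprintf("S%03d", seq_len(ncol(E)))
    samples <- data.frame(sample = ids, tissue = NA_character_,
                          group = NA_character_, stringsAsFactors = FALSE)
  }
  stopifnot(nrow(sites) == nrow(E), nrow(samples) == ncol(E))
  colnames(E) <- samples$sample
  structure(list(E = E, sites = sites, samples = samples),
            class = "editing_matrix")
}

#' Assemble a sites x samples editing matrix
#'
#' Computes the editing index per cell for a chosen site set, masking
#' cells where A + G = 0 or where the sample was excluded at the site by
#' the multi-editing filter.  Per-site means are taken over valid cells
#' only.
#'
#' @param bcm a \code{\link{base_count_matrix}}.
#' @param sites site selection: a \code{\link{run_cascade}} report, a
#'   data.frame with an \code{idx} column (rows of \code{bcm}), or an
#'   integer vector of row indices.
#' @param exclusions optional logical matrix (sites x samples), TRUE =
#'   masked; a \code{filter_report} supplies its own.
#' @param sample_info optional data.frame with columns \code{sample},
#'   \code{tissue}, \code{group} (e.g. a cohort design); matched to
#'   \code{bcm} columns by sample id.
#' @return an object of class \code{editing_matrix}: list with \code{E}
#'   (numeric matrix, NA at masked cells), \code{sites}, \code{samples}
#'   (data.frame of metadata).
#' @export
build_editing_matrix <- function(bcm, sites, exclusions = NULL,
                                 sample_info = NULL) {
  stopifnot(inherits(bcm, "base_count_matrix"))
  if (inherits(sites, "filter_report")) {
    if (is.null(exclusions)) exclusions <- sites$exclusions
    sites <- sites$sites
  }
  idx <- if (is.data.frame(sites)) sites$idx else as.integer(sites)
  site_df <- bcm$sites[idx, , drop = FALSE]
  rownames(site_df) <- NULL

  a <- bcm$counts$A[idx, , drop = FALSE]
  g <- bcm$counts$G[idx, , drop = FALSE]
  E <- g / (a + g)
  E[(a + g) == 0L] <- NA_real_
  if (!is.null(exclusions)) {
    stopifnot(all(dim(exclusions) == dim(E)))
    E[exclusions] <- NA_real_
  }
  dimnames(E) <- list(NULL, bcm$samples)

  samples <- data.frame(sample = bcm$samples, tissue = NA_character_,
                        group = NA_character_, stringsAsFactors = FALSE)
  if (!is.null(sample_info)) {
    m <- match(bcm$samples, sample_info$sample)
    if (anyNA(m)) {
      stop(sprintf("unknown sample id(s): %s",
                   paste(bcm$samples[is.na(m)], collapse = ", ")),
           call. = FALSE)
    }
    if ("tissue" %in% names(sample_info)) samples$tissue <- sample_info$tissue[m]
    if ("group" %in% names(sample_info)) samples$group <- sample_info$group[m]
  }
  structure(list(E = E, sites = site_df, samples = samples),
            class = "editing_matrix")
}

#' @export
print.editing_matrix <- function(x, ...) {
  cat(sprintf("Editing matrix: %d sites x %d samples (%.1f%% cells valid)\n",
              nrow(x$E), ncol(x$E), 100 * mean(!is.na(x$E))))
  invisible(x)
}

#' @export
dim.editing_matrix <- function(x) dim(x$E)

#' Per-site mean editing over valid cells
#'
#' @param em an \code{\link{editing_matrix}}.
#' @return numeric vector; NA where no cell is valid.
#' @export
site_means <- function(em) {
  stopifnot(inherits(em, "editing_matrix"))
  rowMeans(em$E, na.rm = TRUE) |> (\(m) { m[is.nan(m)] <- NA_real_; m })()
}

#' Per-tissue site summary
#'
#' Mean, SD and number of valid samples per site and tissue, computed over
#' valid cells only.  \code{mean_pct} reports the editing percentage to
#' one decimal; the underlying \code{mean} stays a fraction.
#'
#' @param em an \code{\link{editing_matrix}} with tissue labels.
#' @return data.frame: site row, tissue, n, mean, sd, mean_pct.
#' @export
summarize_by_tissue <- function(em) {
  stopifnot(inherits(em, "editing_matrix"))
  tissues <- sort(unique(stats::na.omit(em$samples$tissue)))
  if (!length(tissues)) stop("no tissue labels present", call. = FALSE)
  out <- list()
  for (tis in tissues) {
    cols <- which(em$samples$tissue == tis)
    sub <- em$E[, cols, drop = FALSE]
    n <- rowSums(!is.na(sub))
    mu <- rowMeans(sub, na.rm = TRUE); mu[n == 0] <- NA_real_
    sd <- apply(sub, 1L, stats::sd, na.rm = TRUE)
    sd[n < 2] <- NA_real_
    out[[tis]] <- data.frame(
      site = seq_len(nrow(sub)),
      contig = em$sites$contig, pos = em$sites$pos,
      tissue = tis, n = n, mean = mu, sd = sd,
      mean_pct = round(100 * mu, 1),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Write an editing matrix to TSV
#'
#' @param em an \code{\link{editing_matrix}}.
#' @param path output file.
#' @export
write_editing_matrix <- function(em, path) {
  out <- cbind(data.frame(contig = em$sites$contig,
                          pos_1based = em$sites$pos + 1L,
                          strand = em$sites$strand),
               as.data.frame(em$E))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
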