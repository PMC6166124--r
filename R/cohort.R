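#' Differential editing between two cohorts
#'
#' Per site: group means over valid cells, log2 fold change of the means,
#' and a two-sided test on the per-sample editing indices (Welch's t-test
#' by default; Mann-Whitney U as the nonparametric fallback).  A site is
#' flagged when |log2 FC| >= \code{fc_cutoff} and p < \code{alpha}.  The
#' 0.9 cutoff on the log2 scale corresponds to a ~1.9-fold linear change
#' (2^0.9 = 1.87).
#'
#' Sites with fewer than two valid samples in either group are skipped
#' (recorded in the \code{skipped} attribute).  When both groups are
#' constant, p is reported as 1 if the means are equal and 0 otherwise
#' (degenerate-variance rule).  Fold change is only computed when both
#' group means are positive.  Raw p-values are reported; a
#' Benjamini-Hochberg column (\code{p_adj}) is included for convenience.
#'
#' @param em an \code{\link{editing_matrix}} with group labels (or pass
#'   \code{labels}).
#' @param labels per-sample group labels (defaults to
#'   \code{em$samples$group}).
#' @param groups length-2 character: numerator and denominator group for
#'   the fold change.
#' @param alpha significance level (default 0.05).
#' @param fc_cutoff |log2 FC| cutoff (default 0.9).
#' @param test \code{"welch"} or \code{"mannwhitney"}.
#' @return data.frame of class \code{differential_editing}, sorted by p:
#'   site info, \code{mean_<groups>}, \code{log2_fc}, \code{statistic},
#'   \code{p}, \code{p_adj}, \code{passes_fc_cutoff},
#'   \code{passes_significance}.
#' @export
differential_editing <- function(em, labels = NULL,
                                 groups = c("healthy", "diseased"),
                                 alpha = 0.05, fc_cutoff = 0.9,
                                 test = c("welch", "mannwhitney")) {
  stopifnot(inherits(em, "editing_matrix"), length(groups) == 2L)
  test <- match.arg(test)
  if (is.null(labels)) labels <- em$samples$group
  stopifnot(length(labels) == ncol(em$E))
  colsA <- which(labels == groups[1])
  colsB <- which(labels == groups[2])
  if (!length(colsA) || !length(colsB)) {
    stop(sprintf("both groups must be non-empty (%s: %d, %s: %d)",
                 groups[1], length(colsA), groups[2], length(colsB)),
         call. = FALSE)
  }
  n_sites <- nrow(em$E)
  rec <- vector("list", n_sites)
  skipped <- integer()
  for (i in seq_len(n_sites)) {
    xa <- em$E[i, colsA]; xa <- xa[!is.na(xa)]
    xb <- em$E[i, colsB]; xb <- xb[!is.na(xb)]
    if (length(xa) < 2L || length(xb) < 2L) {
      skipped <- c(skipped, i)
      next
    }
    ma <- mean(xa); mb <- mean(xb)
    l2fc <- if (ma > 0 && mb > 0) log2(ma / mb) else NA_real_
    ht <- two_group_test(xa, xb, test)
    rec[[i]] <- data.frame(
      site = i,
      contig = em$sites$contig[i], pos = em$sites$pos[i],
      mean_a = ma, mean_b = mb, log2_fc = l2fc,
      statistic = ht$statistic, p = ht$p,
      stringsAsFactors = FALSE)
  }
  rec <- rec[!vapply(rec, is.null, logical(1))]
  if (!length(rec)) {
    res <- data.frame(site = integer(), contig = character(),
                      pos = integer(), mean_a = numeric(),
                      mean_b = numeric(), log2_fc = numeric(),
                      statistic = numeric(), p = numeric())
  } else {
    res <- do.call(rbind, rec)
  }
  names(res)[names(res) == "mean_a"] <- paste0("mean_", groups[1])
  names(res)[names(res) == "mean_b"] <- paste0("mean_", groups[2])
  res$p_adj <- stats::p.adjust(res$p, method = "BH")
  res$passes_fc_cutoff <- !is.na(res$log2_fc) & abs(res$log2_fc) >= fc_cutoff
  res$passes_significance <- res$p < alpha
  res <- res[order(res$p), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "skipped") <- skipped
  attr(res, "test") <- test
  attr(res, "groups") <- groups
  class(res) <- c("differential_editing", "data.frame")
  res
}

two_group_test <- function(xa, xb, test) {
  if (test == "welch") {
    ht <- tryCatch(stats::t.test(xa, xb, var.equal = FALSE),
                   error = function(e) NULL)
    if (is.null(ht)) {
      # both groups (essentially) constant
      p <- if (isTRUE(all.equal(mean(xa), mean(xb)))) 1 else 0
      return(list(statistic = NA_real_, p = p))
    }
    list(statistic = unname(ht$statistic), p = ht$p.value)
  } else {
    ht <- suppressWarnings(stats::wilcox.test(xa, xb, exact = FALSE))
    p <- ht$p.value
    if (is.na(p)) p <- 1 # all values tied
    list(statistic = unname(ht$statistic), p = p)
  }
}

#' @export
print.differential_editing <- function(x, ...) {
  g <- attr(x, "groups")
  cat(sprintf("Differential editing (%s vs %s, %s test): %d sites, %d flagged\n",
              g[1], g[2], attr(x, "test"), nrow(x),
              sum(x$passes_fc_cutoff & x$passes_significance)))
  NextMethod()
}

#' Correlate gene expression with editing levels
#'
#' Pearson correlation and least-squares regression of per-sample editing
#' levels on per-sample expression values (e.g. ADAR2 expression vs FLNA
#' editing).
#'
#' @param expression,editing paired numeric vectors (>= 3 complete pairs,
#'   both non-constant).
#' @return list with \code{r}, \code{slope}, \code{intercept}, \code{p}
#'   (two-sided, for r), \code{n}.
#' @examples
#' correlate_expression_editing(1:10, 0.05 * (1:10) + 0.1)$r
#' @export
correlate_expression_editing <- function(expression, editing) {
  stopifnot(length(expression) == length(editing))
  ok <- !is.na(expression) & !is.na(editing)
  x <- expression[ok]; y <- editing[ok]
  if (length(x) < 3L) stop("need at least 3 paired observations", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined for a constant vector", call. = FALSE)
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  fit <- stats::lm(y ~ x)
  list(r = unname(ct$estimate),
       slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       p = ct$p.value, n = length(x))
}

#' Hierarchical clustering of tissue editing profiles
#'
#' Clusters tissues by their mean editing profile across a shared site
#' set (sites with any missing tissue mean are dropped).  Euclidean
#' distance and average linkage by default; tissues are ordered by label
#' before computing distances so the output is deterministic.
#'
#' @param em an \code{\link{editing_matrix}} with tissue labels (>= 3
#'   tissues).
#' @param method linkage method for \code{\link[stats]{hclust}}.
#' @return list with \code{hclust}, \code{phylo} (an \code{ape} tree) and
#'   \code{newick} (character).
#' @export
cluster_tissues <- function(em, method = "average") {
  stopifnot(inherits(em, "editing_matrix"))
  tissues <- sort(unique(stats::na.omit(em$samples$tissue)))
  if (length(tissues) < 3L) stop("need >= 3 tissues", call. = FALSE)
  prof <- vapply(tissues, function(tis) {
    sub <- em$E[, em$samples$tissue == tis, drop = FALSE]
    mu <- rowMeans(sub, na.rm = TRUE)
    mu[!is.finite(mu)] <- NA_real_
    mu
  }, numeric(nrow(em$E)))
  if (is.null(dim(prof))) prof <- matrix(prof, nrow = 1L,
                                         dimnames = list(NULL, tissues))
  complete <- rowSums(is.na(prof)) == 0L
  prof <- prof[complete, , drop = FALSE]
  if (nrow(prof) == 0L) stop("no shared sites across tissues", call. = FALSE)
  hc <- stats::hclust(stats::dist(t(prof), method = "euclidean"),
                      method = method)
  phy <- ape::as.phylo(hc)
  list(hclust = hc, phylo = phy, newick = ape::write.tree(phy))
}
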