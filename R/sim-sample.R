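#' Simulate one sample's base counts or aligned reads
#'
#' Generates, for a single sample of a given cohort group, either the
#' per-position base counts directly (fast path used for large cohorts) or
#' a coordinate-sorted SAM file of ungapped full-length reads (used when
#' the pileup tally itself is under test).
#'
#' At each planted site the number of edited reads is binomially sampled
#' with success probability drawn from
#' \eqn{Beta(\mu\kappa, (1-\mu)\kappa)} around the group's true rate
#' \eqn{\mu}; with \code{per_sample_dispersion = Inf} the rate is exactly
#' \eqn{\mu}.  Every unedited read base is substituted with probability
#' \code{error_rate}, uniformly over the three alternatives.  Reads over
#' '-' genes carry the complement on the reference strand, so an edited
#' base appears as C at a plus-strand T.
#'
#' @param reference,genes output of \code{\link{simulate_reference}}.
#' @param truth a \code{\link{plant_truth}} result.
#' @param sample_id sample name.
#' @param group cohort group; must have a \code{rate_<group>} column in
#'   \code{truth$sites}.
#' @param config a \code{\link{sim_config}}.
#' @param seed integer seed for this sample (derive per sample via
#'   \code{\link{derive_seed}} for reproducible cohorts).
#' @param depth mean coverage (defaults to \code{config$mean_depth}).
#' @param output \code{"counts"} or \code{"sam"}.
#' @param sam_path file path for \code{output = "sam"}.
#' @param snp_carrier logical; whether this sample carries the G allele at
#'   SNP-like confounder positions.
#' @return for \code{"counts"}: a list with \code{positions} (the genic
#'   position table) and integer vectors \code{A,C,G,T} on the transcribed
#'   strand; for \code{"sam"}: the SAM path, invisibly.
#' @export
simulate_sample <- function(reference, genes, truth, sample_id, group,
                            config, seed,
                            depth = config$mean_depth,
                            output = c("counts", "sam"),
                            sam_path = NULL,
                            snp_carrier = FALSE) {
  output <- match.arg(output)
  rate_col <- paste0("rate_", group)
  if (nrow(truth$sites) > 0 && !rate_col %in% names(truth$sites)) {
    stop(sprintf("group '%s' has no true rates in truth", group),
         call. = FALSE)
  }
  if (depth == 0) {
    warning(sprintf("depth = 0: sample '%s' emitted empty", sample_id))
  }
  set.seed(seed)
  if (output == "counts") {
    simulate_sample_counts(reference, genes, truth, group, config, depth,
                           snp_carrier)
  } else {
    if (is.null(sam_path)) stop("'sam_path' required for output = 'sam'")
    simulate_sample_sam(reference, genes, truth, group, config, depth,
                        sam_path, sample_id, snp_carrier)
  }
}

#' Simulate observed editing levels at a single site
#'
#' The per-site sampling model of the cohort simulator, exposed directly
#' for power and null analyses: each sample's true rate is beta-dispersed
#' around the cohort mean, coverage is Poisson, and the observed editing
#' level is the binomial fraction of edited reads.
#'
#' @param mu cohort mean editing rate.
#' @param n number of samples.
#' @param dispersion beta concentration (Inf = no sample-to-sample
#'   spread).
#' @param depth mean coverage.
#' @return numeric vector of n observed editing fractions (NA where a
#'   sample drew zero coverage).
#' @examples
#' set.seed(1)
#' mean(simulate_editing_levels(0.23, 100, 70, 50))
#' @export
simulate_editing_levels <- function(mu, n, dispersion = 70, depth = 50) {
  stop_if_not_fraction(mu, "mu")
  p <- if (is.infinite(dispersion)) rep(mu, n) else {
    if (mu <= 0 || mu >= 1) rep(mu, n)
    else stats::rbeta(n, mu * dispersion, (1 - mu) * dispersion)
  }
  cov <- stats::rpois(n, depth)
  out <- stats::rbinom(n, cov, p) / cov
  out[cov == 0L] <- NA_real_
  out
}

hv_intervals <- function(truth) {
  cf <- truth$confounders
  cf[cf$kind == "hypervariable_region", c("start", "end"), drop = FALSE]
}

# --- counts path ----------------------------------------------------------

simulate_sample_counts <- function(reference, genes, truth, group, config,
                                   depth, snp_carrier) {
  gp <- genic_positions(genes)
  n <- nrow(gp)
  base_plus <- substring(reference[[1L]], gp$pos + 1L, gp$pos + 1L)
  ref_tx <- ifelse(gp$strand == "-", comp_base(base_plus), base_plus)

  cov <- stats::rpois(n, depth)
  counts <- list(A = integer(n), C = integer(n), G = integer(n),
                 T = integer(n))

  # planted editing: edited reads become G on the transcribed strand
  edited <- integer(n)
  if (nrow(truth$sites) > 0) {
    site_row <- match(truth$sites$pos, gp$pos)
    mu <- truth$sites[[paste0("rate_", group)]]
    k <- config$per_sample_dispersion
    p <- if (is.infinite(k)) mu else {
      ifelse(mu <= 0 | mu >= 1, mu,
             stats::rbeta(length(mu), mu * k, (1 - mu) * k))
    }
    ok <- !is.na(site_row)
    edited[site_row[ok]] <- stats::rbinom(sum(ok), cov[site_row[ok]], p[ok])
  }

  # uniform substitution error on the unedited (reference-base) reads
  eligible <- cov - edited
  err <- stats::rbinom(n, eligible, config$error_rate)
  err3 <- split_errors_3(err)
  bases <- c("A", "C", "G", "T")
  for (b in bases) {
    rows <- which(ref_tx == b)
    if (!length(rows)) next
    alts <- setdiff(bases, b)
    counts[[b]][rows] <- counts[[b]][rows] + eligible[rows] - err[rows]
    for (j in 1:3) {
      counts[[alts[j]]][rows] <- counts[[alts[j]]][rows] + err3[rows, j]
    }
  }
  counts$G <- counts$G + edited

  # confounders
  cf <- truth$confounders
  if (nrow(cf) > 0) {
    snp <- match(cf$pos[cf$kind == "snp_like"], gp$pos)
    snp <- snp[!is.na(snp)]
    if (length(snp) && snp_carrier) {
      counts$A[snp] <- 0L; counts$C[snp] <- 0L; counts$T[snp] <- 0L
      counts$G[snp] <- cov[snp]
    }
    mm <- match(cf$pos[cf$kind == "multi_mismatch"], gp$pos)
    mm <- mm[!is.na(mm)]
    if (length(mm)) {
      mu_mm <- mean(config$rate_range)
      cc <- stats::rbinom(length(mm), counts$A[mm], mu_mm)
      counts$A[mm] <- counts$A[mm] - cc
      counts$C[mm] <- counts$C[mm] + cc
    }
    hv <- hv_intervals(truth)
    if (nrow(hv)) {
      in_hv <- rep(FALSE, n)
      for (i in seq_len(nrow(hv))) {
        in_hv <- in_hv | (gp$pos >= hv$start[i] & gp$pos < hv$end[i])
      }
      rows <- which(in_hv)
      for (b in bases) {
        sel <- rows[ref_tx[rows] == b]
        if (!length(sel)) next
        alts <- setdiff(bases, b)
        for (a in alts) {
          x <- stats::rbinom(length(sel),
                             pmax(counts[[b]][sel], 0L),
                             config$hypervariable_rate)
          counts[[b]][sel] <- counts[[b]][sel] - x
          counts[[a]][sel] <- counts[[a]][sel] + x
        }
      }
    }
  }
  list(positions = cbind(gp, ref = ref_tx, stringsAsFactors = FALSE),
       A = counts$A, C = counts$C, G = counts$G, T = counts$T)
}

# --- SAM path -------------------------------------------------------------

simulate_sample_sam <- function(reference, genes, truth, group, config,
                                depth, sam_path, sample_id, snp_carrier) {
  L <- config$reference_length
  rl <- config$read_length
  n_reads <- max(0L, as.integer(round(depth * L / rl)))
  header <- c("@HD\tVN:1.6\tSO:coordinate",
              sprintf("@SQ\tSN:chr1\tLN:%d", L),
              sprintf("@RG\tID:%s\tSM:%s", sample_id, sample_id))
  if (n_reads == 0L) {
    writeLines(header, sam_path)
    return(invisible(sam_path))
  }
  starts <- sort(sample.int(L - rl + 1L, n_reads, replace = TRUE))
  mat <- matrix(unlist(strsplit(substring(reference[[1L]], starts,
                                          starts + rl - 1L), "")),
                nrow = n_reads, byrow = TRUE)

  # substitution errors, uniform over alternatives
  n_err <- stats::rbinom(1L, n_reads * rl, config$error_rate)
  if (n_err > 0) {
    idx <- sample.int(n_reads * rl, n_err)
    cur <- mat[idx]
    mat[idx] <- vapply(cur, function(b) {
      sample(setdiff(c("A", "C", "G", "T"), b), 1L)
    }, character(1))
  }

  plant_at <- function(pos0, plus_base, prob) {
    # set covering reads' base at plus-strand position pos0 with prob each
    covering <- which(starts <= pos0 + 1L & starts + rl - 1L >= pos0 + 1L)
    if (!length(covering)) return(invisible(NULL))
    hit <- covering[stats::runif(length(covering)) < prob]
    if (length(hit)) {
      mat[cbind(hit, pos0 + 2L - starts[hit])] <<- plus_base
    }
  }

  if (nrow(truth$sites) > 0) {
    mu <- truth$sites[[paste0("rate_", group)]]
    k <- config$per_sample_dispersion
    p <- if (is.infinite(k)) mu else {
      ifelse(mu <= 0 | mu >= 1, mu,
             stats::rbeta(length(mu), mu * k, (1 - mu) * k))
    }
    for (i in seq_len(nrow(truth$sites))) {
      # edited G on the transcribed strand: G on '+', C on '-'
      b <- if (truth$sites$strand[i] == "+") "G" else "C"
      plant_at(truth$sites$pos[i], b, p[i])
    }
  }
  cf <- truth$confounders
  if (nrow(cf) > 0) {
    gp <- genic_positions(genes)
    strand_of <- function(p) gp$strand[match(p, gp$pos)]
    for (i in which(cf$kind == "snp_like")) {
      if (snp_carrier) {
        b <- if (identical(strand_of(cf$pos[i]), "+")) "G" else "C"
        plant_at(cf$pos[i], b, 1.0)
      }
    }
    mu_mm <- mean(config$rate_range)
    for (i in which(cf$kind == "multi_mismatch")) {
      b <- if (identical(strand_of(cf$pos[i]), "+")) "C" else "G"
      plant_at(cf$pos[i], b, mu_mm)
    }
    for (i in which(cf$kind == "hypervariable_region")) {
      for (p0 in seq(cf$start[i], cf$end[i] - 1L)) {
        for (b in c("A", "C", "G", "T")) {
          plant_at(p0, b, config$hypervariable_rate)
        }
      }
    }
  }

  seqs <- apply(mat, 1L, paste, collapse = "")
  qual <- strrep("I", rl)
  recs <- sprintf("read%06d\t0\tchr1\t%d\t60\t%dM\t*\t0\t0\t%s\t%s",
                  seq_len(n_reads), starts, rl, seqs, qual)
  writeLines(c(header, recs), sam_path)
  invisible(sam_path)
}
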