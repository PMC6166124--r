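cc_of <- function(A, C, G, T) {
  # candidate count matrices for ref A / alt G rows
  A <- matrix(as.integer(A), ncol = length(A))
  C <- matrix(as.integer(C), ncol = length(C))
  G <- matrix(as.integer(G), ncol = length(G))
  T <- matrix(as.integer(T), ncol = length(T))
  list(ref = A, alt = G, coverage = A + C + G + T)
}

test_that("builtin tissue profiles carry the published cutoffs", {
  p <- builtin_profiles()
  expect_identical(p$aorta$min_coverage, 15L)
  expect_identical(p$aorta$min_editing, 0.05)
  expect_identical(p$aorta$consensus_reads, 2L)
  expect_identical(p$aorta$min_supporting_samples, 70L)
  expect_identical(p$ventricular_appendage$min_coverage, 5L)
  expect_identical(p$coronaries$min_editing, 0.03)
  expect_identical(p$tibial_artery$min_coverage, 5L)
  expect_identical(p$left_ventricle$min_supporting_samples, 100L)
  expect_identical(builtin_profiles("left ventricle")$min_editing, 0.03)
  expect_error(builtin_profiles("brain"), "unknown tissue")
})

test_that("the per-sample support predicate applies all three cutoffs inclusively", {
  aorta <- builtin_profiles("aorta")
  # coverage 14 < 15 fails regardless of editing
  expect_false(sample_supports(cc_of(7, 0, 7, 0), aorta)[1, 1])
  # index 0.2, 2 consensus reads, coverage 10 passes a (0.05, 2, 5, .) profile
  p <- filter_profile("t", 0.05, 2, 5, 1)
  expect_true(sample_supports(cc_of(8, 0, 2, 0), p)[1, 1])
  # one G read fails consensus_reads = 2 regardless of other cutoffs
  expect_false(sample_supports(cc_of(19, 0, 1, 0), p)[1, 1])
  # boundary: exactly at all three cutoffs -> supported (>= semantics)
  p2 <- filter_profile("t", 0.1, 2, 20, 1)
  expect_true(sample_supports(cc_of(18, 0, 2, 0), p2)[1, 1])
})

test_that("multi-editing exclusion flags samples with mixed alternative bases", {
  p <- filter_profile("t", 0.05, 2, 5, 1)
  # (A:10,C:5,G:5): other-alt fraction 5/10 = 0.5 > 0.2 -> excluded
  expect_true(multi_editing_exclusions(cc_of(10, 5, 5, 0), p)[1, 1])
  # (A:10,C:0,G:5): fraction 0 -> kept
  expect_false(multi_editing_exclusions(cc_of(10, 0, 5, 0), p)[1, 1])
  # (A:10,C:1,G:0): only one alternative read, too few to judge -> kept
  expect_false(multi_editing_exclusions(cc_of(10, 1, 0, 0), p)[1, 1])
})

test_that("consistency filter requires a dominant-G majority among qualifying samples", {
  p <- filter_profile("t", 0.05, 2, 5, 1)
  cand <- data.frame(idx = 1L, contig = "chr1", pos = 10L, strand = "+",
                     ref = "A", alt = "G", stringsAsFactors = FALSE)
  mk <- function(g_dom, n) {
    # n qualifying samples; g_dom of them dominant-G, rest dominant-C
    G <- ifelse(seq_len(n) <= g_dom, 5L, 0L)
    C <- ifelse(seq_len(n) <= g_dom, 0L, 5L)
    A <- rep(10L, n); T <- rep(0L, n)
    sites <- data.frame(contig = "chr1", pos = 10L, strand = "+",
                        ref = "A", stringsAsFactors = FALSE)
    bcm <- base_count_matrix(sites,
                             list(A = matrix(A, 1), C = matrix(C, 1),
                                  G = matrix(G, 1), T = matrix(T, 1)),
                             sprintf("S%02d", seq_len(n)))
    list(bcm = bcm, cc = list(ref = matrix(A, 1), alt = matrix(G, 1),
                              coverage = matrix(A + C + G + T, 1)))
  }
  x <- mk(7, 10) # 7/10 = 0.7 < 0.8 -> dropped
  expect_false(consistency_keep(x$bcm, cand, x$cc, p))
  x <- mk(10, 10) # 10/10 -> kept
  expect_true(consistency_keep(x$bcm, cand, x$cc, p))
  x <- mk(0, 0)   # zero qualifying samples -> dropped
  # build a single non-qualifying sample instead of an empty matrix
  x <- mk(1, 1)
  x$bcm$counts$G[] <- 1L; x$cc$alt[] <- 1L # below consensus_reads
  x$cc$coverage <- x$cc$ref + x$cc$alt
  expect_false(consistency_keep(x$bcm, cand, x$cc, p))
})

test_that("blacklist intervals remove exactly the overlapped sites (0-based half-open)", {
  sites <- data.frame(contig = "chr1", pos = c(100L, 100L),
                      stringsAsFactors = FALSE)[1, , drop = FALSE]
  bl <- GenomicRanges::GRanges("chr1", IRanges::IRanges(101, 101)) # [100,101)
  expect_identical(nrow(blacklist_filter(sites, bl)), 0L)
  bl2 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(102, 200)) # [101,200)
  expect_identical(nrow(blacklist_filter(sites, bl2)), 1L)
})

test_that("a malformed BED line is reported with its line number", {
  bed <- tempfile(fileext = ".bed")
  writeLines(c("chr1\t10\t20", "chr1\toops\t30"), bed)
  expect_error(read_bed(bed), "line 2")
})

recovery_sim <- function(seed = 31) {
  simulate_cohort(sim_config(
    reference_length = 8000, n_genes = 6, n_edit_sites = 30,
    n_samples = 40, mean_depth = 40, rate_range = c(0.15, 0.9),
    error_rate = 0.001, seed = seed))
}

test_that("the cascade recovers planted sites and blacklisting removes the covered ones", {
  sim <- recovery_sim()
  prof <- filter_profile("t", 0.05, 2, 5, 30)
  rep <- run_cascade(sim$counts, prof)
  expect_true(all(sim$truth$sites$pos %in% rep$sites$pos))
  # blacklist two planted sites -> exactly those two disappear
  bl_pos <- sort(sim$truth$sites$pos)[1:2]
  bl <- GenomicRanges::GRanges("chr1",
                               IRanges::IRanges(bl_pos + 1L, bl_pos + 1L))
  rep_bl <- run_cascade(sim$counts, prof, blacklist = bl)
  expect_identical(setdiff(rep$sites$pos, rep_bl$sites$pos), bl_pos)
})

test_that("stage counts never increase along the cascade", {
  sim <- recovery_sim()
  rep <- run_cascade(sim$counts, filter_profile("t", 0.05, 2, 5, 30))
  st <- rep$stages
  expect_true(all(st$sites_out <= st$sites_in))
  expect_true(all(diff(st$sites_in) <= 0 |
                  st$sites_in[-1] == st$sites_out[-nrow(st)]))
})

test_that("tightening any single cutoff yields a subset of the looser site set", {
  sim <- recovery_sim()
  base <- list(min_editing = 0.05, consensus_reads = 2L,
               min_coverage = 5L, min_supporting_samples = 25L)
  tighter <- list(min_editing = 0.2, consensus_reads = 5L,
                  min_coverage = 30L, min_supporting_samples = 38L)
  loose_sites <- run_cascade(sim$counts,
                             do.call(filter_profile, c(tissue = "t", base)))$sites$pos
  for (cut in names(base)) {
    args <- base; args[[cut]] <- tighter[[cut]]
    tight_sites <- run_cascade(sim$counts,
                               do.call(filter_profile, c(tissue = "t", args)))$sites$pos
    expect_true(all(tight_sites %in% loose_sites), label = cut)
  }
})

test_that("the cascade is idempotent on its own surviving site set", {
  sim <- recovery_sim()
  prof <- filter_profile("t", 0.05, 2, 5, 30)
  rep1 <- run_cascade(sim$counts, prof)
  idx <- match(rep1$sites$pos, sim$counts$sites$pos)
  sub <- base_count_matrix(
    sim$counts$sites[idx, , drop = FALSE],
    lapply(sim$counts$counts, function(m) m[idx, , drop = FALSE]),
    sim$counts$samples)
  rep2 <- run_cascade(sub, prof)
  expect_setequal(rep2$sites$pos, rep1$sites$pos)
})

test_that("the supporting-sample cutoff is inclusive at the boundary", {
  # 70 samples: exactly 70 supporting -> kept; 69 -> dropped
  n <- 70L
  mk <- function(n_supp) {
    A <- matrix(rep(16L, n), 1); G <- matrix(0L, 1, n)
    G[1, seq_len(n_supp)] <- 4L
    sites <- data.frame(contig = "chr1", pos = 0L, strand = "+", ref = "A",
                        stringsAsFactors = FALSE)
    base_count_matrix(sites, list(A = A, C = matrix(0L, 1, n),
                                  G = G, T = matrix(0L, 1, n)),
                      sprintf("S%03d", 1:n))
  }
  prof <- builtin_profiles("aorta") # min_supporting_samples 70
  expect_identical(nrow(run_cascade(mk(70L), prof)$sites), 1L)
  expect_identical(nrow(run_cascade(mk(69L), prof)$sites), 0L)
})

test_that("A-to-G enrichment traces the fraction of surviving A-to-G candidates", {
  # 9 A->G sites and 1 A->C site, all surviving a permissive profile
  n_samp <- 4L
  ref <- rep("A", 10)
  A <- matrix(12L, 10, n_samp)
  G <- rbind(matrix(8L, 9, n_samp), matrix(0L, 1, n_samp))
  C <- rbind(matrix(0L, 9, n_samp), matrix(8L, 1, n_samp))
  bcm <- make_bcm(ref, A, C, G, matrix(0L, 10, n_samp))
  prof <- filter_profile("t", 0.05, 2, 5, 2)
  rep <- run_cascade(bcm, prof)
  expect_equal(ag_enrichment(rep), 0.9)
  expect_identical(nrow(rep$sites), 9L)

  # error-free simulation with only A->G planted -> enrichment 1.0
  sim <- simulate_cohort(sim_config(reference_length = 3000, n_genes = 3,
                                    n_edit_sites = 6, n_samples = 10,
                                    mean_depth = 40, error_rate = 0,
                                    rate_range = c(0.3, 0.7), seed = 17))
  rep <- run_cascade(sim$counts, filter_profile("t", 0.05, 2, 5, 8))
  expect_identical(ag_enrichment(rep), 1)
})

test_that("uniform error with no editing gives ~1/12 enrichment at nomination", {
  sim <- simulate_cohort(sim_config(reference_length = 12000, n_genes = 8,
                                    n_edit_sites = 0, n_samples = 20,
                                    mean_depth = 60, error_rate = 0.01,
                                    seed = 23))
  rep <- run_cascade(sim$counts, filter_profile("t", 0.05, 2, 5, 14))
  enr0 <- ag_enrichment(rep, stage = "nomination")
  expect_gt(enr0, 1 / 12 - 0.04)
  expect_lt(enr0, 1 / 12 + 0.04)
})

test_that("SNP-like confounders pass the printed cutoffs (documented behaviour)", {
  sim <- simulate_cohort(sim_config(reference_length = 4000, n_genes = 4,
                                    n_edit_sites = 0, n_snp_like = 1,
                                    n_samples = 20, mean_depth = 40,
                                    error_rate = 0, seed = 29))
  snp_pos <- sim$truth$confounders$pos[1]
  rep <- run_cascade(sim$counts, filter_profile("t", 0.05, 2, 5, 8))
  expect_true(snp_pos %in% rep$sites$pos)
})

test_that("detection probability rises with true rate and depth", {
  # 2x2 corner check of the monotone sensitivity surface
  det <- function(rate, depth, seed) {
    sim <- simulate_cohort(sim_config(
      reference_length = 3000, n_genes = 3, n_edit_sites = 10,
      n_samples = 20, mean_depth = depth, rate_range = c(rate, rate),
      error_rate = 0.001, seed = seed))
    rep <- run_cascade(sim$counts, filter_profile("t", 0.05, 2, 10, 16))
    mean(sim$truth$sites$pos %in% rep$sites$pos)
  }
  lo <- mean(vapply(1:3, function(s) det(0.05, 12, s), numeric(1)))
  hi_rate <- mean(vapply(1:3, function(s) det(0.4, 12, s), numeric(1)))
  hi_depth <- mean(vapply(1:3, function(s) det(0.05, 60, s), numeric(1)))
  expect_gte(hi_rate, lo)
  expect_gte(hi_depth, lo)
})
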