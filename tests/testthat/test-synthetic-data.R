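small_cfg <- function(...) {
  defaults <- list(reference_length = 4000, n_genes = 4, n_edit_sites = 8,
                   n_samples = 6, mean_depth = 40,
                   rate_range = c(0.2, 0.8), seed = 7)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

test_that("identical config and seed reproduce the cohort byte for byte", {
  cfg <- small_cfg()
  d1 <- file.path(tempdir(), "simA"); d2 <- file.path(tempdir(), "simB")
  simulate_cohort(cfg, outdir = d1)
  simulate_cohort(cfg, outdir = d2)
  for (f in c("reference.fa", "genes.bed", "base_counts.tsv",
              "truth_sites.tsv", "samples.tsv")) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
})

test_that("gene placement respects strand fraction and disjointness", {
  ref <- simulate_reference(small_cfg(minus_strand_fraction = 0))
  expect_true(all(as.character(GenomicRanges::strand(ref$genes)) == "+"))

  ref <- simulate_reference(sim_config(reference_length = 10000, n_genes = 5,
                                       seed = 3))
  g <- ref$genes
  expect_length(g, 5L)
  # brute-force interval sweep: no base claimed twice
  occupied <- integer(10000)
  for (i in seq_along(g)) {
    span <- GenomicRanges::start(g)[i]:GenomicRanges::end(g)[i]
    occupied[span] <- occupied[span] + 1L
  }
  expect_true(all(occupied <= 1L))
})

test_that("a reference too small for its genes is rejected", {
  expect_error(simulate_reference(sim_config(reference_length = 200,
                                             n_genes = 10,
                                             read_length = 50)),
               "too small")
})

test_that("planted sites are A on the transcribed strand (T on plus for '-' genes)", {
  cfg <- small_cfg(minus_strand_fraction = 0.5)
  ref <- simulate_reference(cfg)
  truth <- plant_truth(ref$reference, ref$genes, cfg)
  base_plus <- substring(ref$reference[[1]], truth$sites$pos + 1L,
                         truth$sites$pos + 1L)
  expect_true(all(base_plus[truth$sites$strand == "+"] == "A"))
  expect_true(all(base_plus[truth$sites$strand == "-"] == "T"))
})

test_that("degenerate rate ranges pin true rates exactly (published presets)", {
  cfg <- small_cfg()
  ref <- simulate_reference(cfg)
  truth <- plant_truth(ref$reference, ref$genes, cfg,
                       rate_ranges = cohort_preset("flna_dcm")$rate_ranges)
  expect_true(all(truth$sites$rate_healthy == 0.23))
  expect_true(all(truth$sites$rate_diseased == 0.12))

  truth <- plant_truth(ref$reference, ref$genes, cfg,
                       rate_ranges = cohort_preset("tibial")$rate_ranges)
  expect_true(all(truth$sites$rate_healthy == 0.878))
  expect_true(all(truth$sites$rate_diseased == 0.685))

  truth <- plant_truth(ref$reference, ref$genes, cfg,
                       rate_ranges = cohort_preset("aorta")$rate_ranges)
  expect_true(all(truth$sites$rate_healthy == 0.775))
  expect_true(all(truth$sites$rate_diseased == 0.626))
})

test_that("zero sites yields an empty site list, confounders only", {
  cfg <- small_cfg(n_edit_sites = 0, n_snp_like = 2)
  ref <- simulate_reference(cfg)
  truth <- plant_truth(ref$reference, ref$genes, cfg)
  expect_identical(nrow(truth$sites), 0L)
  expect_identical(nrow(truth$confounders), 2L)
})

test_that("zero-editing, zero-error samples contain only reference bases", {
  cfg <- small_cfg(error_rate = 0, rate_range = c(0, 0))
  sim <- simulate_cohort(cfg)
  bcm <- sim$counts
  nonref <- 0L
  for (b in c("A", "C", "G", "T")) {
    nonref <- nonref + sum(bcm$counts[[b]][bcm$sites$ref != b, ])
  }
  expect_identical(nonref, 0L)
  # conservation: counts sum to coverage by construction, and coverage
  # equals the reference-base count here
  expect_identical(coverage_matrix(bcm),
                   bcm$counts$A * (bcm$sites$ref == "A") +
                   bcm$counts$C * (bcm$sites$ref == "C") +
                   bcm$counts$G * (bcm$sites$ref == "G") +
                   bcm$counts$T * (bcm$sites$ref == "T"))
})

test_that("observed editing converges to the planted rate", {
  # one deeply covered site: binomial CI check
  set.seed(1)
  x <- simulate_editing_levels(0.5, 1, Inf, 10000)
  se <- sqrt(0.5 * 0.5 / 10000)
  expect_lt(abs(x - 0.5), 3 * se)

  # cohort mean over 100 samples at depth >= 100 within 3 SE of truth
  cfg <- sim_config(reference_length = 2000, n_genes = 2, n_edit_sites = 4,
                    n_samples = 100, mean_depth = 100,
                    rate_range = c(0.4, 0.4), seed = 21)
  sim <- simulate_cohort(cfg)
  i <- match(sim$truth$sites$pos, sim$counts$sites$pos)
  em <- build_editing_matrix(sim$counts, i)
  mns <- site_means(em)
  per_sample_var <- 0.4 * 0.6 / 71 + 0.4 * 0.6 / 100 # beta + binomial
  se <- sqrt(per_sample_var / 100)
  expect_true(all(abs(mns - 0.4) < 3 * se))
})

test_that("infinite dispersion collapses to binomial-only variance", {
  set.seed(4)
  x_inf <- simulate_editing_levels(0.5, 400, Inf, 100)
  x_k5 <- simulate_editing_levels(0.5, 400, 5, 100)
  v_binom <- 0.5 * 0.5 / 100
  expect_lt(var(x_inf, na.rm = TRUE), 1.5 * v_binom)
  expect_gt(var(x_k5, na.rm = TRUE), 5 * v_binom)
})

test_that("depth zero emits an empty sample with a warning", {
  cfg <- small_cfg()
  ref <- simulate_reference(cfg)
  truth <- plant_truth(ref$reference, ref$genes, cfg)
  expect_warning(
    sc <- simulate_sample(ref$reference, ref$genes, truth, "s0", "healthy",
                          cfg, seed = 1, depth = 0),
    "empty")
  expect_true(all(sc$A + sc$C + sc$G + sc$T == 0L))
})

test_that("an unknown group without true rates is rejected", {
  cfg <- small_cfg()
  ref <- simulate_reference(cfg)
  truth <- plant_truth(ref$reference, ref$genes, cfg)
  expect_error(simulate_sample(ref$reference, ref$genes, truth, "s", "x",
                               cfg, seed = 1),
               "no true rates")
})

test_that("cohort matrix has one column per design row", {
  cfg <- small_cfg()
  sim <- simulate_cohort(cfg, design = cohort_design(2, 2))
  expect_identical(dim(sim$counts)[2], 4L)
  expect_identical(sim$counts$samples, sim$design$sample)
})
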