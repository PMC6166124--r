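# editcascade

Detection, quantification and cohort comparison of A-to-G RNA editing
from RNA-Seq pileups, with a ground-truth cohort simulator.

## The problem

A-to-I RNA editing by ADAR enzymes is read as guanosine during
sequencing, so edited adenosines show up in RNA-Seq alignments as A→G
mismatches against the genome. Cardiovascular tissues carry remarkably
high editing activity — the recoding site in Filamin A (FLNA) exceeds
90% editing in arteries — and editing levels at such sites drop in
patients with cardiovascular disease, which makes reliable site
discovery and cohort comparison clinically interesting. The difficulty
is separating true editing from sequencing errors, SNPs and
hypervariable loci among millions of transcribed adenosines.

`editcascade` is aimed at transcriptomicists who want that separation as
an inspectable, testable pipeline rather than a black box:

- **Strand-aware tallies** — `tally_base_counts()` piles up SAM/BAM
  restricted to annotated genes and expresses A/C/G/T counts on the
  transcribed strand (counts at `-` genes are complemented).
- **Staged filter cascade** — `run_cascade()` applies, in order:
  minimal nomination (any A with a G read), a per-sample multi-editing
  exclusion, a cross-sample consistency filter, per-tissue cutoff
  profiles (minimum editing, consensus reads, minimal coverage, minimum
  supporting samples — `builtin_profiles()` carries the five published
  cardiovascular profiles), and a hypervariable-region blacklist. The
  A-to-G enrichment among all 12 mismatch classes is traced per stage.
- **Quantification** — the editing index G/(A+G) per site and sample,
  with masking, per-site means and per-tissue summaries.
- **Cohort statistics** — per-site Welch t-tests (Mann-Whitney
  fallback) with log2 fold changes (default flags: p < 0.05 and
  |log2 FC| ≥ 0.9 ≈ 1.9-fold), expression–editing correlation, and
  deterministic hierarchical clustering of tissue editing profiles.
- **Synthetic cohorts** — `simulate_cohort()` plants editing sites with
  beta-dispersed per-sample rates (rate ~ Beta(μκ, (1−μ)κ), edited
  reads binomial), uniform substitution errors, minus-strand genes, and
  SNP-like / multi-mismatch / hypervariable confounders; presets pin
  published effect sizes (e.g. FLNA 23% healthy vs 12% diseased).
- **Phenotype metrics** — circumferential cyclic strain
  E<sub>θθ</sub>(t) = ½[(r(t)/r(0))² − 1] = [A(t)/A(0) − 1]/2 and the
  impedance-based contraction percentage (1 − CI<sub>min</sub>) × 100.

## Worked example

Simulate a 20-sample cohort with 10 planted sites, run the cascade, and
compare estimated editing levels against the planted truth:

```r
library(editcascade)

cfg <- sim_config(reference_length = 6000, n_genes = 5, n_edit_sites = 10,
                  n_samples = 20, mean_depth = 40,
                  rate_range = c(0.2, 0.8), seed = 11)
sim <- simulate_cohort(cfg)
rep <- run_cascade(sim$counts, filter_profile("demo", 0.05, 2, 5, 15))
rep
#> Filter cascade report (profile 'demo')
#>            stage sites_in sites_out ag_enrichment
#>       nomination      305       305         0.093
#>    multi_editing      305       305         0.093
#>      consistency      305        19         0.165
#>  profile_cutoffs       19        10         1.000
#>        blacklist       10        10         1.000
#> Final A-to-G sites: 10
```

All 10 planted sites survive; the thousands of error-only nominations are
removed, and the A-to-G fraction among surviving candidates of all 12
mismatch classes (`ag_enrichment`) rises from ~1/12 at nomination to 1.0
— the diagnostic used to tune cutoffs.

```r
em <- build_editing_matrix(sim$counts, rep, sample_info = sim$design)
head(cbind(truth = sim$truth$sites$rate_healthy[
             match(rep$sites$pos, sim$truth$sites$pos)],
           estimate = site_means(em)))
#>      truth estimate
#> [1,] 0.402    0.388
#> [2,] 0.202    0.215
#> [3,] 0.231    0.225
#> [4,] 0.419    0.432
#> [5,] 0.792    0.769
#> [6,] 0.546    0.557
```

Estimated site means track the planted cohort rates to within the
sampling error expected at depth 40 over 20 samples.

The methods vignette (`vignettes/editing-cascade.Rmd`) documents the
model, every decided threshold, the simulator's assumptions, and known
limitations.

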