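# skimpute

Genotyping-by-sequencing from low-coverage ("skim") long-read data, for
people who need breeding values, not BAM files. The package implements the
full desk-scale pipeline for a livestock-style study system:

* **Genotype calling** from per-site read pileups: the GATK-style
  base-quality likelihood `GL(G) = prod_i [ 1/2 Pr(b_i|A1) + 1/2 Pr(b_i|A2) ]`
  with `Pr(b|A) = 1 - e` (match) or `e/3` (mismatch), plus strand-aware
  masking of CpG methylation miscalls, and a coverage-binned
  minimum-allele-count (MAC) caller.
* **Reference panels**: phased haplotype panels with strict MAF filters
  (`MAF > 0.1/0.2/0.3`) that always retain the prediction SNP set, and a
  prediction-sites-only (HD-array analogue) panel.
* **Imputation**, two Li–Stephens haplotype HMM engines: a diploid
  genotype-likelihood engine (forward–backward over ordered haplotype
  pairs), and a read-aware engine that assigns whole reads to parental
  gametes by Gibbs sampling — exploiting the co-localization of SNP on long
  reads — and imputes each gamete as a haploid.
* **SNP-BLUP prediction**: GEBVs as the raw product `a_hat = M g_hat` of the
  dosage matrix with a fixed SNP-effect vector.
* **Evaluation**: Pearson correlations with Fisher-z 95% CIs, prediction
  bias (OLS slope − 1), imputation accuracy, duplicate-run concordance,
  quartile re-ranking, coverage subsampling and outlier dropping, and a
  coverage × panel × method grid runner.
* **Synthetic data**: a generator for haplotype panels (beta allele-frequency
  spectrum, founder-mosaic LD), diploid samples, SNP effects and noisy long
  reads (mean 1,792 bp, ~3% base error, quality-blind 10× CpG error
  inflation), so the whole pipeline runs without any external data.

All user-facing functions take and return tibbles (or small list objects
with tibble components) and chain with the pipe; results have
`tidy()`/`glance()`/`autoplot()` methods. The HMM kernels are C++ (Rcpp).

## Worked example

Simulate the default study system (200-haplotype panel, 2,000 SNP over
2 Mb, 500 prediction SNP, 20 samples), sequence it at 0.5× coverage, impute
with the read-aware engine, and score breeding values against the truth:

```r
library(skimpute)

cfg    <- sim_config()                                 # the study conditions
panel  <- simulate_panel(cfg, seed = 1)
truth  <- simulate_samples(panel, cfg$n_samples, seed = 2)
eff    <- simulate_effects(panel$sites, seed = 3)
reads  <- simulate_reads(truth, config = cfg, coverage = 0.5, seed = 4)

post  <- impute_read_aware(reads, panel, seed = 5)
calls <- posterior_to_calls(post)

pred <- which(panel$sites$is_prediction_site)
est  <- gebv(call_matrix(calls, sites = pred), eff)
ref  <- gebv(true_genotype_matrix(truth)[, pred], eff)

imputation_accuracy(calls, truth_calls <- {
  tg <- true_genotype_matrix(truth)
  call_set(rep(truth$sample_id, each = ncol(tg)),
           rep(seq_len(ncol(tg)), nrow(tg)),
           gt = as.integer(t(tg)), sites = panel$sites)
}, sites = pred)
#> [1] 0.983

pearson_ci(ref$gebv, est$gebv[match(ref$sample_id, est$sample_id)])
#> # A tibble: 1 x 4
#>       r    lo    hi     n
#>   <dbl> <dbl> <dbl> <int>
#> 1 0.914 0.791 0.966    20

prediction_bias(ref$gebv, est$gebv[match(ref$sample_id, est$sample_id)])
#> [1] -0.1997
```

At half-fold coverage the imputed hard genotypes match the simulated truth
at 98.3% of the 500 prediction SNP, and the imputed-dosage GEBVs correlate
with the truth GEBVs at r = 0.91 (95% CI 0.79-0.97) on this single
20-sample draw. The regression slope of truth on estimate is 0.80 here;
single-replicate bias is noisy at n = 20 — the five-replicate sweep run by
`scripts/acceptance.R` (which also drops coverage outliers, as the study
design prescribes) puts the mean bias near zero. The full sweep is one
call:

```r
report <- run_grid(grid_config(coverages = c(0.05, 0.1, 0.5, 2),
                               methods = c("read_aware", "diploid_gl"),
                               n_seeds = 3, seed = 1))
glance(report)
autoplot(report)             # r vs coverage, facetted by panel
```

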