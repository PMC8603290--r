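# oncoprofile

`oncoprofile` is a tidyverse-native R package for desk-scale tumor/normal
genomic characterization and immune-checkpoint-inhibitor (ICI) cohort
analysis. It is aimed at bioinformaticians who need a transparent, fully
tested re-implementation of a common in-house tumor profiling stack:
somatic-variant consensus filtering with tumor mutation burden (TMB),
a log-R-ratio (LRR) copy-number caller with GC-bias correction, variable-gene
PCA and gene-set signature scoring for expression data, and biomarker
stratification statistics for survival cohorts. Because real tumor/normal
sequencing data of this kind are access-restricted, the package ships a
synthetic-data generator with known ground truth, so every stage is testable
end to end.

## What it computes

**Somatic variant filtering and TMB.** Calls from three callers are merged
by consensus (default: keep variants reported by ≥ 2 of 3). A variant is
discarded if any rule fires: tumor total read number < 20; tumor variant
allele frequency (VAF = alt reads / total reads) < 0.05; > 2 mutant reads in
the germline control; all variant reads on a single strand; or presence in a
population SNP database or blacklist. TMB is the count of kept
non-synonymous mutations.

**Copy number.** For catalogued SNP positions that are homozygous
(normal VAF ≤ 0.05 or ≥ 0.95) or heterozygous (VAF 0.4–0.6) in the paired
normal, depths are adjusted for the GC fraction of the 100 bp flanking
window (binned median-ratio normalization), the per-site LRR is

```
LRR_i = log2(t_i / n_i)
```

with `t_i`, `n_i` the GC-adjusted tumor and normal depths (median-centered
genome-wide), and the representative LRR at each site is the median over a
1 Mb window centered there. Gene-level status (homozygous loss / loss /
neutral / gain) is called from the mean representative LRR over the gene.

**Expression.** Median-of-ratios size factors + `log2(x + 1)` give a
variance-stabilized-style matrix; the top-k genes by across-sample SD
(default 10,000) feed a centered PCA; gene-set signature scores are
per-sample means of genewise z-scores.

**Cohort statistics.** ROC/Youden cut-off selection against a 6-month PFS
landmark outcome, CD8 × CD155 four-group stratification, Fisher's exact
2×2 test, Kaplan–Meier estimation, log-rank comparison (with Bonferroni
pairwise follow-up), and paired pre/post marker tests.

## Worked example

```r
library(oncoprofile)
cfg <- sim_config(seed = 1)

# somatic filtering and TMB
calls <- simulate_variant_calls(cfg)
decisions <- apply_discard_rules(calls)
tmb_summary(decisions, sample_id = "MEL_sim")
#>   sample_id n_input n_kept n_non_synonymous
#> 1 MEL_sim        75     50               27
```

75 simulated variants (50 true somatics + 25 rule-violating artifacts) are
filtered; exactly the 50 true somatics survive, and the TMB is the 27 kept
non-synonymous mutations.

```r
# copy number: select SNPs, correct GC bias, compute and smooth LRR
sim <- simulate_depth_profile(cfg)
track <- sim$sites |>
  select_informative_snps(sim$db_positions) |>
  gc_adjust_depths() |>
  compute_lrr() |>
  smooth_lrr()
genes <- tibble::tibble(gene = "B2M_like", chrom = "chr3",
                        start = 24e6, end = 26e6)
call_gene_status(track, genes)
#>   gene     chrom    start      end n_sites mean_rep_lrr status
#> 1 B2M_like chr3  24000000 26000000     111        -4.40 homozygous_loss
```

The interval sits inside a simulated two-copy deletion: its mean
representative LRR (−4.40, far below the −1 homozygous-loss threshold)
flags complete loss — the situation of an antigen-presentation gene deleted
in an ICI-resistant tumor.

```r
# cohort: ROC cut-off, stratification, log-rank
cohort <- simulate_cohort(cfg)
cohort$pf6 <- pfs_landmark_outcome(cohort)       # progression-free at 6 mo
cut <- roc_cutoff(cohort, cd8_count, pf6)
glance(cut)
#>   cutoff youden_j   auc     n direction
#> 1   97.6    0.382 0.727   121 >=
strat <- stratify(cohort, cd8_cutoff = cut$cutoff)
glance(logrank_test(strat, pfs_months, pfs_event, stratum))
#>   chi_square    df   p_value     n
#> 1       25.7     3 0.0000111   144
```

The CD8 cut-off maximizing Youden's J is 97.6 cells/field (J = 0.38,
AUC = 0.73), and the four CD8 × CD155 strata separate strongly on PFS
(log-rank χ² = 25.7, 3 df) — the simulated cohort encodes the protective
CD8-high/CD155-low stratum by construction.

```r
fisher_exact_2x2(19, 44, 22, 59)
#>   odds_ratio p_value   n
#> 1       1.16   0.713 144
```

Result objects support `tidy()`, `glance()` and `autoplot()`
(`autoplot(cut)` draws the ROC curve; `plot_lrr_track(track)` the genome
track; `plot_km(strat, pfs_months, pfs_event, stratum)` the survival
curves).

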