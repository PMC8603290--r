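---
title: "Methods behind oncoprofile: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind oncoprofile: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oncoprofile)
```

`oncoprofile` bundles four analysis stages — somatic variant filtering with
tumor mutation burden (TMB), tumor/normal log-R-ratio (LRR) copy-number
calling, variance-stabilized expression analysis, and immunotherapy-cohort
biomarker statistics — together with a ground-truth synthetic-data
generator. This vignette documents the models, the tunable parameters and
their defaults, the numerical conventions, and the choices made where the
design was genuinely open.

## The synthetic-data generator

The generator exists because paired tumor/normal sequencing data with
clinical annotation are access-restricted almost everywhere; it produces
inputs with *known truth* so every downstream stage can be scored exactly.

**Depth model.** Normal depth at SNP site $i$ is negative binomial,
$n_i \sim \mathrm{NB}(\mu = D\,g(gc_i),\ \text{size} = \phi)$, and tumor
depth scales with the local copy number $c_i$ and purity $p$:
$\mu_t = D\,g(gc_i)\,(p\,c_i^*/2 + (1-p))$. The negative binomial is the
conventional overdispersed model for hybrid-capture coverage; $\phi$
(`nb_dispersion`, default 10) gives a coefficient of variation of roughly
$\sqrt{1/\mu + 1/\phi} \approx 0.33$ at the default mean depth $D = 100$
reads — typical of exome data. Purity defaults to 1 because the profiles
emulate clonal cell lines.

**GC bias.** A multiplicative smooth bias
$g(gc) = 1 + a \sin(2\pi\,gc)$ with amplitude $a$
(`gc_bias_amplitude`, default 0.3). GC fractions are drawn from
$\mathrm{Beta}(20, 20)$, concentrating mass in $(0.25, 0.75)$ where $g$ is
strictly decreasing — a monotone confound, as seen in real capture data,
strong enough that raw depth and GC correlate (|Spearman ρ| > 0.2 at the
default amplitude; the test suite asserts this), giving the correction
stage real signal to remove.

**Homozygous deletions.** A $c = 0$ segment at purity 1 would have zero
expected tumor depth, and every site in it would be dropped before the LRR
stage — no homozygous-loss call could ever be made. Real deletions retain a
residual depth from mismapped and contaminating reads, so the generator
floors the copy number at `min_copy_eps` (default 0.1 copies), and the
truth LRR is $\log_2(\max(c, \varepsilon)/2)$ throughout.

**Default copy-number landscape.** Three synthetic chromosomes with
segments of copy number 0–4, each tens of megabases long (so 1 Mb
smoothing windows sit inside segments) and ~60% of sites diploid (so
genome-wide median centering anchors at $c = 2$).

**Variant calls.** True somatics are built to pass every keep-condition and
be reported by ≥ 2 of 3 simulated callers; for each discard rule a
configured number of artifacts violates *exactly that one rule*, which is
what makes per-rule truth recovery a meaningful test. The default artifact
rule set is the five read-evidence rules; the consensus rule can be added
via `artifact_rules`.

**Expression.** Counts are NB with lognormal baseline means
($\log\text{-mean} = \log 100$, sdlog 1); `n_shifted_genes` genes gain
`shift_log2fc` log2 units in group B. **Cohort.** CD8 counts are
Gamma(2.2, scale 55) (right-skewed, mean ≈ 121 cells per 0.25 mm² field);
CD155 scores are ordinal 0–3; PFS is exponential with baseline median 6
months times the stratum hazard ratio; censoring is a competing exponential
with its rate set so each patient is censored first with probability
exactly `censoring_rate` (so `censoring_rate = 0` observes every event).
The defaults (n = 144, a protective CD8-high/CD155-low stratum with hazard
ratio 0.35) encode a cohort in which high T-cell infiltration predicts
benefit unless the inhibitory ligand is high.

What the generator does **not** emulate: read-level artifacts (FASTQ,
alignment), subclonal structure, tumor-in-normal contamination,
copy-number-driven expression changes, correlated censoring, or
inter-marker correlation beyond the hazard model. Tests passing on this
generator demonstrate that the *algorithms* recover what the generative
model puts in — not that the defaults reproduce any particular dataset.

A single `seed` fans out to fixed per-generator child seeds, so each
generator is independently reproducible; equal seeds give byte-identical
outputs.

## Variant filtering

All thresholds carry the strict-inequality semantics of their definitions:
depth < 20 discards (19 fails, 20 passes); VAF < 0.05 discards (VAF = 0.05
passes); germline mutant reads > 2 discard (2 passes). "Single strand" is
operationalized as zero variant reads on exactly one strand with ≥ 1 on
the other — no proportional strand-bias statistic is applied, because none
is defined for this rule set. Population-database membership is a boolean
(no frequency threshold), and the in-house exclusion list is a
user-supplied blacklist keyed by (chrom, pos, ref, alt).

The consensus rule is majority voting (≥ 2 of 3 callers) by default;
`min_callers = 1` gives the union and `3` the intersection. On caller
disagreement, read-count evidence comes from a fixed precedence order
(default: list order), recorded per variant in `evidence_source`.
"Total read number" is interpreted as *tumor* depth. TMB counts kept
non-synonymous mutations; kept synonymous ones stay in the tables but not
in the count.

## Copy-number LRR

Positions are 1-based inclusive internally; BED input is converted from
0-based half-open exactly at the boundary (`read_bed_intervals()`).

**GC adjustment** is binned median-ratio normalization: 1%-wide GC bins
(`bin_width = 0.01`), each sample's depths multiplied by
global-median / bin-median. The estimator choice is deliberately
assumption-light — bin medians are robust to copy-number outliers within a
bin, and require no smoothness tuning. Bins under `min_bin_sites = 20` are
merged with the nearest populated neighbor; without merging, a singleton
bin would force its own depth to the global median and silently erase
signal. Adjustment is independent per sample, which doubles as throughput
normalization up to a constant.

**LRR** is $\log_2(t_i/n_i)$ on adjusted depths. Sites with a zero
adjusted depth in either sample are dropped with a reported count — the
track never contains infinities. `center_median = TRUE` (default)
subtracts a constant so the genome-wide median is 0, standing in for any
residual throughput scaling; the documented caveat is that genome-wide
aneuploidy shifts this baseline, as it does for every median-centered
copy-number method.

**Smoothing** replaces each site's LRR by the median over a 1 Mb window
centered at it (`window_bp = 1e6`, base-pair based as stated, not
site-count based). Windows truncate at chromosome ends (no mirroring) and
never cross chromosomes; median ties use the standard midpoint rule. The
implementation is checked for exact equality against a naive per-site
recomputation in the test suite.

**Gene calls** threshold the mean representative LRR over in-gene sites at
−1.0 / −0.3 / +0.3 (homozygous loss / loss / gain) — conventional values
for purity-1 data, exposed as arguments since no canonical standard
exists. Calls require ≥ 5 sites (`min_sites`); fewer gives a missing
status rather than a noisy one.

## Expression

The `vst_like` transform is median-of-ratios size factors (genes with any
zero excluded from the median) followed by $\log_2(x/s_j + 1)$. It is a
surrogate in spirit: downstream uses (SD ranking, PCA) need approximate
variance stabilization, not bit-compatibility with any dispersion-fitted
transform, and the tag says so. One algebraic subtlety: doubling one
sample's counts doubles its size factor only *relative to* the others —
the geometric-mean reference moves too, so all normalized counts pick up a
common factor $2^{1/n}$; the test suite asserts these exact invariants.

Variable-gene selection ranks by across-sample SD with a deterministic
tie-break on the gene identifier; `k` defaults to 10,000. PCA centers
genes but does not scale them to unit variance — scaling would undo the
variance-based selection. Signature scores are per-sample means of
genewise z-scores over the set∩matrix genes (zero-variance genes
contribute 0); this is a coordinate up/down summary, not an enrichment
test with a null model, and is documented as such.

## Cohort statistics

**Landmark outcome.** The ROC outcome is "progression-free at 6 months".
Patients censored before 6 months without progression are excluded by
default — counting an unobserved outcome either way would bias the cut-off
— with `censored_before = "non_progressor"` available for sensitivity
analysis.

**Cut-off selection** maximizes Youden's J = sensitivity + specificity − 1
over the observed marker values, ties broken toward the smaller cut-off
(deterministic, and favors inclusiveness of the test-positive group).
Youden's J is the standard criterion when a ROC-derived threshold is
reported without further detail. The ordinal CD155 score is scanned
directly, not pre-dichotomized.

**Stratification** uses ≥ for CD8 (a count equal to the cut-off is high)
and the 0–1 / 2–3 split for CD155.

**Tests.** Fisher's 2×2 p-value uses the minimum-likelihood two-sided
convention (`stats::fisher.test`); the reported odds ratio is the sample
$ad/bc$, not the conditional MLE. A zero margin returns p = 1 by
convention with a message. Kaplan–Meier and log-rank computations are
delegated to the `survival` package behind tidy interfaces, and are
cross-checked in the tests against hand-computed product-limit values and
the empirical survival function; pairwise log-rank follow-up applies
Bonferroni over the pairs. The paired pre/post comparison is a paired
t-test; zero-variance differences with nonzero mean report the limiting
p = 0 with a warning rather than failing.

Survival times are validated non-negative at the I/O boundary
(`read_cohort()`), with time measured from ICI initiation.

## Problem sizes and determinism

The shipped test and acceptance runs use sizes chosen to make Monte-Carlo
error small relative to the asserted tolerances while staying desk-scale:
10,000 SNP sites for segment-recovery and GC-removal checks (segment-mean
standard errors ≈ 0.02 LRR), 500 null cohorts of n = 144 for log-rank
type-I calibration, 100 replicate expression matrices (500 genes × 8
samples) for signature ranking, and ≤ 2,000-site tracks for the exact
window-median oracle. All randomness flows from a single seed through
fixed child-seed streams.

## Known limitations

No formal segmentation (CBS/HMM), no B-allele-frequency modelling, no
purity/ploidy estimation — the LRR caller assumes high purity and reads
copy number off thresholded window medians. The expression stage does no
differential testing. Cox modelling is deliberately out of scope. The
Fisher odds ratio is unconditioned; for small tables it differs from the
conditional MLE that `fisher.test` prints.
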