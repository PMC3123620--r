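# mirct

Derivation and validation of miRNA expression signatures from **paired
qPCR-array Ct data** — the setting where each case contributes a malignant
sample and an adjacent-normal sample, expression is measured as
cycle-threshold (Ct) values for hundreds of miRNAs, and the goal is a small
signature that separates the two tissue classes and *generalizes* to unseen
samples.

Because Ct falls as template abundance rises, higher expression means
*lower* Ct; the whole package encodes up-regulation as a Ct decrease.

## What it does

For a cohort of paired samples (features × samples Ct matrix `M`,
annotation table with case ids and tissue classes):

1. **Quantile normalization** across arrays: every sample's Ct
   distribution is forced onto the mean of order statistics
   $\bar q_{(i)} = \frac{1}{S}\sum_s q^{(s)}_{(i)}$, removing per-array
   additive offsets exactly while preserving within-sample ranks; missing
   ("Undetermined") wells are never imputed.
2. **Paired differential expression**: per feature, within-case differences
   $d_c = \mathrm{Ct}_{c,\mathrm{mal}} - \mathrm{Ct}_{c,\mathrm{nrm}}$ are
   tested with the paired Student's t statistic
   $t = \bar d / (s_d / \sqrt{n})$ (two-sided, $n-1$ df) and the Wilcoxon
   signed-rank test (exact for $n \le 25$ without ties), with
   Benjamini–Hochberg FDR adjustment over all testable features.
3. **Signature selection** at strict thresholds (defaults $p < 10^{-4}$ and
   $p < 10^{-5}$), ordered by p with deterministic tie-breaks.
4. **Clustering as a classifier**: Euclidean distances on the signature,
   UPGMA (average-linkage) clustering, a k-cluster cut, and majority-vote
   scoring — misplaced samples are those in a cluster dominated by the
   opposite tissue class.
5. **Cross-validated generalization**: repeatedly re-select the signature
   on 14 randomly drawn training pairs, cluster only the 10 held-out
   samples on it (k = 3), and aggregate misplacement counts into an average
   error rate and per-feature selection frequencies; a permuted-label run
   provides the null.
6. **PCA subgroup discovery**: a descending p-threshold sweep (one-way
   F-test against e.g. Gleason score) over the malignant samples, with
   PCA + seeded k-means concordance scoring at each threshold.

A first-class **synthetic-data generator** (`simulation_config()`,
`generate_paired_dataset()`, `generate_null_dataset()`,
`generate_gleason_dataset()`) emulates the paired 19-case, 667-miRNA Ct
structure — case random effects, array offsets, detection-ceiling
censoring, missing wells, planted DE and subgroup effects — so every stage
runs and is tested without laboratory data.

## Worked example

```r
library(mirct)
cfg <- simulation_config(gleason_profile = gleason_profile(
  scores = c(6, 7, 9, 10), n_features = 16, effect_ct = 4), seed = 42)
res <- run_pipeline(sim_config = cfg, seed = 42)
```

```
simulated cohort: 667 miRNAs x 38 samples
0 sample(s) excluded; 19 complete pairs enter the paired analyses
quantile normalization applied (1256 missing wells untouched)
differential expression: 13 miRNAs at p < 1e-04, 10 at p < 1e-05; Wilcoxon agrees on 11 of the 13 t-test calls
full-cohort clustering (loose signature, k = 2): 0 of 38 samples misplaced
full-cohort clustering (strict signature, k = 2): 0 of 38 samples misplaced
cross-validation: average error rate 0.0% over 15 repetitions (0 failed)
permuted-label null: 13 of 15 repetitions produced no signature
subgroup sweep: 35 miRNAs at p < 0.02 -> 0 of 19 malignant samples misplaced vs Gleason score
```

Reading this: the cohort carries 9 planted differential miRNAs (2-cycle
shifts); the paired t-test finds 13 miRNAs at the permissive and 10 at the
stringent threshold (the planted nine plus borderline false positives, as
expected at these thresholds over 667 tests). Both signatures separate the
38 samples perfectly at a 2-cluster cut. Cross-validation re-selects a
signature 15 times on 14 training pairs and never misplaces a held-out
sample, while the permuted-label null produces no usable signature in 13 of
15 repetitions — the separation is signal, not overfitting. The subgroup
sweep recovers the planted four-level Gleason structure with zero misplaced
malignant samples.

Per-feature stability across the 15 repetitions:

```r
head(res$cv$selection_frequency)
#>   feature_id times_selected frequency
#> 1   miR-0049             15         1
#> 2   miR-0074             15         1
#> ...
```

File-based cohorts work the same way
(`run_pipeline(ct = "ct.csv", annotation = "annotation.csv",
exclude = "s11M", ...)`), and a thin command-line wrapper lives at
`inst/scripts/run_pipeline.R`.

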