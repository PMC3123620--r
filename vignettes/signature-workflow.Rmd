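---
title: "Deriving and validating miRNA signatures from paired qPCR-array Ct data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deriving and validating miRNA signatures from paired qPCR-array Ct data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

TaqMan-style qPCR array cards measure hundreds of miRNAs per sample as
cycle-threshold (Ct) values: the cycle at which amplified signal crosses a
fixed threshold. Ct is inversely related to template abundance — one cycle
less means roughly twice as much starting material — so *lower Ct means
higher expression*. In a paired tumor study, each case contributes a
malignant sample and an adjacent-normal sample, and the scientific question
is whether a small set of miRNAs ("an expression signature") consistently
separates the two tissue classes, and whether that separation generalizes
beyond the samples used to select it.

`mirct` implements that workflow end to end:

1. **Ingestion** of wide Ct tables (features × samples; `"Undetermined"`
   wells are missing) and a sample annotation table, with sample-level
   exclusions that keep the pairing bookkeeping honest.
2. **Quantile normalization** of Ct values across arrays.
3. **Paired differential expression** (Student's t and Wilcoxon signed-rank
   on within-case ΔCt) with Benjamini–Hochberg correction.
4. **Signature selection** at nested significance thresholds.
5. **Clustering as a classifier**: Euclidean distance on the signature,
   average-linkage (UPGMA) clustering, a k-cluster cut, and majority-vote
   scoring of misplaced samples.
6. **Cross-validated generalization** with a permuted-label null.
7. **PCA subgroup discovery** among the malignant samples.

A synthetic-data generator reproduces the statistical structure every stage
assumes, so the whole pipeline is testable without laboratory data.

## The data model and its assumptions

For feature $f$ in sample $s$ of case $c$ the generator — and, implicitly,
the analysis — assumes

$$
\mathrm{Ct}_{fs} = \mu_f + b_c + a_s + \delta_f \,[s\ \text{malignant}] +
\gamma_{f,g(c)} \,[s\ \text{malignant}] + \varepsilon_{fs},
$$

with $\mu_f$ a per-feature baseline (uniform on 20–35 cycles by default),
$b_c \sim N(0, \sigma_b^2)$ a between-case random effect shared by both
members of a pair, $a_s \sim N(0, \sigma_a^2)$ a per-array technical offset,
$\delta_f$ a fixed Ct shift carried by the truly differential features
(up-regulation is a *negative* $\delta$, per the Ct convention),
$\gamma_{f,g}$ optional Gleason-score-dependent shifts on a second feature
set, and $\varepsilon_{fs} \sim N(0, \sigma_\varepsilon^2)$ well noise.
Wells above the 40-cycle detection ceiling are censored to missing — the
qPCR machine would report them "Undetermined" — and further wells are masked
missing completely at random.

The paired t-test is exact under this model because the within-case
difference $d_f = \mathrm{Ct}_{f,\mathrm{mal}} - \mathrm{Ct}_{f,\mathrm{nrm}}$
cancels $\mu_f$ and $b_c$; the array offsets $a_s$ do *not* cancel (each
member of a pair sits on its own array), which is exactly why quantile
normalization has a falsifiable job: with offsets planted and normalization
disabled, differential features are unrecoverable, and with normalization
enabled they are (this ablation is a test).

## Defaults and why

| parameter | default | rationale |
|---|---|---|
| `n_cases` | 19 | an analyzable paired cohort of ~20 cases after one technical exclusion |
| `n_features` | 667 | unique miRNAs on a two-card TaqMan v2.0 array set |
| `n_de`, `effect_ct` | 9, 2 cycles | a small signature of 4-fold shifts, the regime the method targets |
| `case_sd` | 1 cycle | between-case biology comparable to, but larger than, well noise |
| `noise_sd` | 0.5 cycles | typical well-level reproducibility of array qPCR |
| `array_offset_sd` | 1 cycle | loading/efficiency differences between arrays, removable by normalization |
| `missing_rate` | 0.05 | a low MCAR rate on top of ceiling censoring |
| `ct_max` | 40 | the standard 40-cycle protocol |

The published study reports neither its missing-well fraction nor its
dynamic range, so `missing_rate` and `baseline_ct_range` are realistic
choices for FFPE-derived array qPCR rather than estimates of any particular
dataset.

What the generator does **not** emulate: TaqMan chemistry and
pre-amplification bias, card A/B panel structure, replicate wells,
non-Gaussian heavy-tailed noise, correlated miRNA families, and
informative (expression-dependent) missingness beyond the hard ceiling.
Green tests on synthetic data therefore demonstrate the pipeline's
statistical correctness under its stated model, not robustness to every
artifact of real FFPE material.

## Numerical and procedural choices

**Quantile normalization.** The reference distribution is the across-sample
mean of order statistics; for complete samples the post-normalization
multisets are *exactly* equal across samples (asserted to machine precision
in tests). Missing wells are never imputed: a sample with $n_j$ observed
wells is mapped through the reference quantile function at rank positions
$k/(n_j+1)$, linearly interpolated, which reduces to the exact
mean-of-order-statistics rule when no wells are missing. Tied values
receive the mean of the reference values at their tied ranks, so ties stay
tied. Normalization acts on Ct directly, not on ΔCt or fold changes,
because the downstream tests run on normalized Ct.

**Paired tests.** Features with fewer than two usable pairs, or all-zero
differences, are flagged untestable (`p = NA`) rather than raising; identical
nonzero differences (sd = 0) give `p = 0` with a degeneracy flag, avoiding
silent NaN propagation. The Wilcoxon test drops zero differences, uses the
exact signed-rank distribution for $n \le 25$ without ties, and a
continuity- and tie-corrected normal approximation otherwise. BH correction
runs over all testable features on the array (m ≈ 667), not only the
reported hits, since FDR depends on the full family of tests.

**Signatures.** Selection is strict (`p < alpha`), ordered by ascending p
with a lexicographic feature-id tie-break, so signatures are reproducible
and nested across thresholds by construction.

**Clustering.** Distances are Euclidean over the signature features; when a
sample pair shares only a subset of non-missing features the sum of squares
is rescaled by $n_{\text{total}}/n_{\text{used}}$, and a pair with *no*
shared feature is assigned the largest observed distance (the uninformative
sample becomes an outlier rather than a crash). Average linkage is UPGMA —
the unweighted mean of all cross-cluster pairwise distances — which is
verified against an exhaustive naive implementation on random instances.
Tied merge candidates are resolved by the clustering routine's internal
order; on continuous expression data exact ties have probability zero, and
classifications depend only on merges and cuts, not on leaf ordering.
Full-cohort evaluations cut at k = 2 (two tissue classes); the
cross-validation cuts at k = 3, reserving one cluster for the outlier that
small held-out sets typically contain. A within-cluster majority tie is
scored conservatively against the global majority class, deterministically.

**Cross-validation.** Training cases are drawn at the case level so pairs
stay intact (14 of 19 by default, leaving 10 held-out samples); signature
selection sees only training samples — a leakage test perturbs held-out
columns and asserts the selected signature is unchanged. Repeats whose
signature is empty are recorded as failed and excluded from the error-rate
mean but kept in selection-frequency denominators. One global seed drives a
per-repeat seed sequence, so reports are exactly reproducible.

**Permutation null.** The published control says only that class labels
were randomly permuted. The default scheme swaps the normal/malignant
labels within each case with probability ½, because the paired t-test
requires one label of each kind per case to remain computable; an
unrestricted label shuffle is available (`permutation = "free"`), under
which cases drawing two identical labels simply drop out of the paired
test.

**Subgroup sweep.** The "gradually decrease the p-value until groups
emerge" procedure needs a per-feature p-value against the grouping
variable; a one-way ANOVA F-test is the default statistic (the only reading
under which a fixed threshold yields a fixed feature count), and the
statistic is pluggable for variance-style filters. At each threshold the
kept features are standardized (centered, unit variance — the convention of
the PCA tool the procedure emulates), projected onto the top two principal
components, and partitioned by seeded k-means (50 restarts) into as many
groups as the grouping variable has levels; concordance is majority-vote
misplacement. The sweep reports the *largest* threshold attaining the best
concordance — the first stopping point of a descending search — and returns
the full trace, because the F-filter's selection bias means permissive
thresholds admit chance-significant features: on null data the sweep can
reach apparently good concordance, and the honest baseline is the same
sweep on permuted labels (this equivalence is a test). PCA loading signs
are canonicalized (largest-magnitude loading positive); missing wells are
mean-imputed for the projection only.

## Scale of the validation suite

The test suite and the acceptance script run the full 667-feature, 19-pair
pipeline; oracle comparisons (t, Wilcoxon, BH, UPGMA, tree cuts) use 100
random small instances each; signature-recovery and type-I checks use 100
simulated cohorts; the Gleason-subgroup recovery check uses 11 cohorts with
four score levels at a 4-cycle effect and 0.3-cycle noise. These sizes give
stable pass/fail behavior at interactive runtimes.

## Known limitations

- The printed adjusted p-values of the study this workflow emulates are not
  monotone in its raw p-values, which is impossible under plain BH; adjusted
  values from `bh_adjust()` are therefore not expected to reproduce that
  table, only the BH definition.
- Whether the study's exclusion of "sample 11" removed one tissue or both
  is ambiguous; `exclude_samples()` supports both modes and flags orphaned
  partners rather than silently dropping them.
- The clustering classifier has no notion of uncertainty: a sample is
  misplaced or not. Error rates on 10-sample held-out sets are accordingly
  coarse (multiples of 10%).
- With ~19 pairs the t-test's normality assumption is untested at the
  per-feature level; the Wilcoxon comparison (`compare_tests()`) is the
  built-in sensitivity check.
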