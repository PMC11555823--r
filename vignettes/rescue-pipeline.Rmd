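---
title: "Quantifying ASO dose-dependent rescue of a transcriptomic disease signature"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying ASO dose-dependent rescue of a transcriptomic disease signature}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

A gene-dosage disorder — here, a duplication of a dosage-sensitive gene —
dysregulates hundreds to thousands of downstream transcripts. An antisense
oligonucleotide (ASO) that degrades the target transcript lowers its dosage
and should, if dosage is really the driver, pull that disease signature back
toward the unaffected state. `asorescue` implements the computational side
of such an experiment: bulk RNA-seq count matrices from affected and
unaffected cell lines, treated with nothing (naive), a non-targeting
scramble ASO, or targeting ASO sequences at several doses, are normalized,
tested for differential expression, reduced to a signature, compared against
an external loss-of-function dataset, and scored for rescue.

The unit of biology behind each sample is a cell line derived from one
individual; four individuals per genotype is typical. That matters
statistically: genotype and individual are confounded, and the package's
design (and simulator) treats it explicitly rather than pretending samples
are exchangeable.

## Differential expression model

Counts are assumed negative binomial, `Var(K) = mu + alpha * mu^2`.
The pipeline deliberately implements a *simplified* NB Wald analysis rather
than replicating any specific tool:

1. **Size factors** are median-of-ratios: per sample, the median over
   always-positive genes of the ratio of its count to the gene's geometric
   mean across samples; the median is taken on the log scale (so even gene
   counts interpolate geometrically) and factors are rescaled to geometric
   mean 1, making "two identical samples have factor 1" exact. If no gene is
   positive everywhere, genes positive in at least 90% of samples are used
   with geometric means over their positive entries (`fallback_fraction`,
   flagged on the result).
2. **Dispersion** is method-of-moments from pooled within-group residual
   variance of normalized counts, `alpha = (s^2 - mu)/mu^2`, floored at
   1e-8, then shrunk toward a fitted `a0 + a1/mu` trend with weight
   `prior_df = 20` pseudo-observations against the gene's residual degrees
   of freedom. The trend is exactly the simulator's dispersion family, so on
   simulated data the shrinkage target is well-specified; on real data it is
   the standard asymptotic-plus-Poisson approximation.
3. **The Wald statistic** uses group means of normalized counts with a
   pseudocount of 0.5 (finiteness at zeros):
   `log2FC = log2(mu1 + 0.5) - log2(mu0 + 0.5)`, standard error by the delta
   method from the NB variance of each group mean, two-sided normal p.
   Genes with mean normalized count below `min_mean = 1` across the
   contrast's samples are reported with `NA` p-values and excluded from the
   Benjamini–Hochberg denominator. With the shrunk dispersion the test is
   well calibrated at the study's sample sizes: on a simulated 5000-gene
   null at 8-vs-7 the test suite requires (and observes) a raw
   `p < 0.05` fraction inside [0.03, 0.07] and a Kolmogorov–Smirnov distance
   from uniform below 0.05.
4. **Cell-line covariate.** For contrasts where every involved line has
   samples on both sides (the targeting-vs-scramble contrasts), per-line
   centering of `log2(normalized + 0.5)` absorbs baseline line differences
   before the group comparison. For the disease-signature contrast the lines
   are nested in genotype, centering would remove the effect of interest,
   and it is skipped automatically; line-to-line variability then simply
   inflates the dispersion estimate (and mutes p-values — the realistic
   cost of a four-individuals-per-genotype design). A full per-line GLM is
   intentionally out of scope.

Contrasts are grouped into **normalization batches**: size factors are
computed once per batch over the union of its contrasts' samples.
`default_contrast_scheme()` reproduces the study layout — two
scramble-vs-naive negative controls (one per genotype, each its own batch),
one disease-signature contrast pooling naive and scramble controls (its own
batch), and eight targeting-vs-scramble contrasts (per genotype x sequence x
dose, normalized per genotype) — five batches, eleven contrasts.

## The synthetic-data generator

`simulate_dataset()` draws `K ~ NB(mu, alpha)` with

```
mu[g, s] = library[s] * baseline[g] * 2^(genotype + line + treatment) / normalizer
alpha(mu) = 0.02 + 1.5 / mu
```

- `baseline[g]` is log2-normal (`baseline_log2_mean = 5`, sd 2), giving the
  usual right-skewed abundance distribution; libraries are uniform on
  8–12 million reads.
- The **genotype effect** applies +/-`effect_size_log2` (default 1, with
  log-normal per-gene jitter, `effect_sdlog = 0.25`) to `n_dosage_up = 500`
  up and `n_dosage_down = 1000` down genes in the affected genotype — a
  two-thirds-down split of a roughly 1500-gene signature. The target gene
  itself is a `dosage_up` gene with `target_lfc = 1` (the 2-fold effect of a
  duplication) and occupies one slot of the up budget.
- **Cell-line effects** have two parts: gene-specific independent draws
  (`line_sd_log2 = 0.15`) and a per-line scalar on one shared gene-loading
  axis (`line_shared_sd_log2 = 0.3`). The shared axis is what makes
  replicate samples of one individual cluster together and concentrates
  individual-of-origin variance on a single principal axis, as seen in real
  cohorts. It also means genotype differences are partially confounded with
  the individuals drawn — small spurious between-genotype differences are a
  *feature* of the emulation, not a bug.
- **Treatment effects**: scramble arms are exactly null. Targeting arms
  multiply the target gene by `knockdown_per_dose` (defaults 0.65 / 0.5 /
  0.35 of residual expression at 2.2 / 6.6 / 20 uM — a dose-response
  anchored at 35% residual at the top dose), and move a `rescue_fraction`
  (default 0.5) of signature genes by `-rescue_strength * effect` (default
  halfway back) in the affected genotype and by `-aberrant_strength *
  effect` (default 0.5) in the unaffected genotype — the acute
  depletion response that pushes unaffected cells *past* their own baseline.
  The aberrant magnitude is a free parameter; no published value pins it.
- **Seeding** is counter-based: the master seed expands into fixed child
  streams (gene parameters, line effects, one stream per arm), so identical
  seeds are bit-identical and appending arms does not perturb earlier draws.

What the generator does **not** model: per-gene GC/length biases, outlier
counts (no Cook's-style handling exists downstream either), batch effects
beyond the line axes, single-cell heterogeneity of the differentiated
cultures, and any coupling between knockdown kinetics and time. Passing
tests on this generator therefore demonstrates internal statistical
correctness and parameter recovery, not robustness to every artefact of
real libraries.

`simulate_companion_lof()` emulates the loss-of-function companion study at
the DE-table level: each signature gene's effect is sign-inverted with
probability `inversion_fraction` (default 0.8) plus Gaussian noise
(`noise_sd = 0.3`), with a background of expressed null genes. At full
inversion and zero noise the correlation with the truth is exactly −1; the
defaults give r near −0.55 on the shared set.

## Rescue scoring

All three read-outs work on **pooled log2 CPM**: per-sample
`log2(CPM + 0.5)` averaged within named pools (mean of logs by default;
`average = "cpm"` gives log-of-mean instead — both are defensible readings
of "average counts per million", and the mean-of-logs default is symmetric
with the log-ratio definitions). The canonical pools are per-genotype
controls (naive + scramble together) and per-genotype per-sequence targeting
pools, averaging the 6.6 and 20 uM doses unless `pool_doses = FALSE`.

- **Sign-flip rescue** is purely qualitative, exactly the sign rule:
  baseline ratio `affected_control - unaffected_control`, treatment ratio
  `arm - affected_control`, rescued iff the signs are opposite. There is no
  magnitude threshold by default (`min_abs_treatment = 0`). For genes whose
  treatment response is pure noise the flip probability is 1/2, so an
  unresponsive signature scores ~50% — that symmetry point is the null
  reference, and the test suite checks it on a zero-responsiveness
  simulation. One caveat discovered while validating: signature genes that
  are *false positives* of the baseline contrast flip far more often than
  half, because their baseline sign is the same control-pool noise that
  enters the treatment ratio with opposite sign. Keeping the false-discovery
  rate controlled is what keeps the percent-rescued interpretable.
- **Rank patterns**: pooled expression over the four canonical groups
  (unaffected control, unaffected treated, affected control, affected
  treated) is ranked 1–4 per gene; exact ties break by that canonical column
  order (ties are measure-zero on real data). The distinct rank patterns (at
  most 24) are clustered hierarchically (Euclidean, average linkage) and
  genes inherit their pattern's cluster, making the clustering invariant to
  gene order. A cluster is dosage-consistent when the Spearman correlation
  between its mean rank vector and the nominal dosage order (treated
  unaffected < unaffected < treated affected < affected for up-genes;
  reversed for down) is at least 0.8 in absolute value — the threshold is
  configurable since no published value exists.
- **PC shift**: PCA of all samples on signature-gene log2 CPM. Each
  component is oriented so the affected-control group mean is non-negative,
  removing the arbitrary PCA sign and making repeated runs identical. Each
  sample's score on the tested component (default 2) is referenced to the
  mean of the untreated samples of its own cell line (leave-one-out for the
  untreated samples themselves); per genotype x sequence the treated deltas
  are averaged across doses and tested with Student's t — two-sample against
  the untreated deltas by default, one-sample against zero as an option,
  since the published description is ambiguous between the two. A treated
  sample with no untreated line-mate is an error, not a silent drop.

In the generator's geometry the disease axis (the signature-gene effect
direction) dominates the first principal component, and the treatment
displacement — rescue applied only to the responsive subset, plus the
aberrant response in unaffected lines — forms a second, partially orthogonal
axis. The component-2 shift test therefore has power in the
strong-responsiveness regime, which is the scenario the test suite uses for
detection; the halfway-rescue scenario is used for the rank-betweenness
property (treated-affected pools between the two genotype baselines for
responsive genes).

## Validation scenarios and problem sizes

The test suite validates each stage against independent oracles (exhaustive
hypergeometric summation, a literal BH step-up, direct median-of-ratios
recomputation, the DESeq2 size-factor estimator) and the whole pipeline
against the generator's ground truth. Scenario sizes were chosen so each
check's Monte-Carlo error is small relative to its acceptance band:
5000-gene nulls for calibration, 8000 genes with a 300/600 up/down split for
signature recovery, 3000–4000 genes with 2 replicates per line-arm for the
rescue and rank/PC scenarios.

Two scenario choices deserve explanation:

- The rescue-recovery scenarios ("strong responsiveness, low noise" and
  "pure noise") switch cell-line effects off. With them on, the
  individual-genotype confounding seeds the signature with false positives
  whose flip behaviour is biased (see above), which tests the design's
  limitation rather than the statistic. The confounded regime is exercised
  separately by the signature-recovery and clustering tests.
- The pure-noise scenario uses a direction-balanced signature (300/300).
  With a strongly skewed signature (2:1 down), median-of-ratios
  normalization retains a small compositional residue (~0.03 log2 on null
  genes — the mixture median shifts), which at high replication turns into
  direction-concentrated false positives. That is faithful behaviour of this
  normalization family under unbalanced differential expression, worth
  knowing about, but orthogonal to the 50%-symmetry property the scenario
  isolates.

## Numerical choices and degenerate inputs

- Dispersion floor 1e-8; size-factor convention geometric-mean-1; CPM
  pseudocount 1 by default in `cpm()` (log2 of a zero count is then exactly
  0), 0.5 in the fold-change and pooling paths for symmetry with the DE
  pseudocount.
- `benjamini_hochberg()` ignores `NA`s (they keep their positions, do not
  enter the denominator) and validates the [0, 1] range.
- Zero-variance genes in the heatmap z-score become all-zero rows rather
  than being dropped, keeping the matrix aligned with the signature.
- An empty signature is not an error: downstream stages report empty
  results and the pipeline says why it stopped.
- Dose labels are canonical strings ("6.6", "20") wherever they act as map
  keys, avoiding float-equality pitfalls.
- A Wald statistic with zero standard error and zero fold-change (identical
  all-zero groups) is defined as 0 with p = 1.

## Limitations

- The NB Wald analysis is an approximation by design: no independent
  filtering, no outlier detection, no fold-change shrinkage, no
  likelihood-ratio test. Exact numeric agreement with any published tool is
  a non-goal; calibration and sign/recovery behaviour are the correctness
  surface.
- With four individuals per genotype the disease-signature contrast cannot
  separate genotype from individual; the package reports what the design
  supports and the simulator reproduces the resulting false-positive
  behaviour rather than hiding it.
- Percent-rescued denominators are all signature genes with defined pooled
  values (not only genes expressed in the treated arms); the alternative is
  a one-line filter upstream if wanted.
- The ΔΔCt utility fixes amplification efficiency at 2 and supports a single
  housekeeping gene per call; efficiency-corrected and multi-gene
  normalization variants are out of scope.
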