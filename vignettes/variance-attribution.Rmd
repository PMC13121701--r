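---
title: "Attributing transcriptome variance to culture medium versus donor background"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Attributing transcriptome variance to culture medium versus donor background}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(medivar)
```

## The question

Primary cells — endothelial cells isolated from umbilical cords being the
canonical example — vary between experiments for two structurally different
reasons: the culture medium they are kept in, and the genetic background of
the donor they came from. When a lab observes that one line responds and
another does not, it matters greatly which of the two factors is driving the
difference. `medivar` implements a complete analysis path for a crossed
two-factor design (every donor line cultured in every medium, one array per
cell) that quantifies which factor dominates the expression profile, at three
levels: global sample structure, per-gene differential expression, and
function-level gene-set enrichment.

The package is built around a 3-donor × 4-medium, 12-sample single-replicate
design, but nothing in the code assumes those exact counts beyond requiring
at least two levels per factor and at least two replicate samples per
contrasted level.

## Data model

The central container is `IntensityExperiment`, a `SummarizedExperiment`
carrying one non-negative `intensity` assay (gene × sample fluorescence
values), a sample annotation with `donor`, `medium` and optionally `sex`,
and a gene annotation with `symbol`, `chromosome` and two control flags:
`hkg_candidate` (housekeeping reference candidates) and `negative_control`
(lineage-restricted genes not expected in the studied cell type). Validity
is enforced at construction: no missing values, unique identifiers, both
factors present.

## Pre-processing

The pipeline order is fixed and its gene counts telescope in the report:

1. **Housekeeping selection.** From the candidate list, the `k = 12` genes
   with the smallest standard deviation of *log2* intensity across samples
   are selected (`selectHousekeeping()`). The SD is taken on the log scale
   because all downstream analysis is log-scale and a log-scale ranking is
   invariant to overall probe brightness; ties break lexicographically so
   the selection is reproducible.
2. **Normalization.** Each sample is rescaled multiplicatively so its mean
   housekeeping intensity equals the grand mean of per-sample housekeeping
   means (`normalizeByHkg()`). Multiplicative scaling on the raw scale is
   the standard reference-gene convention, preserves non-negativity, and is
   idempotent — re-normalizing changes nothing.
3. **Detection limit.** All intensities of the negative-control genes,
   pooled over all samples, define the fluorescence floor; the limit is
   their 95th percentile (`detectionLimit()`), computed by linear
   interpolation between closest ranks (position `1 + (n-1)q`). The limit
   is computed on the *normalized* matrix — the filter is applied to
   normalized values, so limit and values must share a scale — but the
   raw-scale limit is recorded alongside it in the `PreprocessReport`, so
   either convention can be checked against an external dataset.
4. **Expression filter.** A gene is retained if it is strictly above the
   limit in ≥ 4 samples, above twice the limit in ≥ 2 samples, or above
   three times the limit in ≥ 1 sample (`filterExpressed()`). "Above" is
   strict: a value exactly at the threshold does not count. The filter is
   monotone — raising the limit can only remove genes.
5. **Sex-gene exclusion.** With donors of mixed sex, chromosome-Y genes and
   XIST are removed (`excludeSexGenes()`); genes lacking chromosome
   annotation are always retained rather than silently dropped. The
   exclusion is invertible (`invert = TRUE`) for the quality-control
   contrast in which exactly these genes should light up between male and
   female donors — a positive control the test suite exercises on
   simulated data.

## Differential expression

With one array per donor × medium cell there are no true replicates, so the
design "swaps" them: when two media are compared, the donor lines cultured
in each medium serve as replicates (n = 3 vs 3); when two donor lines are
compared, the four media serve as replicates (n = 4 vs 4). Each pairwise
contrast is therefore a two-group comparison, fitted by `fitContrast()`:

* `log2FC_g = mean(log2 x in A) − mean(log2 x in B)`
* pooled gene-wise variance `s_g²` with `d_g = n_A + n_B − 2` df
* moderated variance `s̃_g² = (d₀ s₀² + d_g s_g²) / (d₀ + d_g)`
* moderated `t_g = log2FC_g / (s̃_g √(1/n_A + 1/n_B))`, `d₀ + d_g` df.

The hyperparameters `(d₀, s₀²)` are estimated by moment matching on
`log s_g²` (`estimateModerationPrior()`): under the scaled
inverse-chi-square prior, `Var(log s²) = ψ′(d_g/2) + ψ′(d₀/2)` and the mean
involves the corresponding digamma terms, so both are solved in closed form
with an in-package Newton inversion of the trigamma function. When the
observed spread of `log s²` does not exceed its sampling spread, `d₀ = ∞`
and every gene is shrunk fully to `s₀²`. Setting `d₀ = 0` disables
moderation and reproduces the textbook pooled t exactly (verified to
1e-10 in the tests); the estimated-prior path is cross-checked against an
independent empirical-Bayes implementation (limma) in the test suite.

P-values are two-sided and Benjamini–Hochberg adjusted across all genes of
a contrast. Genes are classed volcano-style: **red** (|log2FC| ≥ 1 at
fold-change threshold 2 *and* adjusted p < 0.05), **green** (fold change
only), **blue** (significance only), **grey** (neither). Both boundaries
are deliberate: the fold-change condition is inclusive (≥), the
significance condition strict (<), so `adjP = 0.05` is not significant.
The fold-change condition reads the magnitude |log2FC|, covering up- and
down-regulation symmetrically.

Roll-ups follow: `collectDeSets()` unions red genes over the six media
contrasts and over the three donor contrasts (plus the combined union);
`pairwiseSummary()` reports mean ± sample SD of red counts per contrast so
the factors can be compared despite 6 vs 3 comparisons; `topFcSubset()`
takes the top 5% of each contrast's red genes by |log2FC| *per contrast and
then unions* — only that reading makes the subset size scale with the
number of contrasts; `topGenesTable()` lists each contrast's top-k genes
with ties broken by adjusted p, then gene id.

## Sample structure

* `zscoreLog()` standardizes each gene's log2 values (mean 0, sample SD 1;
  constant genes map to zero rows with a warning — they carry no
  between-sample information).
* `clusterSamples()` performs agglomerative clustering on Euclidean
  distances between sample columns with complete linkage. For a
  correlation-heatmap-style analysis, cluster the Spearman matrix itself
  (`clusterSamples(spearmanMatrix(x))`): that clusters samples on Euclidean
  distance between correlation rows rather than on `1 − r`, matching the
  convention of clustering the displayed matrix.
* `spearmanMatrix()` computes rank correlations between samples over the
  gene dimension with mid-ranks for ties. It is computed on raw values;
  because rank correlation is invariant to strictly monotone transforms,
  raw versus log input gives identical results. Positive semi-definiteness
  is *not* asserted — it is not guaranteed for Spearman matrices.
* `pcaSamples()` runs SVD-based PCA on the column-centered sample × gene
  matrix, reporting three components by default, per-gene importances
  (absolute loadings) and percent variance (R²) per component. The sign
  convention — each component's largest-magnitude loading is positive —
  removes the SVD sign ambiguity without changing any geometry.
* `groupingPurity()` turns "the samples cluster by medium" into a number:
  cut the dendrogram into k clusters (removing the k−1 tallest merges) and
  report the fraction of samples whose cluster's majority label matches
  their own. Purity 1.0 at `k = 4` by medium together with purity < 1 at
  `k = 3` by donor is the medium-dominant signature; the statistic is
  invariant to label renaming.

## Gene sets, ORA and preranked GSEA

Gene sets are consumed as GMT files (`readGmt()`/`writeGmt()`), or built
from annotation records by `filterAnnotations()`, which keeps only records
with direct experimental evidence codes (EXP, IDA, IPI, IMP, IGI, IEP) for
human protein-coding genes — one qualifying record suffices to keep a gene.
Typeset GO accessions with thousands separators are normalized
(`normalizeGoId()`). A shipped two-column resource maps the nine anchor GO
terms to the nine endothelial function categories used by
`categorizeTerms()`; unmapped terms are counted separately, never dropped.

`ora()` is a standard upper-tail hypergeometric over-representation test
with BH adjustment across sets; the background universe should be the
post-filter transcriptome, the defensible default the pipeline uses. Note
that this is a plain BH-corrected hypergeometric test, so term counts are
not comparable to web tools using multiple-testing schemes of their own.

The preranked GSEA is implemented from scratch:

* **Ranking** (`rankMetric()`): per gene, mean raw expression in one medium
  across all donors divided by the overall mean across all samples. The
  raw ratio rather than its log is used — the two are rank-equivalent, and
  the ratio is what "average expression divided by overall average"
  denotes literally. Ties break by gene id so the list order is total.
* **Enrichment score** (`enrichmentScore()`): walking the list from top to
  bottom, hits add `|metric|^w / Σ|metric|^w` (weight `w = 1` by default,
  the classic weighted statistic; `w = 0` reduces the score exactly to a
  Kolmogorov–Smirnov statistic) and misses subtract `1/(N − N_hit)`. The
  ES is the walk's maximum deviation from zero, signed; a tie between the
  positive and negative extremes resolves positive.
* **Significance** (`gseaPreranked()`): the null distribution per set size
  comes from gene-label permutations — hit positions drawn uniformly
  without replacement, the only permutation scheme available to a
  single-replicate preranked design. `NES = ES / mean(|null ES| of the
  matching sign)` and the nominal p uses the add-one estimator
  `(1 + #{matching-sign nulls ≥ |ES|}) / (1 + #matching-sign)`, so p is
  never exactly zero and is bounded below by `1/(nperm+1)`. Sets with
  fewer than 10 matching-sign permutations are flagged unstable. The
  permutation evaluation uses an O(N_hit) closed form for the walk's
  extremes (positive extremes occur just after hits, negative just before),
  verified against the full walk in the tests.
* **FDR threshold** (`bhThreshold()`): across all set × medium nominal
  p-values of a run, the largest sorted `p_(i) ≤ i·α/m`; tests with
  `p ≤ threshold` pass. In a full 9-set × 4-media run this reproduces the
  "BH threshold across 36 tests" convention.

NES values are normalization-convention-dependent; implementations that
normalize differently will report different NES magnitudes for identical
enrichments, so NES values should be compared only within a run.

## The simulator: what it emulates and what it does not

`simulateExperiment()` generates log2 intensities as
`baseline_g + mediumEffect_{g,m} + donorEffect_{g,d} + noise`, exponentiates
and clips below at 1 (scanners report positive fluorescence). Effects are
drawn per gene per level from centered normals and re-centered across
levels, so the medium-versus-overall-average fold change is well defined;
only a configurable fraction of genes is affected per factor. Control
probes mirror their real counterparts: housekeeping candidates have no
effects and one fifth of the residual noise; negative controls fluctuate
multiplicatively around `floorLevel` with log2 SD 0.1 (non-degenerate, so
percentiles are meaningful); Y-linked genes sit at the floor in
female-donor samples and XIST at the floor in male-donor samples.

Default conditions (chosen once, as the study conditions the package
emulates): 3 donors (one male, two female) × 4 media × 1 replicate;
`baselineMean = 8`, `baselineSd = 2` (log2 units, a realistic microarray
dynamic range); `sigmaNoise = 0.25` log2 units, the scale implied by a
median technical coefficient of variation near 18% (CV/ln 2 ≈ 0.26);
`floorLevel = 10`; 14 housekeeping candidates, 12 negative controls, 10
Y-linked genes plus XIST; 20% of genes medium-affected and 10%
donor-affected with effect SDs 0.5 and 0.25. Desk-scale gene counts are
used throughout the test suite (300–2,000 genes for structural checks,
10,000 for type-I-error calibration, 20 seeds for stochastic claims);
these sizes give stable statistics while keeping the suite quick to run.

What the simulator does **not** model: two-channel dye effects and
dye swaps, probe-level summarization (input is gene-level), spatial array
artifacts, intensity-dependent (trended) variance, and correlated gene
modules. Consequently, passing tests demonstrate that the algorithms
recover planted additive structure under log-normal noise — they do not
certify behavior under array-specific artifacts that real data may carry.

## Numerical conventions and degenerate inputs

* Logs are base 2 everywhere; the base cancels in z-scores.
* Percentiles interpolate linearly between closest ranks (type 7).
* A contrast of two identical groups yields t = 0 and p = 1; a gene with
  zero moderated variance and zero fold change likewise, while zero
  variance with non-zero fold change gives p = 0.
* Prior estimation drops zero-variance genes with a warning and errors
  only if *all* genes are degenerate.
* Constant sample columns make Spearman correlations undefined; they error
  by default and are kept as `NA` only on request.
* `pcaSamples()` reduces the component count to the matrix rank with a
  warning rather than fabricating null components.
* All stochastic stages are seeded; the pipeline seed fans out
  deterministically to the per-medium GSEA runs, so a `runAll()` with the
  same configuration reproduces every output bit-identically.

## Limitations

The replicate-swapping design conflates interaction effects with noise:
a gene responding to a medium in only one donor inflates the residual
variance of the media contrasts instead of appearing as a signal. The
moderated-t hyperparameters come from one moment-matching convention;
other empirical-Bayes fits (e.g. with robust or trended options) will
differ slightly in borderline genes. ORA here is a plain hypergeometric
test against a user-chosen background and inherits all the usual caveats
of annotation completeness.
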