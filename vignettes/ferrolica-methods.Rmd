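---
title: "Methods: ferroptosis, immune cytolytic activity and OSS scoring"
author: "ferrolica"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ferroptosis, immune cytolytic activity and OSS scoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

## The analysis in one paragraph

`ferrolica` compares ferroptosis-related gene (FRG) activity and local
immune cytolytic activity (LICA) between two tumor cohorts — a basal cell
carcinoma (BCC)-like and a squamous cell carcinoma (SCC)-like group —
from bulk expression matrices, then resolves the cytolytic signal at
single-cell level in a T-cell compartment. The stages are: a
differential-expression (DEG) screen with cross-dataset intersection;
single-sample GSEA (ssGSEA) scoring of immune and tumor-microenvironment
(TME) metabolic gene sets; Pearson association of FRG expression with
those scores; the ferroptosis potential index (FPI); the overall score
share (OSS) per gene set and group, assembled into a
correlation-connected (ccOSS) network; and a single-cell stage scoring
per-cell cytolytic activity from GZMA and PRF1. Every stage can run on
synthetic data with planted ground truth, which is how the package
validates itself.

## ssGSEA scoring

For one sample, genes are ranked by decreasing expression; ties are
broken by gene symbol (a stable, platform-independent rule). Walking
down the ranking, a gene inside the set adds its rank weight
$(N - i + 1)^\alpha$ normalised over all in-set genes, and a gene
outside the set subtracts $1/(N - n_{set})$. The enrichment score is the
*sum* of this running sum over all $N$ positions (the integral variant),
not its maximum deviation. With $\alpha = 0$ the walk is the classical
Kolmogorov–Smirnov-like statistic; the default $\alpha = 0.25$ is the
conventional ssGSEA weighting. Both the variant and $\alpha$ are
exposed because different published pipelines differ here; the integral
variant with $\alpha = 0.25$ matches the methodology the FPI and LICA
constructions were built on.

Because only ranks enter, scores are invariant under any strictly
monotone transform of a sample's values — log base, normalisation
constants and unit changes are all irrelevant. This invariance is
inherited by the FPI and is property-tested.

Set-to-matrix matching is case-insensitive; a set whose coverage
(fraction of members present among the matrix genes) falls below
`min_coverage = 0.8` is skipped with a warning and the per-set coverage
vector is attached to every result, so silent degradation is impossible.
Optional normalisation divides the whole score matrix by its global
`max − min` (per-set rescaling is available by flag); the FPI uses
unnormalised scores.

## Ferroptosis potential index

The FPI of a sample is the ssGSEA score of the positive (pro-ferroptotic
driver) regulator set minus the score of the negative (suppressor) set,
both taken from the FRG catalog. Swapping the direction labels negates
the index exactly; `unassigned` catalog entries are excluded and
reported. The bundled catalog
(`inst/extdata/frg_catalog_reconstructed.tsv`, 63 genes) is a
reconstruction from the published ferroptosis regulator literature: the
analysis it supports prints only ten of the symbols it used, so the
remaining entries and all direction assignments are best-effort and the
file is deliberately user-replaceable (`load_frg_catalog(path)`). The
same caveat applies to the 29 LICA signatures (15 immune cell types, 14
immune functions) and the 7 TME metabolic categories: the shipped GMTs
are reconstructions using well-established marker genes, and exact
reproduction of any published figure requires swapping in the original
supplementary gene lists via `read_gmt()`.

## Overall score share and the ccOSS network

For a gene set with per-sample scores $S_i$, $m$ groups and group sizes
$n_g$:

$$\mathrm{OSS}_g \;=\; \frac{m}{n_g}\;
\frac{\sum_{i \in g} e^{S_i}}{\sum_{i=1}^{N} e^{S_i}}$$

Exponentiation is the default reading because enrichment scores are
signed: a share of raw sums is undefined or negative whenever a set's
total is non-positive, while $e^{S_i}$ is strictly positive. The
literal raw-sum form is available (`exp_scores = FALSE`) and refuses
sets with non-positive totals. The single $n$ of the printed formula is
generalised to per-group $n_g$ so unequal cohorts are handled; with
equal groups the two coincide. Because the integral ssGSEA score grows
with the number of genes, exponentiating *unnormalised* scores drives
shares toward winner-take-all; the pipeline therefore feeds OSS the
globally normalised score matrix by default (scores of order ±1), which
keeps shares graded while leaving every OSS identity intact — the
normalisation is a single positive rescaling of all scores, and OSS is
computed per set from score differences within that set.
Two identities pin the implementation
down and are tested on random configurations: conservation,
$\sum_g n_g \,\mathrm{OSS}_g = m$ (to 1e-9), and the flat baseline —
identical scores give every group $\mathrm{OSS}_g = m/N$ regardless of
group sizes. Scores are max-subtracted per set before exponentiation;
the share is invariant under this shift, so it is purely an overflow
guard (scores of magnitude 800 are handled).

The ccOSS network has one node per gene set (attributes: category, set
size, per-group OSS) and an edge for every pair sharing at least
`min_shared = 1` genes, weighted by the Pearson correlation of the two
score vectors over all samples and signed positive/negative. No
correlation cutoff is applied by default (`min_abs_r = 0`); both
thresholds are arguments. Export is GraphML (via igraph) or a JSON
schema, and both round-trip through `import_network()`.

## DEG screen

Quantile normalisation forces every column to the row-wise mean of the
sorted columns; ties receive the mean of the quantile values they span.
Per-gene testing is Welch's two-sample t-test with
`log2FoldChange = mean(alt) − mean(ref)` and Benjamini–Hochberg
adjustment across all genes of one comparison, never pooled across
datasets. A moderated-t (empirical-Bayes) backend is intentionally not
used: the screen applies hard thresholds (`p_adj < 0.05`,
`|log2FC| > 1`, both strict) where the threshold, not the test family,
drives the intersection; with ≥ 10 samples per group the two tests
select nearly identical genes. The fold-change filter is two-sided by
default — the published DEG set contains genes higher in either cohort —
with a `one_sided` flag for the alternative reading. Genes with zero
variance in both groups are untestable; they are kept with `p = 1` and
flagged rather than dropped. Cross-dataset intersection is plain set
intersection, sorted; FRG intersection attaches regulator directions.

## Group comparisons and median splits

Two-group comparisons default to the Wilcoxon rank-sum test (robust for
scores; Student/Welch t by flag), three or more groups use one-way
ANOVA, and significance stars follow `*` p < 0.05 to `****` p < 0.0001.
`stats::wilcox.test` supplies exact small-sample p-values where
available and the tie-corrected normal approximation otherwise; fully
tied data is answered with p = 1 rather than a degenerate statistic. No
multiple-testing correction is applied across sets — mirroring per-set
star annotations — but a BH-adjusted column is always emitted so
stricter readings are available. Median splits send samples exactly at
the median to the *low* group; this tie rule is arbitrary but fixed and
documented, and a fully constant gene is an error because the split is
undefined.

## Single-cell stage

Counts are normalised as
`log2(1 + count / cell_total × 10^4)`, making the per-cell vector
invariant to library size. Subset markers are screened per annotated
subset against all other cells (Wilcoxon, thresholds `p < 0.05`,
`log2FC > 0.5`), with fold changes computed on de-logged means,
`log2((mean(2^x − 1)_{in} + 1) / (mean(2^x − 1)_{out} + 1))` — the
convention of the major single-cell toolkits. Cytolytic activity per
cell is the geometric mean of GZMA and PRF1,
`exp(mean(log(x + eps)))` with `eps = 0.01` guarding double-zero cells
(their score is near zero, never `-Inf`), or alternatively a per-cell
ssGSEA score of a cytolytic set — the latter reuses the bulk engine
verbatim, so there is exactly one scoring implementation in the
package. Condition differences are tested per subset and for the pooled
T-cell community; subsets present in only one condition are excluded
and flagged. Cell clustering and embedding are out of scope: subset
labels are an input, as when provider annotations are used directly.

## The synthetic-data generators

The bulk generator emulates a two-cohort design: Gaussian values on the
log2 scale (baseline mean 6, noise SD 1 by default — a mid-intensity
array/log-CPM regime), with planted additive log2 effects on named gene
sets in named groups. Contradictory effects on the same (gene, group)
are rejected. A count mode (negative binomial on `2^mean`, returned as
`log2(x + 1)`) exists for realism but is not the default, because every
downstream stage consumes post-normalisation log expression. The
single-cell generator draws negative-binomial counts for seven T-cell
subsets under two conditions, with per-subset marker genes (log2 shift
2 by default), GZMA/PRF1 elevated 4× over background and shifted by
`effector_shift` log2 units in the second condition, and log-normal
(sdlog 0.3) library-size factors as NB exposure so the normalisation
path is genuinely exercised. `generate_genesets()` produces collections
whose pairwise intersections equal a common core of
`round(overlap_fraction × min size)` genes — exact, so set-arithmetic
oracles can verify the network edge layer.

What the simulations do *not* model: array probe effects, batch
structure, gene–gene correlation beyond the planted sets, dropout
beyond NB sampling, and doublets. Passing tests therefore demonstrate
correctness of the algorithms and recoverability of planted signal
under idealised noise — not performance on any particular public
dataset.

## Validation set-up and problem sizes

The test suite validates each stage against independent oracles:
a loop-based ssGSEA re-implementation (agreement to 1e-9 on 100 random
instances of up to 50 genes × 8 samples × 5 sets), a direct BH step-up
procedure (1e-12), textbook Pearson (1e-12), `limma::normalizeQuantiles`
for quantile normalisation, and brute-force set arithmetic for network
edges. Monte-Carlo checks use 100 seeds for the DEG null calibration
(1000 genes, 10 vs 10; type-I error within [0.03, 0.07]) and FPI
recovery (+1.5 log2 on positive regulators, 20 vs 20 samples; detected
in ≥ 95% of seeds), 50 seeds for single-cell effector power (200 cells
per subset, shift 1.0; pooled Wilcoxon p < 0.01 in ≥ 90%), and 10 seeds
for planted DEG recovery (50 of 1000 genes at +2.0, noise SD 0.1 — the
low-noise recovery regime; sensitivity ≥ 0.9 at FDR ≤ 0.1). The
end-to-end pipeline is run twice per check to assert checksum-identical
output.

## Known limitations

* The bundled gene sets and FRG catalog are reconstructions (see above);
  results on real data depend on supplying the intended originals.
* ssGSEA is the only scoring backend; kernel-density (GSVA-style)
  scoring is intentionally not implemented.
* The OSS formula's exponentiated reading is a documented
  interpretation of an ambiguously printed formula; the raw-sum reading
  is provided, and which one a given figure used cannot be determined
  from the text alone.
* No survival association, deconvolution, batch correction, or
  cell-type discovery.
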