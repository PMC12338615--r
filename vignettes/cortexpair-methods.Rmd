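---
title: "Methods: paired spatial and single-nucleus analysis of laminated cortex"
author: "cortexpair"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: paired spatial and single-nucleus analysis of laminated cortex}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`cortexpair` implements an analysis workflow for paired spatially-resolved
transcriptomics (SRT) and single-nucleus RNA-seq (snRNA-seq) of laminated
cortex, of the kind used to compare an agranular region (no granular layer
4, L6 split into sublayers, and a rare deep-L5 neuron type such as von
Economo neurons) against a granular six-layer region sampled from the same
donors. The workflow runs end to end on data from a synthetic generator with
known ground truth, so every stage is testable without downloads; all
functions equally accept real 10x-style inputs through `read_10x_mtx()` and
`read_spot_positions()`.

Spatial clustering itself (e.g. PRECAST), Gaussian-process SVG models,
batch integration, reference label transfer, doublet detection, and the
LD-score regression that consumes the BED annotations are out of scope;
their outputs (cluster labels, cell-type labels, embeddings) are inputs
here.

# Models and procedures

## Quality control

Spots are filtered with hard count rules: out-of-tissue, all-zero, fewer
than 20 detected genes, fewer than 20 total UMIs (strict "less than", so a
spot at 20 is retained), and 100 percent mitochondrial spots are removed,
each spot counted once under the first applicable reason. MAD-based outlier
flags (median +/- 3 MAD with the 1.4826 consistency constant) are computed
for reporting on SRT, and are the intended nucleus-level filter: low-quality
spots concentrate in white matter, so MAD filtering would bias spot
composition, while nuclei have no such confound. When the MAD is zero the
thresholds collapse to the median; the strict rule still applies (a constant
vector flags nothing; any value off the median is flagged). Whether the
sum/detected metrics are MAD-filtered on the log1p scale is not fixed by the
procedure; the default here is log1p for sum and detected and raw for the
mitochondrial rate, all exposed as arguments.

Empty droplets are removed by the barcode-rank knee: on the log-rank versus
log-total curve (ties collapsed to one rank), a smoothing spline is fitted
(df grows with the number of distinct totals, capped at 20), the cliff is
the point of steepest descent, and the knee is the point of minimum signed
curvature at or left of the cliff. A knee requires a clearly concave
transition (minimum curvature below -2); near-linear curves are rejected.
This knee threshold is the droplet filter here; a Monte-Carlo ambient test
is deliberately not implemented.

Feature selection uses the Poisson deviance under a constant-proportion
null, `D_g = 2 sum_j [ y_gj log(y_gj / mu_gj) - (y_gj - mu_gj) ]` with
`mu_gj = n_j pi_g`; because `mu` shares each gene's total, the linear terms
cancel and only nonzero counts contribute. The companion
`null_pearson_residuals()` gives the residual matrix whose PCA approximates
a GLM-PCA.

## Spatially variable genes

The per-sample scorer is Moran's I of each gene's log-normalized expression
on a symmetrized k-nearest-neighbour spot graph with row-normalized weights
(k = 6, the hexagonal lattice neighbourhood). This is a deliberately light
stand-in for nearest-neighbour Gaussian-process ranking: the aggregation
step — the substantive procedure — consumes any per-sample rank table, so GP
ranks can be dropped in unchanged. Aggregation computes each gene's mean
rank across samples (genes filtered out of a sample contribute that sample's
gene count + 1; penalizing absence avoids rewarding sparsity, and a
"present-samples-only" mode is provided) and calls a gene replicated when it
ranks inside the top cut in at least two samples. The top cut should be read
relative to the transcriptome size: the reference analysis used 1,000 of
roughly 14,000 genes, and the property tests use 500 of the generator's
2,000.

## Pseudobulk differential expression

Counts are summed over (group, sample) pairs; columns with fewer than 10
member observations are dropped and reported. Genes are prefiltered by a
deterministic rule (CPM at least 1 in at least as many columns as the
smallest group has; the published pipeline delegates this to a library call
with unstated output, so an explicit rule replaces it). Expression is
log2(CPM + 1) computed plainly, with no prior-count dialect.

The enrichment model fits, per group, per-gene least squares of log
expression on a member-vs-rest indicator plus covariates (donor by default:
pseudobulk columns are nested in donors, making this the conservative
choice, with an off switch). Residual variances are shrunk by empirical
Bayes: the prior degrees of freedom and prior variance are moment-matched on
log s^2 (trigamma inversion by Newton iterations, tolerance 1e-8, prior df
capped at 500 to avoid overflow), the posterior variance is
`(d0 s0^2 + d s^2) / (d0 + d)`, and the moderated t has `d0 + d` degrees of
freedom. Forcing the prior df to 0 recovers the ordinary per-gene OLS t
exactly, which is the oracle identity the tests assert; limma's eBayes is
the independent cross-check, never the implementation. Significance requires
both FDR below 0.05 and |log2 FC| above 1.5; top markers rank by t.

## Spatial registration

Two annotation systems are registered by correlating their one-vs-rest
t-statistics over the union of the reference groups' top-100 markers
(computed on the common-gene intersection). The direction
(reference -> query) is recorded; undefined correlations from zero-variance
vectors are reported as missing, never as 0. The confidence mark uses an
inclusive cutoff of 0.25; the reference analysis marks "high confidence"
cells without printing its threshold, so 0.25 is a declared, exposed
default.

## NMF and pattern transfer

`nmf_fit()` minimizes the Frobenius loss by HALS (hierarchical alternating
least squares): each loading column and weight row is updated in closed form
and projected to the non-negative orthant, which makes the loss
non-increasing — asserted on every fit in the test suite. Initialization is
from seeded uniform draws scaled so the initial reconstruction matches the
data mean; identical seeds reproduce identical factors. On convergence the
loadings are normalized to unit L2 columns with the scale moved into the
weights.

Rank selection holds out a seeded 5 percent speckle of entries, imputes
them from the current reconstruction each sweep (the standard EM-style
treatment), and scores held-out mean squared error per candidate rank,
averaged over replicates; ties go to the smaller rank.

The factorization input is the log-normalized matrix over all genes
(restricting to high-deviance features is available but off by default,
since the reference procedure does not state it). The working rank in the
analysis scripts is 32, roughly four patterns per simulated cell type,
mirroring how the reference analysis chose 75 factors for 19 cell types:
overcomplete factorizations give each type several patterns and let rare
programs separate from their host type's identity program. At ranks near
the type count, the rare type's pattern tends to absorb part of the L5
band program (the decomposition "rare = L5 identity + private markers" is
not unique at low rank), which blurs its spatial transfer.

Technical patterns are flagged by Pearson correlation of pattern weights
against QC covariates (continuous as given; categorical as one 0/1 dummy
per level), at an absolute-correlation threshold of 0.5 — the reference
analysis discards nine named patterns without printing its cutoff, so 0.5
is a declared default. Flagged patterns are excluded from annotation. Each
cell type's top pattern is the non-technical pattern with the highest mean
weight in that type, ties broken by the pattern's specificity ratio then by
lower index; the top-10 loading genes per pattern are recorded.

Transfer restricts the loadings and the target matrix to their shared,
identically ordered genes and solves non-negative least squares per target
observation by cyclic coordinate descent on the normal equations (fixed
sweep order, tolerance 1e-8), so the projection is deterministic. Spots are
classified as pattern-positive by a strictly-nonzero weight (epsilon = 0,
the literal rule; a positive epsilon is available for numeric robustness).
Doubly-positive spots are excluded and counted rather than assigned,
because the reference analysis observed empirical disjointness rather than
defining a rule; the positive classes are pseudobulked by sample and
compared with the pairwise moderated-t model.

## Cross-region mixed model

The combined pseudobulk intersects the two regions' genes, recomputes CPM
on the combined matrix, and models each gene's log expression as
Layer_Tissue fixed effects plus a donor random intercept, fitted by REML.
The variance ratio (donor over residual) is profiled by one-dimensional
minimization on the log scale (tolerance 1e-8) against the ratio-zero
boundary; one eigendecomposition of the donor Gram matrix serves every gene
and every candidate ratio. Wald inference uses the normal reference — the
decision rule itself converts p-values to signed z-scores — and a gene
counts as DE when |z| > 1.645 and |log2 FC| > 1.5, both strict, exactly as
printed (an absolute z of 1.645 corresponds to two-sided p < 0.10). The DEG
matrix covers every (region-A domain, region-B domain) pair, with rows
scaled by the A-domain's total. Precision weights from the reference
workflow's mean-variance step are deliberately omitted: log expression is
modeled homoskedastically per gene, preserving the stated decision rule
while dropping a tool-internal detail. Fixing the ratio at zero reproduces
OLS z-scores exactly, and the REML fit matches lme4 to numerical precision
in the tests.

The logFC-logFC concordance classifies each shared gene against an
enrichment threshold of 1.25 on either region's one-vs-rest logFC:
A-enriched, B-enriched, both, or neither, with the Pearson correlation over
all shared genes.

## smFISH quantification

The anchor gate clusters cells at k = 3 on the anchor gene's (copy count,
signal intensity) pair — standardized to unit variance by default, which the
source procedure leaves unstated — and keeps the top two clusters by
copy-count centroid, reporting the implied minimum copy count and intensity
among positives. Analysis is restricted to a polygon: drawn vertices
(validated against self-intersection) or, in auto mode, the convex hull of
the gated cells; the even-odd rule counts boundary points as inside. Copy
counts are scaled by cell area divided by the sample's median area — read as
division by relative area, down-weighting large cells, with the
multiplicative reading behind a switch since the sentence is ambiguous.
Expressor calls use a one-dimensional two-component Gaussian mixture fitted
by EM (k-means++-style seeded initialization, 10 restarts, tolerance 1e-8,
variance floor 1e-6), calling a cell expressing when its posterior for the
higher-mean component reaches 0.5 — a standard mixture decision rule that is
less boundary-sensitive than a hard threshold between means. Copy counts
saturate for highly expressed genes, which is why calls replace thresholds.
Coexpression is summarized by the conditional matrix (proportion of gene-i
expressors also expressing gene j; rows with no expressors are missing, not
0), exact-2 and all-3 proportions, and pairwise Spearman correlations with
average-rank ties.

## Gene-set enrichment and genome annotation

External signatures are split at adjusted p < 0.1 (strict) by logFC sign;
local domain or cell-type sets use FDR < 0.05 and logFC > 1 (strict,
enrichment direction only); backgrounds are the remaining overlapping
genes. The two-sided Fisher test is the standard exact test (summing
hypergeometric probabilities at or below the observed table's), checked
against full fixed-margin enumeration in the tests; BH runs across each
test family. Ortholog mapping keeps one-to-one rows, resolves one-to-many
by an optional priority column, and otherwise drops and reports conflicts.
Genome annotations take, per group, the top decile of genes by mean
normalized CPM (the "specificity ratio" variant — group share of the gene's
total CPM — is behind a switch, since the source names a specificity-score
approach without printing the formula), after dropping thin columns,
low-expression genes, duplicated symbols and non-coding genes, and write
0-based half-open BED intervals padded by 100 kb and clipped at zero. The
pipeline stops at the annotations; the heritability regression that
consumes them is out of scope.

# The synthetic generator

`simulate_paired_regions()` draws negative-binomial counts (shared
dispersion 0.5, the simplest overdispersion model adequate for UMI data)
with rate = base x type profile x marker effect x donor effect x library
size. Its defaults define the study conditions: 10 donors, 2,000 genes, one
capture area per donor per region with 7 bands x 20 spots, 400 nuclei per
donor, marker log2 fold-change 2, rare-type prevalence 3 percent, lognormal
library sizes (sigma 0.35), per-donor gene effects (sigma 0.15), and a
single seed driving one RNG stream.

Design choices a reader should know:

- **Band programs.** Each of the eight band programs (L1, L2, L3, L4, L5,
  L6a, L6b, WM) elevates 100 marker genes by 2^2 inside its band; region
  B's merged L6 band expresses both sub-band programs. Program breadth (100
  genes) matches the scale of laminar DE sets in real cortex, where
  enrichment models yield hundreds of significant genes per layer.
- **Marker detectability.** Marker base rates are floored at the
  transcriptome median: real laminar markers are, by selection, expressed
  genes. Without the floor a tail of planted "markers" sits below the
  detection limit of any method at this depth.
- **Broad type profiles.** Every cell type (and its aligned band) carries a
  transcriptome-wide lognormal profile (sigma 0.4): real cell types differ
  across thousands of genes, not just at markers. This decorrelates NMF
  loadings the way real data does; without it, all patterns share one
  baseline and non-negative least squares smears weight across them.
- **The rare type is an L5 subclass.** It shares the L5 type's broad
  profile and band program and adds two 100-gene programs of its own (its
  private markers and an associated deep-L5 program), mirroring how a rare
  deep-layer neuron class relates to its host layer. Both programs are
  confined to the deeper half of region A's L5 band, with a low ambient
  background (2 percent of base) across region-A spots and all nuclei —
  leaky transcripts are ubiquitous in droplet data — and are entirely
  absent from region B, as the transcripts of a cell type that does not
  exist there. The absence is what lets the projected pattern attain exact
  zeros in region B.
- **Technical genes.** Fifty genes scale with library size a second time,
  planting a library-size-driven factor for the technical filter to catch.
- **Flat genes.** Three hundred genes carry no type, band, or marker
  structure — the spatially null reference against which the SVG
  replication rule's specificity is tested.

What the generator does not emulate: spatial autocorrelation beyond band
structure (no smooth within-band gradients), cell-type mixtures within
spots, doublets, batch or chemistry effects beyond library size, image
data, and real gene-gene correlation. Passing recovery tests therefore
demonstrates that the procedures are implemented correctly and recover
planted structure under realistic noise — not that they are robust to every
artefact of real tissue.

`simulate_smfish()` draws cell positions uniformly, lognormal areas, an
anchor gene elevated only inside a horizontal band (two elevated
subpopulations, so the k = 3 gate has natural clusters), and per-gene
two-component Poisson copy counts (off rate 0.5, on rate 20 — the scale of
real off/on smFISH separation) whose rates scale with relative cell area,
with intensity correlated to copies.

# Problem sizes and numerical choices

The test suite and the acceptance script run everything at the generator's
default scale (20 capture areas of 140 spots, 4,000 nuclei, 2,000 genes),
with NMF at rank 32 (about 300 HALS sweeps) and rank selection on
500 x 600 planted-rank-3 Poisson matrices over ranks 1-6 with two
replicates per seed. Smaller module fixtures (3 donors, 600 genes) exercise
the same code paths. Tie-breaks are deterministic everywhere: SVG ranks by
score, then mean expression, then gene id; pattern assignment by mean
weight, then specificity, then index; rank selection by smaller rank.
Degenerate inputs (constant genes, zero-variance patterns, empty classes,
all-zero columns, degenerate Fisher margins) return flagged results or
informative errors rather than NaN.

Known limitations: the mixed model supports a single random intercept
(donor), not crossed or nested designs; Moran's I measures autocorrelation,
not spatial variance components, so its ranks differ from GP-based ranks on
genes with long-range trends; the moderated-t prior assumes a common
variance distribution across genes within each fit; and the NMF objective is
non-convex, so factors are reproducible only at a fixed seed.
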