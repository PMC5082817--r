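---
title: "Methods: models, parameters, and design choices in StimProfiler"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters, and design choices in StimProfiler}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(StimProfiler)
```

## The analysis problem

StimProfiler implements a complete analysis chain for paired
antigen-stimulation studies of peripheral blood mononuclear cells (PBMCs).
The motivating design is a pediatric egg-allergy cohort: PBMCs from
baked-egg-reactive (BER), baked-egg-tolerant (BET), and atopic egg-tolerant
control (AC) children are cultured with egg-white protein (EW) or media
alone (M); transcription is measured on arrays after stimulation and
secreted cytokines by multiplex assay. The scientific questions are (i)
which genes respond to antigen differently across clinical groups, (ii)
which immune cell types and activation states those responses point to, and
(iii) how stimulation-induced cytokine secretion depends on the clinical
group.

Every stage is exercised against a synthetic-data generator with planted
ground truth, so the statistical guarantees of the pipeline are testable
without access to patient data.

## Differential expression

Expression is analyzed on the log2 scale after standard array
preprocessing: probes detected above background in fewer than 20% of
samples are removed (`filterProbesByDetection()`; a probe at exactly 20% is
retained — the filter discards only probes *below* the threshold), and each
gene is represented by its highest-mean-expression probe
(`collapseProbesToGenes()`, ties broken by lexicographically smallest probe
id so the collapse is reproducible).

Three contrast families cover the design (`fitContrast()`):

1. **Between groups within a condition** — per-gene OLS of expression on
   group with gender and batch covariates, restricted to one condition's
   samples.
2. **Within group, EW vs M** — the paired stimulation effect. Pairing is
   handled by explicit per-subject differencing (EW − M), then the mean
   delta is tested against zero with gender and batch as subject-level
   covariates. Differencing keeps designs full-rank and removes all
   subject-level offsets, including any cell-composition differences
   between subjects.
3. **Difference of differences** — the per-subject deltas of two groups are
   compared, i.e. the stimulation-by-group interaction. This is the
   pipeline's headline contrast: it asks which genes are modulated by
   antigen *to a different extent* across clinical phenotypes.

Per-gene variances are estimated by ordinary least squares with no
empirical-Bayes moderation; two-sided p-values come from the t
distribution, and Benjamini–Hochberg adjustment is applied across all genes
within one contrast (never across contrasts). With dozens of subjects per
group and a single variance parameter per gene this is well calibrated (the
test suite checks a Kolmogorov–Smirnov statistic < 0.05 against uniform
p-values on null simulations at 2000 genes); a moderation hook could be
added behind a flag without changing any interface.

Degenerate designs are handled explicitly: aliased covariate columns are
dropped with a warning (the contrast coefficient itself may never be
aliased), and zero residual degrees of freedom is an error rather than a
silent NA.

### Standardized signatures

Raw significant-gene lists differ enormously in size across contrasts,
which would confound any comparison of enrichment results. Signatures are
therefore standardized (`standardizeSignature()`): per direction, keep the
500 smallest p-values, then the 200 largest |log2FC| among them. Ties break
by (p ascending, |log2FC| descending, gene id ascending), making the result
invariant to input row order; genes with log2FC exactly 0 belong to neither
direction.

## Over-representation analysis

`fisherEnrichment()` tests a query list against a gene set with the
one-sided (greater) Fisher exact test — the hypergeometric upper tail of
the 2×2 overlap table. The universe is all genes present in the expression
matrix after probe collapse; gene sets are intersected with it before
testing, which is standard ORA practice and keeps the table margins honest.
The alternative is one-sided because signatures already encode direction
(up/down lists are tested separately). Odds ratios are cross-product ratios
with a Haldane correction of 0.5 per cell applied only when a cell is zero.
Gene identifiers are matched as exact strings; no ortholog mapping is
attempted, so cross-species collections must be pre-mapped.

## The Immune Annotation Score (enrichment of enrichment)

Public pathway collections identify processes but not cell types or
activation states. The package's two-stage procedure scores *categories* of
immunologic signatures (e.g. "CD8 cells", "TLR-stimulated macrophages") at
four annotation levels — cell type, cell subset, activation state, and
myeloid TLR stimulation — supplied as a signature-to-category map
(`AnnotationMap`; one category per signature per level; signatures not
assignable at a level are excluded from that level's universe).

Stage one (`firstStageEnrichment()`) enriches the query against every
annotatable signature and keeps those with FDR-adjusted p ≤ 0.01. Stage two
(`categoryTest()`) asks, for each category containing at least one enriched
signature, whether enriched signatures are over-represented inside the
category: a one-sided Fisher test on the 2×2 table over all signatures
tested at the level, rows in-category vs not, columns enriched vs not. The
phrase "using all significantly enriched signatures as a background" admits
more than one 2×2 construction; the one implemented here is the only one in
which both the Fisher test and its odds ratio are well defined, and it is a
documented package decision rather than an external fact.

The combined score is

$$\mathrm{score} = \big(-\log_{10}\,\mathrm{median\ FDR\ p}\big)\times
  \big(-\log_{10}\,\mathrm{category\ p}\big),$$

with the median taken over the category's *enriched* members only. At the
double significance boundary (both inputs 0.01) the score is exactly 4.
Note an ambiguity worth surfacing: a "score above 2" is sometimes read as
the significance boundary, yet with the first-stage gate at 0.01 the median
factor is always ≥ 2, so a category significant at 0.01 in stage two always
scores ≥ 4; a score just above 2 instead reflects a strong stage-one median
with a stage-two p only trending toward significance. Both readings are
reported rather than resolved: the per-category BH-adjusted stage-two
p-value (`category_fdr_p`) is emitted alongside the score and can be used
on its own. Only categories with at least one enriched signature appear in
the output (`runAnnotationLevel()`), and a p-value of exactly 0 is clamped
at 1e-300 with a warning rather than producing an infinite score.

## Co-expression modules

A deliberately lightweight weighted-correlation network:

- **Adjacency**: unsigned, $a_{ij} = |r_{ij}|^\beta$ with soft power
  $\beta = 7$ (a user parameter; no scale-free fitting is performed).
  Unsigned matches the convention that a module may contain genes
  anti-correlated with its summary profile.
- **Topological overlap**: the standard unsigned TOM,
  $(\sum_{u} a_{iu}a_{uj} + a_{ij}) / (\min(k_i,k_j) + 1 - a_{ij})$,
  checked in the tests against a brute-force triple-loop oracle to 1e-10.
- **Detection**: average-linkage clustering of 1 − TOM cut at a *static*
  height, by default 0.85 × the tallest merge. A static cut replaces the
  dynamic tree-cut heuristic: it is fully deterministic, one-parameter, and
  sufficient for the acceptance surface (recovery of planted modules). The
  0.85 default was chosen from the merge-height structure of the planted
  geometry: within-module joins complete below ~0.8 of the tree while
  background genes — including chance-correlated ones — attach above
  ~0.88. Higher cuts contaminate modules with background genes; lower cuts
  split modules. Clusters of ≥ 50 genes (default) become modules, numbered
  by decreasing size; everything else is unassigned (label 0).
- **Eigengenes**: first principal component of the z-scored member
  submatrix, unit norm, sign-oriented so the mean member correlation is
  non-negative. Orientation is a convention, not an inference — individual
  members may anti-correlate with their eigengene. Zero-variance members
  are dropped from the computation.
- **Merging**: modules whose eigengene dissimilarity (1 − r) is below 0.29
  are merged iteratively (closest pair first, eigengenes recomputed after
  each merge).
- **Module–trait association**: simple linear regression of each trait on
  each eigengene with BH across all pairs. When traits are per-subject
  cytokine deltas, eigengenes are first reduced to per-subject EW − M
  deltas (`eigengeneDeltas()`) so the two sides of the regression live on
  the same units of observation.

A documentation note on external reference points: published analyses of
this design report a minimum module size of 50 alongside a smallest
observed module of 45 genes, and gene-space sizes of both 19956 and 19959 —
internally inconsistent figures that are recorded here as-is; the package
enforces its own stated parameter (all assigned modules ≥ `minModuleSize`).

## Cytokine analysis

The stimulation effect per subject and cytokine is the concentration
difference EW − M in pg/ml (`computeDelta()`; unpaired entries are dropped
with a count). These deltas can be zero or negative, so a plain log10 is
undefined; the package uses a signed symmetric log transform
(`log10TransformDelta()`):

$$f(\delta) = \mathrm{sign}(\delta)\,\log_{10}(1 + |\delta|/o),$$

with offset $o$ defaulting to 1 pg/ml (the order of the assay floor). The
transform is monotone, odd, zero at zero, and equals $\log_{10}\delta$ for
large positive deltas. This is a deliberate, prominently documented
convention — analyses that only ever see large positive deltas will match a
plain log10; analyses with negative deltas get a defined, symmetric
treatment instead of dropped observations.

Group effects are estimated per cytokine by Huber M-estimation
(`huberGroupFit()`): IRLS with $\psi$-tuning constant $k = 1.345$ (95%
Gaussian efficiency, the common default for robust regression), scale =
median absolute residual / 0.6745 (consistent at the normal), convergence
when the largest coefficient change drops below 1e-8 or after 50 iterations
(non-convergence is flagged and the last iterate returned). The model is
univariate — group is the only predictor, AC the reference level — and Wald
p-values use the asymptotic-normal M-estimator variance. BH is applied
across cytokines separately per group coefficient. The test suite verifies
the estimator against an independent robust-regression implementation and
checks its OLS limit as $k \to \infty$.

## The synthetic generator

`simulationConfig()` defaults *are* the emulated study conditions:

- **Design**: 14 AC / 20 BET / 34 BER subjects (the expression-passing
  sample counts of the motivating cohort), two samples per subject (EW, M),
  gender Bernoulli(0.5), hybridization batch round-robin over 5 levels.
- **Expression**: additive Gaussian noise on the log2 scale (matching
  variance-stabilized, quantile-normalized array intensities), gene
  baselines N(8, 1.5), residual SD 0.5. 2000 genes stand in for the ~20k
  array gene space — a scale at which the suite's simulations (power,
  calibration, planted-category recovery) run in seconds while leaving
  multiple-testing behaviour intact.
- **Planted DE**: 100 genes shifted by +1 log2 unit in EW samples of the
  allergic groups (BER, BET) only.
- **Modules**: one latent factor per module shared by its genes with
  loading $\sqrt{0.8}$, giving expected pairwise correlation 0.8; module
  recovery simulations use 3 modules of 100 genes plus 300 background genes
  in 60 samples.
- **Covariate offsets**: small additive batch (SD 0.2) and gender (+0.3 on
  5% of genes) effects are injected at the subject level. Because both of a
  subject's samples share them, they cancel exactly in paired deltas —
  covariate adjustment is therefore exercised by the between-group family,
  while the delta families gain robustness by construction.
- **Signatures**: 100 signatures of 100 genes in 20 categories; the five
  signatures of the planted category draw 60% of their members from the
  planted DE genes, all others are uniform draws.
- **Cytokines**: log10-scale baselines (median ~3 pg/ml), a mild universal
  stimulation response (+0.2 log10), group-specific planted shifts for
  IL-9, TNFa and IL-5 in the allergic groups, null cytokines alongside,
  noise SD 0.3, and a detection floor of 0.5 pg/ml applied by clamping
  (imitating a multiplex assay's lower limit; clamping was chosen over
  truncation-resampling for simplicity and determinism).

What the generator does **not** emulate: intensity-dependent variance,
probe-level structure (detection filtering and probe collapse are tested on
hand-built fixtures instead), correlation between the expression modules
and the cytokine responses (unless a test plants one explicitly), batch
effects that interact with stimulation, and missing samples. Passing tests
therefore demonstrate the statistical machinery on clean, correctly
specified inputs — they do not certify behaviour under array artefacts the
generator leaves out.

## Numerical conventions

- p-values of exactly 0 (possible in degenerate exact fits) are clamped to
  the smallest positive double before BH so outputs stay in (0, 1].
- All orderings have total, documented tie-breaks (gene id, probe id,
  category name), making every table byte-reproducible under permutation
  of inputs.
- Seeds fully determine generator output; the pipeline records the seed and
  a config fingerprint in every report.

## Known limitations

- The static tree cut trades the adaptivity of dynamic cutting for
  determinism; data with modules of very unequal tightness may need a
  per-dataset `cutHeight`.
- Per-gene OLS without variance moderation loses power for very small
  groups (and the covariate-adjusted fits need enough subjects per group to
  keep residual degrees of freedom; the fitters raise errors rather than
  degrade silently).
- The Fisher-based category test treats signatures as exchangeable units;
  overlapping signatures within one category are counted independently.
- The signed symmetric log transform is one of several defensible
  treatments of non-positive concentration deltas; its offset is a unit
  choice that should match the assay floor.
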