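---
title: "Methods: composition, copy number and interaction analysis of lung tumor transcriptomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: composition, copy number and interaction analysis of lung tumor transcriptomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lunghet)
```

This vignette documents the models behind `lunghet`, the choices that were
genuinely open when the package was designed, and what its synthetic cohorts
can and cannot tell you about real data. The package analyses lung tumor
transcriptomes (LUAD and LUSC, the two major NSCLC subtypes) along three
axes: malignant-cell identification and subclone structure from
expression-inferred copy number; bulk-cohort cellular composition by
signature-based deconvolution, with composition modules linked to survival;
and permutation-tested ligand–receptor interactions between cell types.

## The synthetic cohort

Real tumor atlases of this kind (hundreds of thousands of cells across
dozens of patients, plus external bulk cohorts with survival) are not
redistributable, so every stage is exercised on seeded synthetic cohorts
with complete ground truth. The generator is first-class, tested code, and
its defaults define the study conditions used throughout the tests and the
acceptance script.

**Counts model.** Gene baseline means are log-normal (`meanlog = -1`,
`sdlog = 1`, i.e. a median of ~0.37 counts per gene per cell over a
2000-gene desk-scale genome — roughly the per-gene depth of droplet
scRNA-seq). Counts are negative binomial with dispersion 0.5 (variance
`mu + 0.5 mu^2`); `dispersion = Inf` gives the Poisson limit used by
calibration tests. Per-cell library factors are log-normal with sigma 0.2.

**Cell identity.** Twelve cell types (8 non-immune: AT1, AT2, basal, club,
ciliated, neuroendocrine, fibroblast, endothelial; 4 immune: T, B,
macrophage, mast), each with a disjoint block of 40 marker genes elevated
8-fold. Disjoint markers make signature recovery testable: the provenance of
every selected marker can be checked against truth.

**Malignancy and subclones.** Malignant cells occur in AT2 under LUAD and
basal under LUSC (fraction 0.5 of those types in tumor samples). Each
subclone carries contiguous dosage events (amplification multiplier 2,
deletion 0.5) spanning 10–17.5% of the genome; expected expression is linear
in dosage, the premise of expression-based CNV inference. The default AT2
population carries two subclones (a single 200-gene amplification; a
deletion plus an amplification), basal one.

**Bulk cohort.** Bulk samples are noisy mixtures: a sample's true
composition is drawn from its group's Dirichlet archetype (concentration 50
on the dominant type, 1 elsewhere, matching a strongly dominated mixture; the
"hybrid" archetype is uniform with concentration 5), the expected profile is
`profiles %*% composition`, and multiplicative log-normal noise with sigma
0.2 is applied. Survival is exponential with group-specific hazards (1.0 for
the fibroblast-dominated archetype, 0.35 otherwise — a hazard ratio in the
range seen for poor-prognosis strata) and independent exponential censoring
calibrated to a 20% censoring fraction.

**What is *not* emulated:** doublets, ambient RNA, batch and chemistry
effects, UMI saturation, cell-size confounding, immune-repertoire structure,
and any transcriptional program that is not a marker block or a dosage
event. Passing tests therefore demonstrate that the estimators recover the
structure they model, under realistic count noise — not that they are robust
to artifacts the generator omits.

## CNV inference

Expression is transformed to `log2(counts/libsize * 1e5 + 1)` — log2 of
(CPM/10 + 1) — chosen so a dosage doubling adds ~1 in the high-expression
limit and dosage acts additively in log space. The chain is:

1. center each gene on the mean of the **reference cells** (cells assumed
   copy-number normal; immune cells in the drivers);
2. re-center each cell by its median — removes the residual depth shift
   that library normalization leaves in log space (depth and the median
   shift correlate at r ≈ 0.96 in the synthetic cohort);
3. clamp to ±3 (configurable), limiting the leverage of extreme detections;
4. average sliding windows of 100 genes, step 1, in chromosome order;
   windows never span chromosomes, and windows truncated at a chromosome end
   are kept while they hold at least half a window (a shorter chromosome
   keeps one whole-chromosome window);
5. re-center each cell by its median over windows, then re-center every
   window on the reference, so reference window means are exactly zero (this
   contract is asserted in tests to 1e-6).

The 100-gene flat average is the field's convention for this analysis; the
window size is the main resolution/noise trade-off (events much shorter than
a window are diluted proportionally).

**Malignancy calling.** A cell's burden is its mean squared window
deviation, computed after zeroing deviations within 1.5 reference SDs of
zero per window — the same denoising idea inferCNV applies, which removes
the bulk of the null contribution while leaving genuine dosage plateaus
untouched. The threshold is `mean + 3 SD` of the reference cells' burden.
On the default cohort this flags under ~1% of reference cells,
with specificity ~0.99 and sensitivity ~0.82–0.87 against truth.

**Detection limits (known limitation).** At desk scale the genome holds only
~17 independent 100-gene windows, so the null burden has a 30–50% relative
SD across cells and the +3 SD threshold sits at roughly twice the null
level. A subclone whose events cover ≥15% of the genome clears it with
sensitivity ≈ 0.9; a single event covering 10% adds only about 0.9× the null
burden at a 2× dosage under realistic droplet counts and sits at the
detection limit (per-subclone sensitivity ≈ 0.5). This is an information
limit of the burden-threshold rule in the shallow-count regime, not a
tuning artifact: widening or narrowing the denoise band moves the aggregate
sensitivity between ~0.80 and ~0.94 without making the 10% event reliably
detectable, and standardizing each cell's noise scale shrinks the signal by
the same factor it shrinks the noise. On deep (continuous-valued) expression
the same rule detects 10% events comfortably, as the expected-value tests
show.

**Subclones.** Ward-linkage agglomerative clustering on Euclidean distance
in window space; `k` selected in 2..8 by mean silhouette width (first
maximum on ties); cells are processed in lexicographic id order so
dendrogram ties resolve deterministically. Driver-gene scores average all
windows containing the gene, per subclone.

## Differential expression, tau, and gene-set scores

Normalization for all expression-program work is the single-cell convention
`log(counts/libsize * 1e4 + 1)` (natural log). The test is the Wilcoxon
rank-sum (normal approximation with tie and continuity correction, verified
identical to `wilcox.test` and computed vectorized across genes), with
Benjamini–Hochberg adjustment over the tested genes; all-zero genes are
reported with p = 1 and excluded from the adjustment. The log fold change is
`log((mean_a + 1)/(mean_b + 1))` on the linear normalized scale. The logFC
base is a genuine convention choice — published thresholds of 0.25
(single-cell) and 1 (bulk) are applied here on the natural-log scale, the
scale on which those conventions arose.

Tau specificity is `sum(1 - x/max(x))/(n - 1)` over per-type mean
expression: 0 for uniform, 1 for single-type expression; it is scale
invariant and undefined (an error, not 0) on all-zero input. Gene-set
scores are per-cell means of linear normalized expression over the set's
present genes, with an optional `log2(x + 1)`; an empty intersection is an
error naming the set, never a silent 0. Max-score assignment breaks exact
ties toward the lexicographically first set name and flags them.

## Deconvolution

The signature matrix keeps, per cell type, the top 50 one-vs-rest DEGs
(adjusted p < 0.05, logFC > 0.25) that also have tau ≥ 0.6 and attain their
row maximum in their source type ("marker coherence" — every signature row
peaks in the type it marks). Entries are mean linear normalized expression.

Deconvolution solves non-negative least squares per bulk sample over the
shared genes, after dividing each gene by its signature-row SD so that
highly expressed genes do not dominate the fit; weights are normalized to
sum to one and the pre-normalization residual is recorded. Linear space is
essential — mixtures are additive in expression, not in log expression.
Sum-normalized NNLS was chosen over simplex-constrained least squares as the
minimal faithful estimator; the two agree on (near-)exact mixtures but can
differ by a few parts per thousand under noise, which is why the package's
grid-search cross-check uses an exact mixture. Missing signature genes are
dropped rather than zero-filled, to avoid biasing residuals; a fit is
refused when less than half the signature remains.

On the default cohort, noiseless mixtures are recovered with per-weight MAE
below 1e-6 and sigma-0.2 mixtures with overall Pearson r ≈ 0.999 against
truth, mirroring at the property level the cross-cohort consistency
reported for this family of methods.

## Composition modules, classification, survival

Samples are clustered with average linkage on correlation distance
(1 − Pearson). The correlation is computed on **column-standardized**
weights: raw composition vectors are nearly one-hot for dominated samples,
which makes flat ("hybrid") samples incoherent under correlation distance —
they share no within-vector pattern and individual hybrids glue to dominant
clusters. Standardizing expresses each sample relative to the cohort, giving
flat archetypes a shared pattern; with it, planted archetypes are recovered
exactly across seeds. Group naming uses mean z-scored weights: top type
`T` gives `T-high` when its mean z exceeds 1 and no other type is within
0.25 z; exactly one runner-up within 0.25 gives `T1-T2 hybrid`; more ties,
or no type above 1, give `hybrid`. The thresholds make an inspection-based
naming practice explicit and testable.

Classification of sample classes from compositions uses a linear-kernel SVM
under stratified k-fold cross-validation (5 folds, 20 repeats with derived
seeds), reporting one-vs-one ROC AUC macro-averaged per repeat, with mean
and SD over repeats — pairwise AUC is primary because subtype contrasts are
pairwise. Augur-style cell-type prioritization subsamples 50 cells per
condition per repeat, selects the 100 most variable genes, fits a ridge
logistic classifier (fixed penalty 0.1) under 3-fold CV, and ranks types by
held-out AUC; equal subsampling removes abundance as a confounder, and only
the subsample–classify–rank scheme is kept from the original algorithm.

Kaplan–Meier estimation and the log-rank test are delegated to the standard
survival machinery; the package adds the "named group vs rest" contrast,
per-group curves, and a degenerate-data convention (no events at all gives
chi-square 0, p = 1, with a warning). Under equal hazards the log-rank
p-values are uniform (KS-checked over 500 replicates), and the full
simulate → deconvolve → cluster → log-rank chain flags the planted
high-hazard group in ≥ 80% (observed ~90%) of replicates.

## Ligand–receptor interactions

The interaction score of a pair for (sender, receiver) is the mean of the
ligand's mean expression in senders and the receptor's mean in receivers.
The null shuffles cell-type labels across all cells (implemented as random
disjoint sender/receiver index sets of the observed sizes);
`p = (k + 1)/(B + 1)` one-sided, which respects the permutation grid and
never returns 0. Pairs are gated on ≥10% detection of the ligand in senders
and receptor in receivers (the cited tool's convention); types with fewer
than 3 cells are flagged with p = 1 rather than tested. Counts of
significant pairs use nominal p < 0.05 with no multiplicity correction —
a deliberate convention, documented rather than hidden, matching how
interaction counts are reported in this literature; tumor/adjacent count
differences are reported descriptively, never tested with an unstated
statistic.

## Numerical and testing choices

- Problem sizes: the default cohort is 2000 genes × ~3000 cells with 120
  bulk samples; calibration tests use 200–1000 genes and 40–300 cells; the
  survival chain runs 25 replicates and the null calibrations 200–500 —
  sizes chosen so the full suite and the acceptance script each run in
  minutes on one core while keeping Monte-Carlo error well inside the
  asserted bands (binomial/KS 3-SE bounds).
- Determinism: every stochastic routine takes a seed and is a pure function
  of (inputs, seed); repeated CV derives per-repeat seeds from the base
  seed; clustering tie-breaks are fixed by lexicographic cell order.
- Degenerate inputs fail loudly: all-zero tau vectors, empty gene-set
  intersections, zero-variance references, and unknown survival groups are
  errors naming the offending object; all-zero NNLS solutions fall back to
  uniform weights with a warning.
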