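# lunghet

Integrative analysis of cellular heterogeneity in non-small-cell lung cancer
(NSCLC) from single-cell and bulk RNA-seq, built as an R package plus a set
of numbered analysis drivers. It is aimed at computational biologists who
want to dissect a tumor atlas along three axes: **which cells are malignant
and what subclones they form** (expression-inferred copy number), **what
cell-type mixtures make up bulk tumors and how those mixtures stratify
patients** (signature-based deconvolution, composition modules, survival),
and **how cell types talk to each other** (permutation-tested
ligand–receptor interactions). Because the original patient cohorts are not
redistributable, the package ships a seeded synthetic-cohort generator with
full ground truth that reproduces the statistical structure every stage
assumes, so the whole chain is testable end to end.

## Methods at a glance

**CNV inference.** Expression is normalized to `log2(CPM/10 + 1)`, centered
gene-wise on a reference of presumed-normal cells, re-centered per cell,
clamped to ±3, and averaged over sliding windows of 100 genes (step 1) in
chromosome order — the windowed-smoothing idea behind inferCNV. A cell's
**burden** is its mean squared window deviation (computed on deviations
outside the reference noise band); cells above
`mean(ref burden) + 3·SD(ref burden)` are called malignant. Malignant cells
are clustered into subclones by Ward-linkage hierarchical clustering in
window space, with `k` chosen by silhouette.

**Deconvolution (cellular composition).** A signature matrix `S` (marker
genes × cell types) is built from the single cells: per type, one-vs-rest
Wilcoxon differential expression, candidates filtered by
`adjusted p < 0.05`, `logFC > 0.25`, tau specificity ≥ 0.6 and marker
coherence, top 50 by logFC kept. Each bulk profile `b` is decomposed by
non-negative least squares over the shared genes after per-gene unit-variance
scaling,

```
w* = argmin_{w ≥ 0} || S w − b ||₂ ,   then  w* ← w*/Σ w*
```

**Composition modules and survival.** Samples are hierarchically clustered
(correlation distance on z-scored weights, average linkage); groups are
named `<Type>-high` from their mean z-scored weights, or `hybrid`. Group
structure is validated by a linear-kernel SVM (repeated stratified CV,
one-vs-one ROC AUC) and an Augur-style prioritization (subsample cells,
classify condition from expression with ridge logistic regression, rank cell
types by AUC). Survival differences between a named group and the rest use
Kaplan–Meier curves and the log-rank test.

**Expression programs.** Wilcoxon DEGs with the `|logFC| > 0.25` (single
cell) / `> 1` (bulk), `adjusted p < 0.05` convention; tau cell-specificity
`τ = Σ(1 − x̂ᵢ)/(n−1)`, `x̂ᵢ = xᵢ/max(x)`; stage-specific gene modules;
stemness-style gene-set scores (mean expression of a marker set, optionally
log2) with max-score cluster assignment.

**Cell–cell interactions.** For a ligand–receptor pair and a (sender,
receiver) type pair, the score is the mean of the two mean expressions; its
p-value comes from shuffling cell-type labels (one-sided,
`p = (k+1)/(B+1)`), gated on ≥10% detection, in the style of CellPhoneDB.
Significant pairs are counted per type pair and per type.

## Worked example

```r
library(lunghet)
catalog <- generate_gene_catalog(5, 400, seed = 1)
design  <- cohort_design(seed = 1)          # 12 cell types, ~3000 cells
sim  <- simulate_single_cells(catalog, design)

# malignant-cell calling from inferred CNV, immune cells as reference
ref   <- sim$cells$meta$cell_id[sim$cells$meta$cell_type %in% design$immune_types]
prof  <- compute_cnv_profile(sim$cells, catalog, ref)
calls <- call_malignancy(prof)
table(truth = sim$cells$meta$malignant, call = calls$calls$label)
#>        call
#> truth   malignant non_malignant
#>   FALSE        28          2913
#>   TRUE         68            15

# deconvolve bulk mixtures and stratify survival by composition group
profiles <- cell_type_profiles(sim$cells)
bulk   <- simulate_bulk(catalog, profiles, design, seed = 2)
sig    <- build_signature_matrix(sim$cells)   # 480 marker genes x 12 types
comp   <- deconvolve(sig, bulk$bulk)
groups <- discover_groups(comp, k = 4)
table(groups$groups$group_name, bulk$truth$group)
#>            AT2-high Fib-high hybrid NE-high
#>   AT2-high       30        0      0       0
#>   Fib-high        0       30      0       0
#>   hybrid          0        0     30       0
#>   NE-high         0        0      0      30

surv <- simulate_survival(bulk$truth$group, design$hazards,
                          design$censoring_rate, seed = 3)
grp  <- groups$groups$group_name[match(rownames(comp$weights), groups$groups$sample)]
logrank_test(surv$time, surv$event, ifelse(grp == "Fib-high", "Fib-high", "rest"))
#> log-rank test: chisq = 38.929 on 1 df, p = 4.394e-10
```

The confusion table shows the CNV burden rule recovering most planted
malignant cells at ~1% false-positive rate; the composition groups are
re-discovered exactly and correctly named; and the fibroblast-dominated
group — simulated with an elevated hazard — is strongly separated in
survival.

## Analysis workflow

`analysis/` contains numbered drivers that run the full study on the
synthetic cohort and write tables under `results/`:

1. `01_simulate_cohort.R` — single-cell atlas + bulk cohort + survival.
2. `02_cnv_subclones.R` — CNV profiles, malignancy calls, subclones,
   driver-gene scores, malignant ratios.
3. `03_signatures_deconvolution.R` — signature matrix and deconvolution,
   checked against true compositions.
4. `04_composition_modules_survival.R` — composition correlation, group
   discovery/naming, SVM validation, log-rank stratification.
5. `05_cell_interactions.R` — ligand–receptor permutation tests and
   interaction counts, tumor vs adjacent.
6. `06_expression_programs.R` — malignant DEGs, shared-DEG partition, tau,
   stage modules, stemness scoring.

## Limitations

The synthetic generator covers negative-binomial counts, marker structure,
dosage events, mixture noise and censored survival, but not doublets,
ambient RNA, batch effects or immune-repertoire structure; see the methods
vignette (`vignettes/lung-heterogeneity-methods.Rmd`) for what passing tests
do and do not imply about real data, and for the detection limits of the
burden-threshold malignancy rule at desk scale.
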