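---
title: "Models and methods behind epiage"
author: "epiage authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind epiage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette explains the statistical models the package implements, the
assumptions behind them, the tunable parameters with their defaults, what
the synthetic-cohort generator does and does not emulate, and the design
choices made where more than one reasonable definition exists. It states no
empirical result beyond what the test suite and `scripts/acceptance.R`
compute at run time.

## The data model

The substrate is a beta-value matrix: per CpG probe and sample, the
methylated-signal fraction `beta = M / (M + U)` in [0, 1] (`computeBeta()`).
The package assumes this matrix is already normalized and imputed —
background correction, dye-bias and probe-type correction, batch removal
and KNN imputation are array-processing steps upstream of this package's
scope. What the package does handle is probe-level filtering
(`filterProbes()`: SNP-related and multi-hit exclusion lists, optional
removal of chrX/chrY probes) and probe annotation: CpG-island relation
(Island / Shore / Shelf / OpenSea, where a shore is the 2 kb flanking an
island and a shelf the 2 kb beyond that), gene-feature class (TSS200,
TSS1500, 5'UTR, 1stExon, Body, ExonBnd, 3'UTR, IGR), and a distal flag for
enhancer-like positions. Coordinates are 1-based inclusive, the convention
of array manifests.

Cohorts are stored as `MethylSet`, a `SummarizedExperiment` subclass whose
validity method enforces beta values in [0, 1] and unique probe/sample
ids. Probe annotation lives in `rowData`, per-sample covariates in
`colData`, so every downstream function takes one object.

## Global summaries

`meanMethylation()` is the per-sample mean beta over non-missing probes.
`methylationEntropy()` is the per-sample mean of the binary Shannon entropy
`-(b log2 b + (1-b) log2(1-b))`, with betas clipped to `[eps, 1-eps]`
(default `eps = 1e-6`) so the logarithms stay finite. Several entropy
variants exist in the literature (per-read, per-region, different bases and
normalizations); the per-site binary entropy averaged over probes, in bits,
was adopted because it is bounded in [0, 1], symmetric under
`beta -> 1 - beta`, and maximal at beta = 0.5 — which is exactly the
"drift toward intermediate methylation" signal it is meant to capture.
Missing betas are excluded pairwise rather than imputed, since imputation
belongs to the upstream processing.

## Cell-composition estimation

Whole blood is a mixture; age changes its composition (neutrophils up,
naive T cells down), so any probe tracking a cell type masquerades as an
aging probe. `estimateCellProportions()` implements the reference-based
projection step of the Houseman approach: per sample, minimize
`||R w - b||^2` subject to `w >= 0`, `sum(w) = 1`, where `R` holds purified
reference profiles over marker probes. The constrained problem is solved as
non-negative least squares (Lawson–Hanson, via `pracma::lsqnonneg`) on a
system augmented with a heavily weighted sum-to-one row (weight 1e4),
followed by renormalization; the result satisfies the simplex constraints
to well below 1e-8. The full two-stage Houseman EWAS model is not
reproduced — only the projection that produces per-sample proportions for
use as covariates. Real flow-sorted references are external data; the
package ships a generator (`simulateCellReference()`) producing
block-structured synthetic references with the six blood leukocyte labels
(CD8T, CD4T, NK, Mono, Bcell, Neu).

## Age-related DMP calling

`fitSiteModels()` fits, per probe, ordinary least squares of beta on age
plus covariates (sex coded 0/1, BMI, cell proportions — note that because
proportions sum to one, callers must drop one cell type, conventionally
neutrophils, to keep the design full-rank; the function refuses collinear
designs by name). All probes share a design matrix, so the fit is one QR
decomposition applied to the whole matrix. The reported slope is the age
coefficient in beta units per year, with its two-sided t-test p-value.

A deliberate divergence: the classical workflow uses limma's moderated
t-statistics. This package uses exact per-probe OLS instead, because the
defining thresholds of the analysis are the effect-size and FDR gates, not
the variance moderation, and exact OLS admits an external
normal-equations oracle that the test suite checks to 1e-8. Moderation is
an empirical-Bayes refinement that mostly matters at small n; a moderated
variance estimator can be slotted in front of `callDmps()` without touching
the gate logic.

`callDmps()` applies Benjamini–Hochberg across all tested probes and the
joint gate: adjusted p < 0.01 **and** |slope| > 0.002 beta/year. Both
cutoffs are arguments; 0.01 is the default (an alternative convention of
0.05 appears in some published analyses of the same design, so the
threshold is exposed rather than hard-coded). Direction is the slope sign
among passing probes. `contextComposition()` tabulates per-direction
proportions over the island and feature enumerations;
`genomicDensity()` counts DMPs in half-open 1-Mb bins
`[k*binSize, (k+1)*binSize)` per chromosome — plain integer arithmetic,
since fixed-width binning needs no interval machinery.

## Sliding-window change-point scan

To find *ages* at which the methylome changes most (rather than probes that
change linearly), `slidingWindowDmp()` evaluates a contrast at window
centers spaced `parcel` years apart (default 5): samples one window below
the center (`age` in `[c - window, c)`) versus one window above
(`[c, c + window]`), per-probe Welch t-tests, BH across probes within the
center, and a count of significant probes split by the sign of the
old-minus-young difference. This dichotomize-at-the-center contrast is the
DE-SWAN scheme. An alternative reading — center window versus flanking
parcels — was considered and rejected: a step change at the center age
contaminates both of that scheme's groups equally, so the scheme cannot
detect a change point located *at* a center, which is precisely the
signature the scan exists to find. The implemented contrast detects a
planted step at its nearest center (tested), and on null cohorts its counts
stay at the false-positive floor. Centers lie on the parcel grid and
require at least `minPerGroup = 2` samples per side; degenerate probes
(zero variance in both groups) get p = 1.

## Methylome–transcriptome integration

`selectFeatureProbes()` keeps DMPs that can plausibly act on transcription:
distal (enhancer-like) probes plus promoter classes TSS200/TSS1500.

`probeGenePairs()` tests each candidate probe–gene pair (candidates = the
10 nearest genes up- and downstream by signed rank distance) with the
extreme-group design: samples are ranked by the probe's beta; the top and
bottom `q = 0.20` fractions (size `ceiling(q n)`) form groups M and U; a
one-sided Mann–Whitney test asks whether expression in M is *lower* than in
U. One direction serves both pair classes, because both encode
anti-correlation of methylation and expression: a hypermethylating DMP with
falling expression ("repressed") and a hypomethylating DMP with rising
expression ("activated") each predict lower expression in the
high-methylation extreme. The class label, not the test direction, follows
the DMP direction.

Significance is calibrated empirically because nearby-gene expression is
not exchangeable across pairs: per probe, the identical test is rerun on
`nPerm` genes drawn at random from the expression matrix (same M/U
groups), and the empirical p is the add-one rule
`(1 + #{null p <= observed p}) / (1 + nPerm)` — never zero, and equal to
the exhaustive-enumeration p when the null pool enumerates all labelings
(tested on a 4-vs-4 toy against all C(8,4) = 70 assignments). The
permutation unit (random genes, same probe) and `nPerm` are this package's
documented defaults, not a claim about any particular published pipeline;
random probes with the same gene is the other defensible unit, and both
share one property worth knowing: when a large fraction of the feature
space is genuinely age-coupled, the null is contaminated and empirical
p-values become conservative. The generator therefore builds expression
fixtures in which linked genes are a small minority of the transcriptome,
which is the realistic regime.

`motifEnrichment()` consumes a precomputed motif-by-probe occurrence table
(occurrences within ±250 bp of each probe; sequence scanning against a
motif database is out of scope, and a fixture generator plants known
enrichment for testing). Per motif it forms the 2×2 table of motif presence
in the probe set versus the remaining background, computes the odds ratio
with Haldane–Anscombe 0.5 correction when a cell is zero (a motif present
or absent in *every* probe has no measurable association and is fixed at
OR = 1 with a vacuous CI), a Wald 95% CI on the log odds ratio, and a
Fisher exact p, BH-adjusted once across motifs. Enrichment requires all
three gates: in-set count ≥ 10, CI lower bound > 1.1, adjusted p < 0.05.
`tfMethylationCorrelation()` then correlates the per-sample mean beta over
a motif's probes with the expression of the motif's TF gene (Pearson,
two-sided).

## Epigenetic clocks

Chronological age enters the regression through the piecewise transform

$$f(\mathrm{age}) = \begin{cases}
(\mathrm{age}+1)/(A+1) - 1 & \mathrm{age} \ge A\\
\log\!\big((\mathrm{age}+1)/(A+1)\big) & \mathrm{age} < A
\end{cases}$$

with adult age `A = 20`; it is continuous (and zero) at the knot and its
exact inverse (`t >= 0 -> 21 t + 20`; `t < 0 -> exp(t + log 21) - 1`) maps
predictions back to years. The log branch compresses the rapid epigenetic
drift of development so one linear model spans the age range.

`trainClock()` fits, for each alpha in 0.1–0.9, an elastic-net path with
lambda chosen by internal 10-fold cross-validation on the training samples
(fold assignment seeded), and scores each candidate by MAE on a held-out
validation set. The split is stratified by sex and age decile
(`stratifiedSplit()`, default 50/50). Model selection MAE is computed in
years, after the inverse transform — ages are what the clock is for, and an
error of 0.1 on the transformed scale means different things at 25 and at
85; scoring on the transformed scale remains available by setting
`transform = "identity"` on pre-transformed targets. The winning
alpha/lambda model is returned with its nonzero CpG weights and the
training-set mean beta of each model probe; `predictAge()` uses those means
to impute model probes missing from a new matrix (the standard recourse
when array versions differ), reports how many were imputed, and refuses to
predict when none are present. Published clocks can be applied through the
same path via `importClockCoefficients()`; their coefficient lists are
user-supplied files, not vendored data.

`stepwiseReduce()` builds compact panels by backward elimination from an
OLS fit on a starting probe set: at each step, every single deletion is
scored and the probe whose removal least degrades the criterion is dropped,
until `stopK = 5` remain. The criterion is AIC by default (BIC available);
"contribution" in backward stepwise regression is not uniquely defined, so
the choice is stated here and verified structurally — the test suite checks
the elimination order against an independent brute-force search rather than
asserting any particular five CpGs.

`trainMultimodalClock()` targets multi-modal biological ages (composite,
facial, transcriptomic, …) with the same elastic-net protocol but
leave-one-out evaluation: per alpha, each sample is predicted by a model
trained on all others; the LOO predictions are scored against the target;
the best alpha is refit on all samples. Multi-modal targets are used on
their own scale (identity transform): the piecewise transform exists to
linearize *chronological* age, and these targets are already age-scaled
estimates. Cross-validation folds are assigned by a deterministic function
of the sample-id set, which makes each LOO prediction invariant to the
ordering of the other samples — a property the tests check.

## Pace of aging

`computeAgePace()` regresses predicted on chronological age by OLS and
takes the residual as the pace: positive = epigenetically older than the
cohort trend predicts. Residuals sum to zero and are exactly orthogonal to
chronological age, so pace is uncorrelated with age by construction —
comparisons between pace groups are therefore not age comparisons in
disguise. The regression is fit on whichever evaluation subset the caller
provides (typically the validation set); that choice is an input, not
hard-coded. `classifyPaceGroups()` labels the top and bottom
`ceiling(q n)` residuals (default q = 0.20) accelerators and decelerators,
ties broken deterministically by sample id.

Group comparisons follow the modality: Welch t-tests for numeric
phenotype/lifestyle features; chi-squared for dichotomous features, with a
Fisher exact fallback when any expected cell is below 5 (flagged in the
output). `differentialOmics()` handles protein, metabolite and transcript
matrices with one contract: keep features detected in more than 2/3 of the
compared samples, optionally divide by each sample's mean abundance and
log2-transform (`normalize = "sample_mean_log"`, which makes results
invariant to global scale), Welch t-test on complete cases plus log2 fold
change, pass when p < 0.05 and |lfc| > 0.5. For transcripts the p gate uses
BH-adjusted values. This is deliberately simpler than the specialized
tools for each modality — no negative-binomial count model, no
variance-stabilizing transform, no KNN imputation of missing proteins;
complete-case testing per feature replaces imputation. The shared contract
is the point: one documented rule, testable against planted effects.

## The synthetic-cohort generator

`simulateCohort()` produces the conditions the analysis assumes, with truth
stored in `rowData`:

- ages uniform on 20–87 (uniform, not demographically matched, to maximize
  regression power at modest n);
- 5% of probes hypermethylate and 10% hypomethylate with age, with slope
  magnitudes uniform on 0.002–0.008 beta/year — bracketing the calling
  threshold so recovery is a real test, not a giveaway;
- hypermethylating probes preferentially sit in island/TSS contexts and
  hypomethylating probes in the open sea, so the context-composition
  machinery has a planted signal;
- baselines are drawn per island class (islands low, open sea high,
  Beta-distributed) to mimic the bimodality of real methylomes; with the
  10%-down/5%-up imbalance this yields declining mean methylation and
  rising entropy with age;
- per-sample blood-cell proportions are Dirichlet-like; with
  `confoundCells = TRUE` the neutrophil mean rises and T-cell means fall
  with age (|r| > 0.3), and a small set of *cell-driven* probes responds to
  a cell proportion only — the planted confound that covariate adjustment
  must remove;
- noise is Gaussian on the beta scale (default SD 0.03, which puts clock
  errors in the a-few-years regime at n = 250), clipped to [0, 1] with the
  clipped fraction reported. Logit-scale noise would avoid clipping but
  complicates the exact-slope examples used as oracles; the clipping
  fraction stays around a percent at default settings.

`simulateExpression()` couples a linked gene to each non-null probe
(anti-correlated, both pair classes) among a majority of noise genes, and
emits the candidate-gene table with the true gene hidden at a random rank.
`simulateCellReference()`/`simulateMixtures()` provide deconvolution truth,
`simulateMotifTable()` plants motif enrichment, `simulateAbundances()`
plants omics group shifts. Identical seeds give bit-identical output
everywhere.

What the generator does **not** emulate: probe-type chemistry and
normalization artifacts, batch effects, sex chromosomes, spatially
correlated probes (each probe's noise is independent), count-distributed
transcripts, and demographically realistic age/sex structure. Passing tests
therefore demonstrate that the implementations honor their contracts and
recover planted structure under the stated noise model — not that any
particular biological finding generalizes.

## Numerical choices and problem sizes

Collinearity in site models is refused at QR rank deficiency or condition
number above 1e10. Elastic nets are solved by glmnet (the de-facto standard
coordinate-descent implementation) with seeded or deterministic fold
assignments. Clock JSON uses 17 significant digits, which round-trips
doubles losslessly; the tests assert bit-identical predictions after a
write/read cycle. Degenerate inputs are handled explicitly: zero-intensity
probes give missing betas, constant genes are skipped in pairing, constant
predictions flag an undefined correlation, zero-variance features are
skipped with a message.

The bundled demo configuration runs the full pipeline at 250 samples ×
2000 probes with 100 permutations and a 20-sample LOO clock — sizes chosen
so an end-to-end run completes in well under a minute per stage on a single
CPU while leaving every statistical property measurable. The acceptance
script uses 250 × 2000 cohorts for DMP/clock quantities and a 100 × 100
cohort with a 300-gene noise transcriptome for pair recovery. Defaults in
`epiageDefaults()` scale to full arrays: the site-model fit is a single QR
for any number of probes, and glmnet handles hundreds of thousands of
predictors.

## Known limitations

- OLS rather than moderated statistics at very small n (see above).
- The deconvolution is the projection step only; it inherits whatever bias
  the reference panel carries.
- Empirical pair p-values are conservative when much of the transcriptome
  is age-coupled (contaminated null).
- The stepwise panel criterion (AIC) and the permutation unit for pairing
  are reasonable defaults among several; both are arguments and both are
  tested against their own contracts, not against any published site list.
- Sex-stratified X/Y analyses, DMR (region-level) calling, pathway
  enrichment and count-model differential expression are out of scope.
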