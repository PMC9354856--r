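---
title: "Methods: the raidr virtual microarray"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the raidr virtual microarray}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and model

`raidr` implements a quantitative in vitro to in vivo extrapolation
(QIVIVE) system for transcriptomics: one penalized linear model per
gene, predicting the gene's in vivo log2 fold change in rat liver from
(a) curated and normality-transformed chemical descriptors and (b) the
in vitro log2 fold changes of all modeled genes in primary hepatocytes.
The collection of fitted models — the *virtual microarray* — can then be
applied to substances for which only chemical structure (and optionally
in vitro data) is available, and the predicted expression profiles fed
into the same read-across analytics (PCA, loading rankings, biosimilar
neighbors) that a measured in vivo profile would support.

The core assumptions are:

* per-gene effects are additive and linear in the feature set on the
  log2 scale; interactions and saturation are not modeled;
* the in vitro feature block may carry signal for only a subset of
  genes — the elastic net's L1 component performs that selection per
  gene rather than assuming a fixed in vitro/in vivo gene pairing;
* replicate noise is approximately lognormal, so group comparisons are
  performed on log2 signals;
* unreliable measurements are best handled by deterministic shrinkage
  of the fold change toward 1 (no differential expression) before
  modeling, rather than by discarding cells or imputing.

# Preprocessing rules and their parameters

**Fold change.** Per substance and gene, the ratio of the treated-group
mean signal to the control-group mean signal (MAS5-scale expression
units). The replicate design is three treated + three control samples
in vivo and two + two in vitro; readers enforce these counts.

**Welch p-values.** A two-sample unequal-variance t-test on the log2
replicate signals of each cell. The underlying source does not name its
test; we chose Welch on log signals because variances routinely differ
between treated and control groups and signals are lognormal-ish. When
both groups are exactly constant the test is undefined and the p-value
is `NA`; an `NA` p-value never triggers a p-based shrinkage rule. The
test is a configuration point of `compute_fold_change()` in the sense
that p-value matrices can also be supplied externally via
`fold_change_matrix()`.

**Reliability adjustment** (`adjust_fold_change()`). Exactly one rule
fires per cell, the most severe applicable:

1. all detection calls Absent (treated and control, and — when paired
   matrices are adjusted with `apply_adjustment()` — in both the in
   vivo and the in vitro source): the fold change becomes 1;
2. p > 0.1: the increment above/below 1 shrinks to one fourth;
3. treated Absent calls at or above the source threshold (2 of 3 in
   vivo, 1 of 2 in vitro), or 0.05 <= p <= 0.1: the increment is halved;
4. otherwise the value is untouched (bit-exactly — the identity branch
   performs no arithmetic).

Down-regulated cells (F < 1) shrink in reciprocal space,
`F' = 1 / (1 + (1/F - 1) k)`, so shrinkage is symmetric in the sign of
the log2 fold change; the source rules are only exemplified for F > 1
and this symmetric convention is ours. Rule severity ordering (1 >
quarter > half > none, no compounding) is likewise a convention: no
worked example in the source ever compounds two rules.

**Sample weights** (`assign_weight()`). Weight 1.5 at a >= 1.5-fold
change and 2 at >= 4-fold, applied to the magnitude `max(F, 1/F)` so
down-regulation is weighted symmetrically. Weights are computed from
the *target* gene's adjusted in vivo fold change — whether the
thresholds were meant per target gene or per whole sample is not
stated; per target gene matches a per-gene regression.

**Gene filter** (`filter_genes()`). A gene is kept if at least 10
substances show a >= 1.5-fold magnitude change in the adjusted *in
vivo* matrix (the modeling target; counting in vitro responses instead
is possible but would retain genes with no signal in the target).

**Descriptor curation** (`curate_descriptors()`). Drop order: columns
with any missing value, constant columns, then a left-to-right greedy
scan dropping the later column of any pair with |Pearson r| > 0.95
against an already-retained column. Greedy left-to-right retention is
order-dependent; fixing it to input column order makes curation
reproducible. The operation is idempotent.

**Normalizing transforms** (`normalize_descriptors()`). Candidates per
column: Yeo-Johnson (always applicable; lambda by maximum likelihood on
[-5, 5]), Box-Cox and log10 (strictly positive columns), square root
(nonnegative), arcsine of the square root (values in [0, 1]), identity.
The winner minimizes a Pearson chi-squared goodness-of-fit statistic of
the standardized transformed values against N(0, 1), with
`ceiling(2 n^(2/5))` equiprobable classes, divided by its degrees of
freedom `classes - 1 - p` where `p` counts estimated parameters (2 for
standardization, plus 1 for a fitted Yeo-Johnson/Box-Cox lambda). The
df charge for the fitted lambda is the textbook correction for
goodness-of-fit tests with estimated parameters; without it the
one-parameter families win ties against identity on data that is
already normal, which measurably warps linear relationships downstream.
The fitted pipeline (choices, lambdas, centers, scales) is stored in
the trained bank and replayed verbatim on new substances.

# The model bank

Each gene's model minimizes the weighted elastic-net loss over an alpha
grid (default 0, 0.1, ..., 1) and a 100-point lambda path log-spaced
over four decades down from the data-derived `lambda_max`. Features are
standardized internally (training mean/sd stored in the model);
coefficients are reported on both scales. Cross-validation folds are
substance-level, balanced, drawn once per gene from `seed + gene index`
and shared across the whole grid, so no substance straddles folds and
training is reproducible and parallelizable.

**Solver and lambda convention.** Fitting is delegated to glmnet with a
precomputed path. glmnet parameterizes the quadratic penalty relative
to the standardized response, i.e. the effective L2 strength is
`lambda (1 - alpha) / sd_w(y)` while the L1 strength is `lambda alpha`
exactly. Because lambda is always selected by cross-validation over a
data-derived path, the explored model family is identical under either
labeling; the tests verify the fitted coefficients against a
closed-form weighted ridge solve in this documented convention.

**Hyperparameter selection.** The default is the one-standard-error
rule: locate the CV-MSE minimum over the (alpha, lambda) grid, then —
within the winning alpha — move to the largest lambda whose CV MSE is
within one standard error (over folds) of the minimum. We chose the
parsimonious rule deliberately: minimum-CV elastic nets are known to
over-select, and this bank exists as much for interpretation (which
descriptors and which in vitro signals drive a gene; the in vitro
importance ranking) as for raw prediction. On synthetic data with
planted sparse effects, minimum-CV selection roughly triples the number
of false-positive coefficients while improving fit only marginally.
`selection = "cv_min"` restores plain minimization.

**Degenerate targets.** A zero-variance target yields a flagged null
model (all coefficients 0, intercept = weighted mean); prediction then
returns the constant.

**Numerical tolerances.** CV fold fits run at glmnet `thresh = 1e-10`
(only the ranking of grid points matters); the final fit at the
selected pair runs at `1e-14`, which keeps the coefficients within
about `1e-6` of the closed-form solution on toy problems.

**In vitro importance.** For a fitted model, the sum of absolute
standardized coefficients over the in vitro feature block divided by
the sum over all features; 0 for a null model. "Importance" is not
formally defined in the source material; this standardized-magnitude
ratio is our convention, stated prominently because rankings depend on
it.

**Prediction.** New substances pass through the stored descriptor
pipeline; missing in vitro cells (or wholly absent in vitro profiles)
are imputed with the training median of each gene's in vitro log2 fold
change before the models are applied. Predicting with no in vitro
argument is exactly equivalent to supplying the median profile.

# Read-across analytics

Expression PCA is column-centered and unscaled (descriptor PCA consumes
already-normalized columns); components come from the SVD and each
loading column is sign-fixed so its largest-magnitude element is
positive, making quadrant assignments reproducible across linear
algebra backends. External substances are *projected* onto the training
loadings rather than refit, keeping the training geometry (and the
interpretation of quadrants) fixed; refitting with externals included
is available by simply calling `fit_pca()` on the combined matrix.

Loading length is `sqrt(PC1^2 + PC2^2)`; quadrant rankings sort by it
descending with ties broken by gene id. Principal-component gene sets
take the top and bottom 30 genes by signed loading on each of PC1 and
PC2; their Venn partition across sources (in vivo / predicted / in
vitro) counts every nonempty membership region.

For the RMSE comparison, each source's log2 matrix is z-normalized over
all its pooled entries (per-gene normalization is a reasonable
alternative; pooled matches the idea of removing *distributional*
differences between sources), then per-gene RMSEs against the in vivo
matrix are computed for the predicted and the in vitro source and
compared with Welch's t-test. A zero-variance source is centered but
not scaled. The unit of analysis is the gene (RMSE across substances),
matching the contrast of gene scopes (all genes vs genes whose models
use in vitro data).

PLS-DA is a minimal 2-component PLS1-NIPALS on a centered 0/1 response
with a stratified 70/30 split and a 0.5 decision threshold; it exists
to confirm class separability where PCA is unsupervised, not as a tuned
classifier. Probability ellipses are reported as per-class means,
covariances and 95% chi-squared ellipse axes rather than drawn.

# The synthetic study generator

`generate_study()` emulates the statistical structure the bank assumes,
with every quantity derived from a single seed:

* descriptors: standard normal, plus planted near-duplicate columns
  (r about 0.995), and constant columns to exercise curation;
* a sparse descriptor-to-in-vitro map `A` and descriptor-to-in-vivo map
  `B` (default 10% nonzero entries, effects N(0, 1) on the log2 scale —
  about two-fold effects, typical of strong hepatotoxicant responses);
* an in vitro-to-in vivo coupling `C`, nonzero only for a designated
  "in-vitro-driven" gene subset (default 8 of 20), with coefficients of
  magnitude U(0.8, 1.2) and random sign;
* true fold changes `V = DA + e_vitro`, `Y = DB + VC + e_vivo`
  (noise sd 0.1 each by default);
* replicate signals around per-cell lognormal baselines `2^N(7, 1)`
  (MAS5-scale hundreds), control `baseline * 2^e` and treated
  `baseline * 2^(logFC + e)` with replicate noise sd 0.1;
* Absent calls at a 10% marginal rate with probability decreasing in
  the signal's rank, mimicking MAS5 detection behavior, so the
  flag-based rules engage preferentially at low intensities;
* toxicity labels by thresholding the mean absolute in vivo response at
  the 43% quantile — the toxic fraction of the 115-substance
  hepatotoxicity panel this workflow targets.

What the generator does **not** emulate: probe-level artifacts,
correlated gene modules and pathway structure, realistic descriptor
distributions or chemistry, batch effects, dose-response, and
inter-study heterogeneity. Passing the recovery tests therefore shows
that the pipeline's machinery is correct and well-conditioned under its
own assumptions — not that comparable accuracy would be achieved on
real toxicogenomics data.

**Ground-truth support.** For recovery tests, the true feature set of a
gene includes the descriptors with nonzero direct effect and, for
driven genes, both the gene's in vitro feature and the descriptors
driving that in vitro signal (`truth_support()`): since `V` is a
near-deterministic linear function of those descriptors, a model using
either route has identified the same planted mechanism, and penalized
regression may legitimately prefer either.

# Problem sizes and runtime choices

The shipped tests and examples run at desk scale by design: the default
synthetic study uses 80 substances, 20 genes and 30 descriptors (the
recovery suite trains banks at these sizes in tens of seconds), the
serialization and prediction tests use a 30-substance, 6-gene study,
and the oracle comparisons use problems of at most 15 x 5. The
architecture has no intrinsic scale limit — a real application with
about a hundred substances and about 1,600 retained genes multiplies
the per-gene fitting cost linearly, and genes are embarrassingly
parallel.

# Known limitations

* The p-value treatment assumes replicate-level data; precomputed
  fold-change matrices without p-values simply never trigger p rules.
* The gene filter and weights are computed from the in vivo matrix
  only; alternative policies are arguments, not defaults.
* Transform selection is per-column and univariate; it cannot repair
  joint non-normality, and monotone-but-nonlinear transforms slightly
  distort linear relationships that were exact in the raw features.
* The importance score ignores correlation between the descriptor and
  in vitro blocks: when both carry the same signal, credit assignment
  between them follows the penalty's preference, not causality.
* PLS-DA is deliberately minimal (fixed components, single split); it
  is a sanity check, not a validated classifier.
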