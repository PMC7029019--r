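---
title: "Statistical methods in ifomics"
author: "ifomics authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical methods in ifomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ifomics)
```

# Scope

`ifomics` implements the statistical core of a two-group multi-omics study
design in which an intervention (for example, intermittent fasting in
diabetic mice) is read out simultaneously through hippocampal gene
expression, gut microbial composition and microbial metabolites. The package
covers four layers:

1. **Compositional microbiome statistics** — cumulative sum scaling (CSS),
   rarefaction, the centered log-ratio (CLR) transform, Bray–Curtis
   dissimilarity, principal coordinate analysis (PCoA), PERMANOVA, partial
   constrained analysis of principal coordinates (CAP/db-RDA) and ANCOM
   differential abundance.
2. **Per-block predictive validation** — PLS-DA inside repeated double
   cross-validation (rdCV) with a permutation gate.
3. **Multi-block sparse discriminant integration** — a sparse generalized
   canonical correlation (sGCCA) model with exact per-block cardinality
   (keepX), cross-block feature links and clustered-image-map orders.
4. **Co-expression modules** — signed topological-overlap networks, static
   tree-cut modules, module eigengenes and conjunctive hub-gene selection.

A synthetic multi-omics generator with a planted shared latent factor makes
every stage testable without any external download.

# The synthetic generator and its defaults

Each sample carries a latent factor $u_i = \mu_{g(i)} + \varepsilon_i$,
$\varepsilon_i \sim N(0,1)$, with group means $\pm\,\delta/2$ where
$\delta$ is `group_effect`. Continuous features are
$x_{ik} = b_k + \gamma_k u_i + e_{ik}$ with $e_{ik} \sim N(0,
\sigma^2_\text{noise})$; metabolite intensities are exponentiated so they
stay positive (log-normal-like). OTU counts follow a logistic-normal /
multinomial model: per-sample log-abundances
$\eta_{ij} = b_j + \gamma_j u_i + \epsilon_{ij}$ are soft-maxed to a
composition and counts drawn from a multinomial with a log-normal library
size. The logistic-normal/multinomial form (rather than
Dirichlet-multinomial) was chosen because a single latent factor then
induces cross-block correlation in exactly the way the integration model
assumes.

Default shapes mirror the motivating study design: groups of 10 and 11
samples; 36 genes and 26 metabolites with 10 informative features each; 50
taxa of which 17 respond to the latent factor (in both directions);
per-feature loading 2 and unit noise. Library sizes are log-normal with
mean 35,000 so the conventional rarefaction depth of 28,257 is feasible on
defaults. A cyclic timepoint covariate shifts all baselines, providing a
nuisance term orthogonal to group for the partial-CAP workflow, and
per-sample phenotypes (fasting glucose in mg/dL, insulin in mU/L,
bodyweight) carry a group shift so the HOMA-IR formula and CLR–phenotype
correlations can be exercised.

`group_effect` defaults to 4 latent-SD units. Because every informative
feature shares the same latent factor, the best attainable classifier works
on $u$ itself and its error is $\Phi(-\delta/2)$ — about 2% at
$\delta = 4$. That is the "near-separable" regime reported for studies of
this kind, where each omics block predicts treatment status with 90–100%
accuracy; weaker settings are a parameter away (`group_effect = 0` gives
the calibration null used throughout the tests). Effect sizes of the real
study are unknown; these defaults are explicit modelling choices, not
estimates.

What the generator does *not* emulate: sequencing-read noise, chimeras,
taxonomy, batch or injection-order drift, overdispersion beyond the
logistic-normal noise, and block-specific missingness. Passing tests
therefore demonstrate correctness of the statistical machinery under the
stated generative model, not robustness to every artefact of real data.

The planted truth (`true_model`) is stored in a separate sub-record that
analysis stages never read; only tests and the recovery reports touch it.

# Preprocessing conventions

* **CSS**: the scaling factor of sample $j$ is the sum of its counts up to
  the `quantile` (default 0.5) of its positive counts, computed with R's
  default type-7 quantile; values are scaled by a constant (default 1000).
  The adaptive-quantile variant of the original method is intentionally
  omitted — the quantile is an explicit knob instead.
* **CLR**: pseudocount 1 by default (configurable); exact scale invariance
  holds only as the pseudocount tends to 0, which the tests check.
* **Autoscaling** uses the sample standard deviation (n − 1 denominator);
  centering/scaling parameters are stored so held-out samples can be
  projected with the training parameters (`apply_autoscale()`).
* **Expression filter**: strictly greater than the threshold (default 1,
  i.e. FPKM > 1) in at least `min_samples` (default 10) samples.
* **Rarefaction** draws without replacement (multivariate hypergeometric,
  via `vegan::rrarefy`); samples below depth are dropped with a warning
  rather than failing a run.

# rdCV PLS-DA

PLS-DA is NIPALS PLS2 on the one-hot class indicator; X is centered and
unit-variance scaled with training data only. The rdCV framework uses a
stratified outer loop (default 7 folds) for testing and an inner loop
(default 6 folds) that tunes the component count (1..`max_components`,
default 3) to minimum *balanced* misclassification — balancing protects the
10-vs-11 design; plain error is available by flag. Ties in tuning resolve
toward fewer components. The outer loop is repeated (default 200 times);
class probabilities are defined as assignment frequencies across
repetitions — matching the per-repetition dots averaged into large dots in
swim-lane displays — and accuracy is correctly-predicted samples over total
samples using the repetition-averaged assignment. The prediction rule is
the maximum predicted indicator ("max dist"); nearest-centroid is available
by flag. Ties in prediction break deterministically toward the first class.

The permutation gate refits rdCV on label-shuffled data (default 1000
permutations at 1 repetition each, a tractability compromise that is itself
configurable) and reports both the +1-corrected empirical p-value and a
one-sided t comparison of the observed accuracy with the permuted
distribution.

Fold counts are not inherited from any published configuration (none is
printed for this design); 7/6 keeps every outer-training class large enough
for stratified inner folds at n = 21.

# Multi-block sparse integration

The integration model maximizes the design-weighted sum of covariances
between one score per block and the response score,

$$\max \; \sum_{a<b} c_{ab}\,\mathrm{cov}(X_a w_a, X_b w_b)
 \;+\; \sum_b \mathrm{cov}(X_b w_b, Y v), \qquad
 \lVert w_b \rVert = 1,\; \lVert w_b \rVert_0 \le \text{keepX}_b,$$

with the *full* design ($c_{ab} = 1$) by default. Each block-coordinate
update is the design-weighted sum of covariances with the other blocks'
scores, hard-thresholded to the keepX largest absolute entries and
renormalized. Hard cardinality (rather than a continuous L1 path)
reproduces keepX semantics exactly: the fitted model has exactly keepX
nonzero loadings per block per component, with ties broken by feature
index. Because each update maximizes the objective in one block holding
the rest fixed, the objective is non-decreasing over iterations; this is
asserted on every fit. Initialization from each block's dominant singular
vector makes fits deterministic without a seed. Convergence is max weight
change < 1e-6 or 100 iterations, with a warning (plus diagnostics) on
non-convergence.

With a single block, a response-only design and full keepX, the update
equations collapse to NIPALS PLS2, and the first component equals
`plsda_fit()`'s to machine precision — later components can differ because
the response block is deflated by its own score rather than the X-score.
keepX tuning is coordinate-wise over blocks in input order against k-fold
(default tenfold) cross-validated misclassification, ties toward the
smallest keepX. Prediction is per-block regression followed by a majority
vote, ties broken by averaged predicted indicators.

Cross-block "circos" links are Pearson correlations between selected
features on the autoscaled data at a threshold (default 0.7 — a display
convention, not an inferential cutoff), and the clustered image map uses
Euclidean distance with complete linkage on both axes.

# Microbiome statistics

PCoA eigendecomposes the Gower-centered $-D^2/2$ matrix; negative
eigenvalues (expected under Bray–Curtis, which also need not satisfy the
triangle inequality) are reported and excluded from coordinates — no
Cailliez/Lingoes correction, preferring transparency over silent
adjustment. PERMANOVA uses Anderson's pseudo-F on sums of squared
distances with whole-sample label permutation and the +1 correction, so
p = 0 is impossible. An explicit permutation matrix can be supplied, which
the tests use for exhaustive enumeration at n = 4.

Partial CAP embeds the distance matrix on its positive PCoA axes, regresses
out the condition (nuisance) design, and projects the residual coordinates
onto the condition-residualized constraints. Inertia fractions therefore
satisfy conditioned + constrained + residual = 1 exactly on the embedded
space. Significance uses Freedman–Lane-style permutation of reduced-model
residuals (raw permutation by flag). Constraints fully absorbed by the
condition yield constrained variance 0 with a warning; partial rank
deficiency is an error.

ANCOM tests every pairwise log-ratio (pseudocount 1) for a location shift —
Wilcoxon rank-sum for two groups, Kruskal–Wallis otherwise — BH-adjusts
within each focal taxon at level alpha (0.05) and counts rejections into
the W statistic; detection requires W ≥ 0.7·(m − 1). These defaults follow
the original ANCOM publication's common configuration; the variant and
cutoff used by any particular study are rarely printed, so module
membership of real-data results is not claimed.

# Co-expression modules

The signed adjacency is $a_{ij} = ((1 + r_{ij})/2)^\beta$ (unsigned
$|r|^\beta$ by flag), the topological overlap is
$\Omega_{ij} = (L_{ij} + a_{ij}) / (\min(k_i, k_j) + 1 - a_{ij})$, and
modules come from average-linkage clustering of $1 - \Omega$ with a
*static* branch cut — dynamic tree cutting is deliberately out of scope, so
the cut height and minimum module size are explicit parameters rather than
adaptive. The soft threshold is chosen as the smallest power whose log-log
connectivity regression reaches R² ≥ 0.8 (argmax otherwise). Module
eigengenes are first principal components of standardized module
expression, sign-oriented to correlate positively with the module mean;
hub genes must satisfy all three published-style criteria simultaneously:
kME > 0.8 in their own module, |trait correlation| > 0.85, and BH-adjusted
trait-correlation q < 0.01. Network edges are exported above weight 0.4.
With a 36-gene panel the defaults for module detection are scaled down
(minimum size 5) — the classical minimum of 30 presumes genome-wide input.

# Pipeline reproducibility

`run_pipeline()` executes per-block validation before integration, then
the microbiome and co-expression suites, writing TSV artifacts plus a JSON
manifest containing the config snapshot, per-stage seeds and MD5 checksums.
Per-stage seeds derive from the global seed by hashing the stage name, so
adding a stage does not shift the randomness of others; two runs with the
same config and seed are byte-identical. The OTU block enters the
integration CLR-transformed by default (CSS relative abundances by flag),
and metabolite intensities are log-transformed before autoscaling by
default, since the generator (and typical acquisition) produces log-normal
intensities and the integration model is correlation-based. The planted
truth is never read by any analysis stage.

# Problem sizes used in validation

The bundled checks run the generator's default 21-sample study: rdCV at 20
repetitions for the power check (the full profile of 200 repetitions and
1000 permutations runs in the acceptance script), permutation-null
calibration on 200 simulated null datasets at 99 permutations each,
integration recovery over 20 seeds, ANCOM over 50 simulations, and
exhaustive PERMANOVA enumeration at n = 4. These sizes were chosen to make
the Monte-Carlo bounds sharp while keeping a full validation run on one
CPU comfortably short.

# Known limitations

* Classification only: regression-mode and multi-level PLS are out of
  scope, as are >2-class designs beyond indicator coding.
* UniFrac is not computed (tree-dependent); precomputed distance matrices
  can be supplied to the ordination and permutation tests instead.
* PCoA negative eigenvalues are dropped, which slightly understates total
  inertia for strongly non-Euclidean dissimilarities.
* The ANCOM variant and W cutoff are configurable approximations of an
  under-specified procedure; real-study membership lists are not
  reproduced.
* Module detection uses a static cut; very unequal module densities may
  merge or split relative to dynamic cutting.
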