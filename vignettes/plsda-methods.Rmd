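---
title: "PLS-DA of inflammatory biomarker panels: model, validation and design notes"
author: "gaitPLSDA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{PLS-DA of inflammatory biomarker panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gaitPLSDA)
```

## The problem

Chronic low-grade inflammation ("inflammaging") and declining physical
performance are both hallmarks of aging, but single inflammatory mediators
correlate only weakly and inconsistently with function. A multivariate view
asks instead whether a *pattern* across a panel of circulating markers
separates older adults with preserved gait speed (normal walkers, NW,
>= 0.8 m/s over 4 m) from slow walkers (SW). The statistical obstacles are
the usual ones of multiplex panels: more variables than would be comfortable
for the sample size, strong inter-marker correlation, heterogeneous units
(serum cytokines in pg/mL next to plasma adhesion molecules in ng/mL), and a
small, imbalanced cohort (27 vs 11 in the motivating design).

`gaitPLSDA` implements the full inference pipeline for this setting:
partial least squares discriminant analysis (PLS-DA) with variable
importance in projection (VIP) marker selection, double cross-validation
for honest complexity selection and error estimation, and permutation
tests of three classification figures of merit. A synthetic-cohort
generator reproduces the statistical structure of such panels so that
every stage is testable without access to individual-level data.

## The model

### PLS1 regression

With $X$ the $n \times p$ matrix of marker concentrations and $y$ a
response vector, PLS regression seeks coefficients $B$ with $y = XB$, but
builds them through a low-dimensional projection: scores $T = XR$ lie
along latent variables (LVs), directions of maximal covariance between the
$X$ block and $y$; the response is predicted from the scores as
$y = Tq^\top$, and the two maps combine into $B = Rq^\top$. Because $T$
has few, mutually orthogonal columns, the regression is well-posed even
when $p > n$ or predictors are collinear — exactly the regime of
biomarker panels.

The engine uses NIPALS for a single response, deflating $X$ only. The
projection matrix is recovered as $R = W(P^\top W)^{-1}$ from the weight
and x-loading matrices; for a single response the coefficient vector $B$
is algorithm-invariant, but the intermediate $W$, $P$, $T$ follow the
NIPALS scaling convention (unit-norm weight vectors), which this package
documents as its own choice rather than an inference about any particular
prior implementation.

Preprocessing defaults to autoscaling — per-column mean-centring and
unit-variance scaling — estimated on the training partition only and
applied frozen to anything evaluated. Without scaling, the highest-
concentration marker (sVCAM-1, hundreds of ng/mL) would dominate every
covariance and the pg/mL cytokines would be invisible. The response is
centred but not scaled; predictions are invariant to response scaling in
PLS1.

Numerical edge cases: requesting more LVs than $\min(n-1, p)$ is an
error; a weight vector whose norm falls below $10^{-12}$ of the first
LV's terminates extraction early with a warning (the model keeps the
achieved count); a zero-variance column under autoscaling is an error
naming the column; a constant response yields the zero-coefficient model
predicting the constant.

### Discriminant layer

Class membership is dummy-coded: NW $\mapsto 1$, SW $\mapsto 0$. A
predicted response above 0.5 classifies a subject as NW; everything else
— including values below 0, above 1, or exactly at 0.5 — as SW. The tie
rule is a deliberate closure: only the strict "greater than 0.5" branch
is conventionally specified, so the complement is assigned
deterministically to the negative class. Swapping the two codes flips
every coefficient sign and reflects predictions about the threshold but
leaves the induced partition and all VIP scores unchanged (a tested
invariant).

### VIP marker selection

Variable importance in projection uses the cumulative Wold formulation:

$$\mathrm{VIP}_j \;=\; \sqrt{\,p \cdot \frac{\sum_a \mathrm{SSY}_a\,
(w_{aj}/\lVert w_a\rVert)^2}{\sum_a \mathrm{SSY}_a}\,}, \qquad
\mathrm{SSY}_a = q_a^2\, t_a^\top t_a ,$$

the response variance explained by component $a$ weighting that
component's squared normalised weights. The scaling makes the mean
squared VIP exactly 1 over the $p$ markers, which is what licenses the
conventional strict "VIP > 1" selection rule. VIP is computed on the
full-data model at the final complexity (fold-wise VIPs can be obtained
by fitting on folds, but the full-data model is the reported one); the
sign of each marker's regression coefficient is reported alongside —
with NW coded 1, a positive sign means higher concentration in normal
walkers.

## Validation machinery

### Figures of merit

* **NMC** — the number of misclassified subjects.
* **AUROC** — implemented in the Mann–Whitney formulation: the
  probability that a random NW–SW pair is ordered correctly by the
  predicted response, ties counted one half. Under this standard
  convention 0.5 is chance level and values below 0.5 indicate inverted
  ranking; descriptions of AUROC as ranging "from 1 down to 0 = no
  discrimination" conflate the two, and this package follows the
  convention, not the phrasing.
* **DQ²** — discriminant $Q^2 = 1 - \mathrm{PRESS}_D/\mathrm{TSS}$,
  where residuals of predictions that overshoot their class code in the
  correct direction ($\hat y > 1$ for class 1, $\hat y < 0$ for class 0)
  are set to zero: a classifier is not penalised for being "too right".
  With no overshoot DQ² equals the plain $Q^2$; it always dominates it
  and, unlike $R^2$-type quantities, can be negative.

### Double cross-validation

Selecting the number of LVs and estimating the error on the same
cross-validation would be overoptimistic. The double CV separates the
two: an outer loop withholds a stratified external set (default 20% of
each class, at least one subject) that touches neither preprocessing,
selection, nor fitting; an inner stratified k-fold CV (default $k = 6$)
on the remainder selects the complexity minimising the number of
misclassifications (ties broken by lower RMSECV, then by the smaller
count); a model at that complexity is refit on the full remainder.
Correct-classification rates are recorded per class at three levels —
calibration (refit model on its own remainder), internal validation
(inner out-of-fold predictions), external validation (the withheld set) —
and averaged over iterations (default 50). Autoscaling parameters are
re-estimated inside every training partition at every level; stratified
sampling protects the 27:11 imbalance throughout.

Two overall aggregates are always reported, explicitly labelled: the
class-size-weighted overall rate, and the balanced (unweighted class
mean) rate. With imbalanced groups the two differ systematically — under
a pure-noise null the weighted rate concentrates near the majority share
(~71% at 27:11) while the balanced rate is centred at 50% — so the
balanced rate is the right chance-level reference, and the weighted rate
the right "fraction of subjects correctly classified". The final
full-data model is fit at the *modal* inner-selected complexity across
iterations (ties toward fewer LVs), a reconciliation rule this package
fixes explicitly since averaging complexities across resamples has no
canonical definition.

### Permutation tests

Empirical null distributions of NMC, AUROC and DQ² are built by randomly
permuting the class labels (class sizes preserved) and re-running the
whole modelling stage — resampling, complexity selection, fitting —
per permutation. Complexity re-selection inside every permutation is the
default (freezing it via `nLV` is available), since a null distribution
should reflect everything the observed statistic was allowed to adapt.
The p-value is permutation-inclusive, $p = (b+1)/(N+1)$ with $b$ the
count of null merits at least as extreme (NMC: $\le$ observed; AUROC,
DQ²: $\ge$ observed) — a valid finite-sample p that is never zero.
Extremeness directions are fixed per metric; the default merit evaluation
is a reduced-iteration double CV (10 outer iterations) on per-subject
averaged external predictions, keeping $N = 1000$ permutations tractable;
a single k-fold evaluation (`mode = "kfold"`) is provided where speed
dominates.

## The synthetic-cohort generator

The generator emulates the study conditions the pipeline is designed
for: two groups of 27 (NW) and 11 (SW) subjects and 14 markers whose
per-group means and SDs equal the published group-wise concentration
moments of the inflammatory panel (GM-CSF through sVCAM-1). Because the
two groups' target moments differ, the default cohort carries the real
design's group structure — including the directions of the six reported
discriminant markers — without any injected effect.

Marginals default to the lognormal, parameterised by exact moment
matching ($\sigma^2 = \log(1 + s^2/m^2)$, $\mu = \log m - \sigma^2/2$):
several markers have SD larger than the mean (IFN-γ: 6.04 ± 12.28
pg/mL), implying strong right skew and strict positivity that no normal
can honour. A zero-truncated normal family is available for tamer
markers (it cannot match SD ≥ mean; the moment equations are solved
numerically). Dependence is imposed through a Gaussian copula on the
latent normals before the marginal transform, preserving the marginal
moments exactly; the default latent correlation is the identity because
the true inter-marker covariance of the study population is unknown —
the default spec is a stand-in for testing, not a population claim.
Units (pg/mL, ng/mL) are carried as metadata only.

`injectEffects()` adds controlled group separation for parameter-recovery
studies: flagged markers' group means are pushed apart by a stated number
of pooled SDs (half up in NW, half down in SW, sign +1 = higher in NW);
values pushed below zero are clamped at zero, a documented distortion
relevant only for large negative shifts on low-abundance markers.

What the generator does *not* emulate: assay noise floors and limits of
detection, triplicate-well averaging, batch effects, and any real
inter-marker correlation structure. Tests passing on these cohorts
therefore demonstrate the correctness and calibration of the *inference
machinery*, not the reproducibility of any particular cohort's biology.

## Problem sizes and numerical choices in the shipped tests

The test-suite and acceptance-script problem sizes are the package's own
choices, balancing statistical resolution against a desk-scale run:
moment convergence at $10^5$ draws per group; copula checks at $10^4$;
parameter recovery over 20 seeds with 100 subjects per group and six
markers shifted by 1 pooled SD (fit at 5 LVs); null calibration of the
double CV at 50 outer iterations and of the permutation p-values over
200 repetitions of $N = 99$ permutations (k-fold evaluation mode);
the demo pipeline at 25 outer iterations and $N = 199$. The SD-convergence
simulation is restricted to markers with coefficient of variation below 1:
for the heavy-tailed lognormals the sampling error of a sample SD at
$n = 10^5$ exceeds the 2% band by itself, so matching is verified
analytically (exact moment-equation inversion) for every marker instead.

Determinism is part of the contract: every resampling function takes a
seed, consumes a single RNG stream under it, and restores the caller's
RNG state; identical seeds reproduce cohorts, CV results, permutation
results, and every pipeline export byte-for-byte (the timing log is the
one deliberately non-deterministic artifact).

## Known limitations

* PLS1/two-class only: no multi-response PLS2, OPLS, kernel variants, or
  more than two gait-speed categories.
* VIP is reported from the full-data model; fold-wise stability of the
  selection is left to the user (the building blocks are exported).
* The identity-correlation default understates the collinearity of real
  cytokine panels; users with a plausible correlation matrix should
  supply it to `syntheticCohortSpec()`.
* Classification uses the fixed 0.5 threshold of the dummy-coding
  convention; no probability calibration or cost-sensitive thresholds.
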