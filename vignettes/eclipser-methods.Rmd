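---
title: "Methods: density-based elimination of endogenous-like cells"
author: "eclipser"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: density-based elimination of endogenous-like cells}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The modelling problem

Multicolor flow cytometry measures J marker intensities on every cell of
every individual in a cohort. In a responder (patient, challenged subject),
the cells that carry the response are mixed with — and usually outnumbered
by — cells indistinguishable from those of healthy controls. The package
identifies and removes those "normal" cells so that downstream models
describe only response-specific marker co-expression.

The data structure is a *multiset*: one N<sub>i</sub> × J event block per
individual, all sharing a marker panel, with a group label (0 = control,
≥ 1 = responder). All models in the package respect this structure — every
individual contributes equally regardless of how many cells were measured,
and per-individual information (scores, densities, retention) is never
pooled away.

Key assumptions:

* the control group is homogeneous (one shared cell-variability structure
  plus per-individual location offsets);
* the data are compensated; spillover correction is out of scope;
* response-specific variability is expressible in the measured markers
  (linear components of transformed intensities);
* the density comparison happens in the 2-D plane of the first two control
  components, as do the published analyses this design follows; residual
  variation outside that plane is handled by the SPE statistic instead.

## Pre-processing

Raw intensities are variance-stabilized with `arcsinh(x / cofactor)`
(cofactor 5 by default, the standard choice for compensated fluorescence
data) or `log10(x + shift)`, where the default shift `1 - min(0, min(x))`
keeps nonpositive compensated values finite. Each block is centered by its
own per-variable mean: per-individual centering removes sample-to-sample
location offsets, which are nuisance for a cohort-level model. Scaling
divides every variable by one scale vector:

* `over_controls` (control-model default): the per-variable standard
  deviation of the pooled centered *control* events, frozen and reused for
  responder blocks, so responders are expressed in control units;
* `per_individual` (response-model default): each block autoscaled by its
  own standard deviation;
* `over_all`: pooled over every individual.

Standard deviations use the population (1/n) convention; at cytometry event
counts the difference from n−1 is negligible, and the 1/n form makes the
two-point worked example in the unit tests exact. Before any simultaneous
decomposition each block is additionally multiplied by 1/√N<sub>i</sub>,
which equalizes the blocks' total sums of squares — the realization of
"every individual contributes the same amount of information". Scores are
always computed on the *unweighted* blocks, so a cell's coordinates do not
depend on how many cells its donor contributed.

## Simultaneous component model and SPE

The control model is PCA of the stacked, block-normalized control events
under one common loading matrix (SCA with equal patterns): loadings are the
first R right singular vectors of the stacked matrix. SVD is used rather
than an eigendecomposition of the covariance for numerical stability; the
unit tests verify subspace agreement with a dense eigendecomposition oracle
to < 1e-6 rad. Per component, the largest-magnitude loading entry is made
positive, a deterministic sign convention so that serialized models
reproduce across platforms.

The squared prediction error of a cell is the row sum of its squared
residuals — its squared distance from the model plane. Per control
individual, the SPE limit at level α (default 0.05) is the empirical
(1 − α) quantile under the nearest-rank (type 1) convention: deterministic,
no interpolation ambiguity; an interpolated variant is available via
`speLimits(quantileType = "interpolated")`. The pooled limit is the
arithmetic mean of the per-individual limits. Responder cells whose
projection SPE *strictly* exceeds the pooled limit are set aside as
non-normal; ties are not flagged (conservative toward keeping the normal
label).

## Densities and the DbD filter

Score densities are product-Gaussian KDEs evaluated on a common rectangular
grid (default 256 × 256). Bandwidths are selected per axis by the diffusion
/ improved Sheather–Jones fixed point: the binned data are cosine
transformed and the optimal squared bandwidth is the root of the plug-in
fixed-point map; unlike reference rules it does not oversmooth multimodal
score distributions, which cytometry data routinely are. When the fixed
point has no root in the search range (tiny or pathological samples) the
Silverman rule is used with a warning. Whether a 2-D selector or per-axis
selection is the better reading of the published method is open; per-axis
was chosen because the two component scores have different scales, and the
selector is replaceable via the `bandwidths` arguments.

The common grid spans the pooled control scores extended by 3 × the largest
bandwidth, so kernels of extreme cells keep essentially all their mass on
the grid; responders are evaluated on the *same* grid, a precondition for
bin-wise subtraction. Estimation is linear binning followed by zero-padded
FFT convolution; for node-aligned points this equals direct summation to
numerical precision, and the tests hold it to 1e-6 relative against a
double-loop oracle. Densities are renormalized to exact unit mass on the
grid; cells outside the grid are clipped to the boundary with a message.
Pooling control densities averages the per-individual estimates (each
already normalized over its own cell count, so individuals get equal
weight) and renormalizes.

The Difference between Densities of responder *i* is
`DbD = KDE_control_pooled − KDE_responder_i`, the responder density built
from SPE-inlier cells only (outliers are reintroduced after the filter).
Cells are assigned to their *nearest grid node* — the plainest reading of
"binned onto the DbD", and deterministic — and retained iff the DbD there is
strictly negative. Bins at exactly zero (no cells anywhere, or equal
intensity) eliminate their cells; with no minimum-density threshold stated
in the published method, both situations are treated alike, which is
conservative toward elimination. The final retained set is the union of SPE
outliers and DbD-negative cells, with disjoint provenance flags.

## Response model and stratification

Retained cells are re-processed *from raw* with the same transform but
response-side scaling: per-individual autoscaling by default, or `over_all`
(both appear in the published analyses; which fits depends on whether
between-individual location differences are signal). If a responder's
retained cells have a zero-variance marker, per-individual scaling falls
back to `over_all` with a warning rather than dividing by zero. The
decomposition is the same SCA machinery with provenance
`eclipse_general`.

For stratification, each responder's cells are binned onto a common
64 × 64 histogram over the pooled response scores (coarser than the density
grids — raw histograms, not KDEs, are the default distance substrate; a
KDE-vector option exists because the published description can be read
either way), normalized to unit mass and flattened. Pairwise Euclidean
distances (Jensen–Shannon available, since the vectors are probability
masses) feed average-linkage hierarchical clustering. The number of
clusters k is the analyst's choice from the dendrogram; no automatic cut
criterion is imposed. Partial models rerun the response-model pipeline
independently per cluster.

## Component-number validation

Cells are bootstrapped *within* each individual (block sizes preserved) and
the model refitted per replicate; for each candidate R the largest
principal angle between the replicate's first-R loadings and the full-data
loadings is recorded. The largest principal angle is the most conservative
of the R angles — the published account does not say which is meant — and is
invariant to sign flips and within-subspace rotations (tested). As a
numeric default, `chooseComponents()` keeps the largest R whose 95th
percentile angle is ≤ 0.35 rad (≈ 20°); the rule is an invention of this
package (the published criterion is qualitative) and is always overridable.
Note that at R = J the subspace is the whole marker space and the angle is
identically zero, so full-rank candidates are vacuous.

## The synthetic cohort generator

`generateCohort()` draws Gaussian-mixture populations in *transformed*
space — where the models operate — and back-transforms to raw-intensity-like
output, so the pre-processing path is exercised honestly. Per individual it
draws a mean offset (sd 0.15 transformed units, emulating sample-to-sample
shifts that per-individual centering should remove), then cells from the
mixture; responders additionally receive their phenotype's spiked
populations at the stated abundance. Everything is deterministic given the
seed, and ground-truth population labels are returned for
sensitivity/specificity computation.

The frozen `lpsLikeDefault()` design mirrors an endotoxin-challenge study:
7 neutrophil markers, 8 + 8 individuals, 17,500 cells each (the event depth
of that study, ~2.8e5 events over 16 individuals; at much lower depth
single-responder KDE noise, not the method, dominates the rim of the DbD),
bimodal control mixture with two orthogonal co-expression axes
(CD11b/CD11c/CD16 and CD62L/CD32/CD69), and two spiked populations at 15%
abundance with equal-and-opposite in-plane displacements (anticorrelated
CD62L/CD16 phenotypes; balance matters because per-individual centering
couples the spike displacement to the normal cells' position). One spike
also sits 2.0 units off the component plane so the SPE limit catches it;
with the 5% baseline this puts per-responder SPE-flagged fractions near one
sixth by construction. `threePhenotypeDefault()` (8 controls, 9 responders,
3,000 cells) gives each phenotype a symmetric spike pair along a
phenotype-specific direction, so phenotypes stay distinguishable after
per-individual centering.

What the generator does **not** emulate: instrument artifacts (spillover,
debris, doublets, time drift), non-Gaussian population shapes, covariance
differences between individuals, or abundance-only responses (normal cells
increasing in number without changing expression). Passing tests therefore
demonstrate correct mechanics and recovery under the stated generative
assumptions, not performance on real instruments.

## Numerical choices and degenerate inputs

* Quantiles: nearest-rank; ties at the SPE limit and at DbD = 0 eliminate.
* Loadings orthonormality is enforced to 1e-8; score/residual
  reconstruction to 1e-8; density unit mass to 1e-6 (class validity).
* FFT round-off can produce tiny negative density values; they are clamped
  to zero before renormalization.
* Zero-variance markers: an error naming the marker at control fitting; a
  warning plus `over_all` fallback at response fitting.
* A responder with zero retained cells is dropped from the response model
  with a warning; an all-SPE-outlier responder gets an identically-zero DbD.
* Degenerate stratification grids (all cells in one point) are widened by
  ±0.5 score units so binning stays defined.
* Serialization is JSON at full precision (`digits = NA`), round-trip exact
  for loadings, scale vectors and limits.

## Problem sizes in the test suite

Unit tests run on cohorts of 200–4,000 cells per individual, where every
mechanical property (oracle agreement, calibration, invariances) is already
decided; the end-to-end recovery checks use the frozen default designs
(17,500 and 3,000 cells per individual), the sizes at which those designs
are defined. `scripts/acceptance.R` recomputes the headline quantities at
exactly the frozen sizes.

## Known limitations

* The DbD operates in the first two control components; responses living
  mainly in components 3+ reach the retained set only through SPE.
* The pooled control limit assumes comparable SPE scales across control
  individuals; a strongly heterogeneous control group violates the model's
  premise.
* Stratification distances are sensitive to the histogram grid at small
  retained-cell counts.
* The FCS reader covers list-mode FCS 3.0/3.1 with float/double/integer
  data — the common modern case — not the full breadth of the standard
  (no analysis segments, no delimited-data workarounds, read-only).
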