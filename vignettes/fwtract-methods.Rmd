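---
title: "Methods: free-water tractometry of peritumoral white matter"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: free-water tractometry of peritumoral white matter}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(fwtract)
```

# The model

## Bi-tensor free-water decomposition

Each voxel's diffusion-weighted signal is modeled as a mixture of a tissue
compartment with full tensor $D$ and an isotropic free-water compartment
with fixed diffusivity $d_{iso}$:

$$S_i = S_0\left[(1-f)\,e^{-b_i\,g_i^\top D\,g_i} + f\,e^{-b_i\,d_{iso}}\right],$$

where $f \in [0,1]$ is the free-water signal fraction (FWF), $g_i$ the unit
gradient direction and $b_i$ the b-value of volume $i$. FW-FA and FW-MD are
the fractional anisotropy and mean diffusivity of the fitted tissue tensor
$D$ — tissue properties with the edema/CSF contribution removed.

`fit_free_water()` minimizes

$$\sum_{v \in \text{mask}} \sum_i \left(S^{pred}_{v,i} - S^{meas}_{v,i}\right)^2
  \;+\; \lambda \sum_v \lVert \nabla f_v \rVert^2,$$

a squared-residual data term plus a Tikhonov penalty on the
finite-difference gradient of $f$ over the 6-neighborhood graph of the
mask. The penalty is this package's concrete form of a spatial-continuity
constraint; it is deliberately simpler than curvature-flow formulations of
the same idea because it is linear, easy to differentiate, and easy to
verify in tests, while expressing the same qualitative prior — free water
varies smoothly in space.

### Identifiability and the tissue-MD ceiling

With a single shell the decomposition is fundamentally degenerate: for any
$\delta$, replacing $(f, D)$ by $(f', D + cI)$ with
$c = \ln\!\big((1-f')/(1-f)\big)/b$ reproduces the weighted signals
exactly, because a uniform eigenvalue shift of $D$ is indistinguishable on
one shell from a rescaling of the tissue amplitude. Informative
initialization alone does not pin the solution down; an optimizer will
drift along this flat direction.

The package therefore constrains the tissue compartment's mean diffusivity
to at most `md_max` (default $0.7\times10^{-3}$ mm²/s, the canonical
healthy deep-white-matter value). The projection is a uniform downward
eigenvalue shift — exactly the degenerate direction — so it removes the
ambiguity without touching the tensor's anisotropy. Consequences users
should know:

* In voxels whose true tissue MD exceeds `md_max`, FW-MD saturates at the
  ceiling and part of the excess diffusivity is attributed to $f$.
* Multi-shell data do not need the ceiling; set `md_max = NULL`.
* The fit's recovery is only asserted (and only assertable) with the
  regularization and an informative initialization; tests never claim
  recovery from arbitrary starts.

### Optimization scheme

Alternating, monotone by construction:

1. **Tensor step.** Given $f$, the water contribution is subtracted from
   each weighted signal, and a log-linear least-squares tensor is fitted
   per voxel, then projected (eigenvalues clamped to $\ge 0$; MD ceiling).
   The update is accepted per voxel only where it lowers that voxel's
   residual, so the data term never increases.
2. **Fraction step.** $f$ is parameterized as the logistic transform of an
   unconstrained field $z$ (keeping $f \in (0,1)$ and the objective
   differentiable, in preference to hard clipping) and updated by a
   backtracking gradient step on the full objective, accepted only when
   the objective decreases.

The recorded objective sequence is non-increasing; the invariant is tested.
Convergence is declared when the relative objective change drops below
`tol` ($10^{-7}$) or after `max_iter` (200) iterations.

### Initialization

$f$ starts from log-linear interpolation of each voxel's mean weighted
attenuation between a pure-tissue reference $e^{-b\,\mathrm{md\_tissue}}$
(`md_tissue` = $0.6\times10^{-3}$ mm²/s) and a pure-water reference
$e^{-b\,d_{iso}}$, clipped to $[0.01, 0.99]$; tensors start from ordinary
least squares on signals corrected with that initial $f$. The
interpolation is exact for log-linear mixtures and biased for true
bi-exponential voxels — it is a starting point, not an estimator; the
constrained fit does the estimation. All-zero voxels are removed from the
mask with a warning rather than silently producing NaNs.

## Tractometry

* **Nodes.** Every streamline is resampled to `n_nodes` (default 100)
  points at equal arc-length spacing with endpoints preserved; node $k$ of
  a bundle aggregates point $k$ of every streamline.
* **Metric sampling** is trilinear; **label sampling** is nearest-voxel
  (labels are never interpolated). Points outside the volume are missing
  and are excluded from node means; a node with no valid point propagates
  NA rather than being imputed.
* **Node values** are unweighted means over streamlines. Core-weighted
  schemes exist upstream in the ecosystem; the unweighted mean is the
  simplest defensible choice and keeps every oracle test exact. The
  aggregation point is a single internal function, so a weighting hook is
  a one-line change.
* **Involvement.** A node's spatial extent is its multiset of resampled
  streamline points; the involvement fraction per compartment is the share
  of those points whose voxel carries that label (BraTS-style codes:
  1 necrotic, 2 edema, 4 enhancing; configurable since datasets differ).
  *Involved* means fraction strictly $>$ threshold; *eligible* for
  asymmetry means combined fraction strictly $<$ threshold. A node exactly
  at the threshold is therefore neither — the literal reading of
  "more than 5%" and "< 5%", kept deliberately and configurably.

## Asymmetry statistics

The directional percent asymmetry
$A = (ipsi - contra)\,/\,\big((ipsi + contra)/2\big) \times 100$ is
antisymmetric, scale-invariant and bounded in $[-200, 200]$ for
non-negative metrics; $A$ is undefined (NA) when both values are 0. Nodes
are paired by index across hemispheres within a tract, which presumes
consistently oriented homologues — `orient_bundle()` enforces a canonical
start, and the generator's mirror construction guarantees it for synthetic
data.

Collapsing is two-stage everywhere: node asymmetries are averaged within
each tract, then per-tract means are averaged into one subject-level value
(per metric, and per distance segment in the binned analysis). Two-stage
and pooled-node averaging genuinely differ whenever tracts contribute
unequal node counts; the pooled variant is available (`pooled = TRUE`) for
comparison but is never the default.

Distances to the tumor margin are along-tract node-index differences to
the nearest involved node (unit: nodes, not mm), binned into segments 1–5,
6–10, 11–15, 16–20, ≥21. Tracts with no involved node have no within-tract
margin; they are excluded from the distance analysis by default, with an
`uninvolved = "distal"` option assigning them to the most distal segment
instead, since either convention is defensible. Eligibility filters on
ipsilateral involvement only (with unilateral tumors, contralateral
involvement is essentially zero); a defensive `filter_contralateral`
option exists.

## Inference

Kruskal–Wallis, Mann–Whitney (exact enumeration when both groups have
$n \le 10$ without ties, normal approximation with continuity and tie
correction otherwise), Shapiro–Wilk and Spearman correlation are delegated
to R's stats library; all tests are two-sided. Group regressions use dummy
coding with glioblastoma as the reference level; asymmetry models omit
age/sex covariates because asymmetry is computed within subject. Logistic
separation is flagged, never silent; rank-deficient designs error naming
the collinear columns.

Benjamini–Hochberg FDR is implemented in this package (not delegated)
because the family stratification carries the analysis' multiplicity
logic: q-values are computed independently within explicit family labels —
one family per metric for asymmetry comparisons, one per compartment for
involvement comparisons — and the implementation is verified against a
brute-force evaluation of the step-up definition on all subsets of eight
p-values, and against the reference implementation.

# The synthetic cohort

`cohort_config()` + `generate_cohort()` / `cohort_profiles()` emulate the
statistical structure the analysis assumes:

* **Groups.** Three pathology groups, default 10 subjects each (equal
  allocation gives balanced power for the group comparisons at desk scale,
  unlike clinical prevalence, which would leave ~2% oligodendrogliomas).
  Demographics are group-dependent (glioblastoma older), sex ~40% female.
* **Tumors.** Nested concentric ellipsoids (necrotic ⊂ enhancing ⊂ edema)
  with group-dependent radii: glioblastoma largest enhancing/necrotic
  compartments, astrocytoma intermediate, oligodendroglioma non-enhancing
  with edema only — reproducing the qualitative volume ordering of the
  three pathologies. An irregular-blob variant (`irregular = TRUE`)
  modulates the shared ellipsoid surface smoothly, preserving nesting, for
  robustness checks. Tumor volumes are reported as proportions of brain
  volume excluding a ventricle ellipsoid.
* **Bundles.** Three synthetic bundles per hemisphere (one passing near
  the tumor, one inferolateral, one superior), each a core trajectory with
  smooth per-streamline jitter; right homologues are exact mirror images
  through the midsagittal plane, so with zero injected asymmetry the
  left/right profiles agree to numerical precision (tested at $10^{-6}$).
* **Metric fields.** White-matter baselines (FA 0.45, MD
  $0.75\times10^{-3}$ mm²/s, FWF 0.05, with small between-subject
  variation), FWF elevated to 0.45 inside edema, and an injected
  asymmetry: ipsilateral FA multiplied by $1 + a\,e^{-d/\tau}$ and MD by
  $1 - a\,e^{-d/\tau}$ around bundle nodes at along-tract distance $d$
  from the margin. Default signed peaks: $a = -4\%$ (glioblastoma),
  $-2\%$ (astrocytoma), $+5\%$ (oligodendroglioma), decay $\tau = 8$
  nodes; the signs and proximal dominance encode the qualitative pattern
  the analysis should recover, while the magnitudes are free parameters
  chosen once at plausible effect sizes, not measured values.
* **Signals.** 55 directions at $b = 2{,}000$ s/mm² plus one $b=0$ on a
  2 mm isotropic grid, axially symmetric tissue tensors built from
  (FA, MD, bundle tangent), Rician noise with $\sigma = S_0/\mathrm{SNR}$
  (default SNR 40) — the magnitude-MRI noise model.

The injected FA/MD perturbation is painted into voxels around bundle node
points (one-voxel neighborhood). Trilinear re-sampling through partially
painted neighborhoods attenuates the recovered magnitude slightly relative
to the injected peak; the recovery tests therefore assert signs, ordering
and decay, not exact magnitudes.

**What the generator does not emulate** — and hence what green tests do
not certify about clinical data: realistic anatomy (no template brains, no
atlas bundle geometry), scanner artifacts (eddy currents, susceptibility,
motion), gray-matter partial voluming, infiltration that alters tensor
*shape* rather than scaling scalars, and segmentation error. Passing the
suite shows the estimators recover what they are designed to recover under
the model's own assumptions.

# Problem sizes and numerical choices

Deliberate scales used by the tests and the acceptance script: free-water
fit checks run on $20^3$ (and smaller) phantoms; the end-to-end cohort is
30 subjects on a $64^3$ grid profiled against ground-truth metric fields,
with the fit exercised separately on the phantom — fitting all 30 subjects
would add nothing statistically, since the fit's recovery is already
quantified where ground truth is voxel-exact. Calibration uses 2,000 null
replicates, bounding the type-I-error check at roughly ±1.3 percentage
points (99% binomial). Per-subject seeds derive deterministically from the
master seed, so cohorts, manifests and analysis tables are bit-reproducible.

Other numerics: the $b=0$ volumes are averaged into one $S_0$ per voxel
before fitting; symmetric 3×3 eigenvalues use a closed-form trigonometric
solution (vectorized over voxels, verified against `eigen()`); negative
eigenvalues are clamped to zero with a warning in scalar computation;
degenerate statistical inputs (all-constant samples) return flagged
results with conventional p-values rather than erroring mid-pipeline;
missing data propagate as NA and are excluded from means, never imputed.

# Coordinates and formats

All internal geometry is world RAS in mm with 0-based voxel indices; node
indices are 1-based to match the distance segments (1–5, ...). NIfTI I/O
(via RNifti) writes the affine as sform; label volumes round-trip as
integers. TRK files are written/read with version-2 headers (points in
voxmm space under the header affine, converted to RAS on read); TCK files
store RAS mm directly; both readers/writers are implemented in the package
since no installed R package handles streamline formats. Profile CSVs are
long-format, comma-separated, UTF-8, header required, missing = empty
field, floats at 9 significant digits, stable row order; analysis outputs
carry the threshold and config hash that produced them.

# Known limitations

* The tissue-MD ceiling biases FW-MD downward in genuinely hyperdiffusive
  tissue; it is the price of single-shell identifiability.
* Node "spatial extent" is point-based, not a voxel dilation; with few
  streamlines the involvement fractions are coarse (multiples of
  1/n_streamlines).
* The two-stage collapse weights all tracts equally regardless of how many
  eligible nodes they retain; tracts reduced to a handful of eligible
  nodes contribute noisy means.
* Logistic involvement models on small synthetic cohorts frequently sit at
  separation; they are flagged and should be read qualitatively.
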