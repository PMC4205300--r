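---
title: "Landmark annotation variability and dense correspondence: models and methods"
author: "landcorr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Landmark annotation variability and dense correspondence: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(landcorr)
```

This vignette is the package's own account of the statistics and geometry it
implements: the models, the tunable parameters and their defaults, the
numerical choices, what the synthetic-face generator does and does not
emulate, and the design decisions that were genuinely open.

## The annotation variability model

A repeated-annotation study has a balanced crossed design: every one of $a$
operators annotates every one of $c$ portraits (scanned faces) in each of
$b$ sessions. Per landmark and coordinate axis we model an annotation as

$$Y_{ijk} = \mu + O_i + D_j + I_k + \varepsilon_{ijk},$$

with independent zero-mean random effects: $O_i$ the operator's systematic
offset (inter-operator variability), $D_j$ the session-day effect
(intra-operator variability), $I_k$ the portrait effect (real anatomical
variation between faces), and $\varepsilon_{ijk}$ the residual. All effects
are isotropic across x/y/z here; per-landmark components are reported as
the *sum* over the three coordinate axes (the trace of the 3D component
covariance), a rotation-invariant quantity in mm². So a per-coordinate
operator SD of 1 mm appears as a summed operator component of 3 mm².

**Estimator.** For balanced complete data the components are estimated by
the expected-mean-squares (ANOVA) equations: with one observation per
(operator, session, portrait) cell,

$$\hat\sigma^2_O = \frac{MS_O - MS_E}{bc}, \qquad
  \hat\sigma^2_D = \frac{MS_D - MS_E}{ac}, \qquad
  \hat\sigma^2_I = \frac{MS_I - MS_E}{ab},$$

with the residual mean square taken from the additive fit
($df = abc - a - b - c + 2$). For balanced complete data this closed-form
estimator coincides with MIVQUE0, which is what the tests verify against an
independent quadratic-form oracle (projection matrices plus a numerically
solved expected-sum-of-squares system). We deliberately support only
balanced designs: no REML, no unbalanced layouts, no p-values for random
effects. Negative component estimates — routine when a true component is
near zero — are truncated at zero and flagged in the output.

**Error summaries.** The per-landmark "combined" error summary is the
pooled distribution of Euclidean distances from each annotation to its
portrait's consensus (the mean over all operator × session replicates):
`mean_error` is the grand mean of those distances, `sd_error` their pooled
SD. This is the only definition consistent with reporting a single
mean ± SD per landmark; whether such summaries should instead be per-axis
is undecidable from a single-number-per-landmark table, and the 3D-distance
pooling is recorded here as an assumption. Note that distances to an
estimated mean are shrunk by the centering factor $\sqrt{(r-1)/r}$ at $r$
replicates; the test oracle accounts for this.

**Interaction check.** The additive model is preferred over one with
two-way interactions when no interaction mean square exceeds twice the
residual mean square (sums of squares pooled over the three axes). The
factor 2 is a configurable screening threshold, not a formal test — the
decision it operationalises is "interactions do not contribute further
explanation", and at full study size (36 × 6 × 2) the additive simulation
passes it in well over 90% of seeded runs.

## Dense point correspondence

Template-to-target propagation has three stages.

1. **Volumetric TPS warp.** The 3D thin-plate spline with kernel
   $U(r) = r$ — the biharmonic radial basis in three dimensions — plus an
   affine part, interpolating the sparse landmark pairs exactly. No kernel
   is canonical for "volumetric TPS"; $U(r)=r$ is the standard 3D choice.
   Coplanar landmark configurations make the affine block rank-deficient
   and are rejected by name. At least 5 landmark pairs are required.
2. **Closest-point projection.** Every warped template vertex moves to its
   globally nearest point over all target triangles (exact point-triangle
   distances, compiled code; ties broken by lowest face index).
3. **MRF refinement.** Closest-point propagation fails where curvature is
   moderate, so the correspondence field is regularized by minimising
   $$E(\ell) = w \sum_{(u,v) \in \text{edges}} \lVert d_u - d_v\rVert^2
     + \sum_v \left(H_\text{tpl}(v) - H_\text{tgt}(\text{foot}_\ell(v))\right)^2,$$
   where $d_v$ is vertex $v$'s displacement from the warped template to its
   footpoint, and $H$ is sphere-fit mean curvature. The first term is the
   Gaussian smoothness prior on the deformation field; the second steers
   vertices toward target regions of similar curvature. One scalar $w$
   (`prior_weight`) carries the entire prior/observation trade-off; the
   observation term is unweighted by construction.

**Curvature.** Mean curvature at a vertex is $\pm 1/R$ of the least-squares
sphere through the vertices within a neighborhood radius, positive where
the sphere center lies opposite the outward normal (convex). The default
radius is 3 mean edge lengths — scale-aware, and wide enough that the
algebraic sphere fit is well conditioned on meshes of a few thousand
vertices. Exactly coplanar neighborhoods (rank < 3) and fits with radii
beyond 10⁶ mm return curvature 0, the planar limit. Footpoint curvature is
interpolated barycentrically from the target's vertex curvatures.

**Optimization.** The footpoints are constrained to the target surface by
construction: each vertex chooses among a discrete candidate set — its
closest-point footpoint plus the `candidate_count` nearest points of an
on-surface sample pool (all target vertices plus `pool_factor` jittered
face-interior samples per vertex, seeded barycentric jitter). The labelling
is optimized by annealed iterated conditional updates: vertices are visited
in a seeded random order; at each visit all candidate labels are scored by
their local energy and one is drawn from the Gibbs distribution at the
current temperature (`temp0`, geometric `cooling` per sweep; at zero
temperature the update degenerates to the deterministic iterated
conditional modes rule). Sweeps stop after `max_sweeps` or a full sweep
without a label change. The best labelling ever visited — including the
initial closest-point field — is returned, so the refined energy can never
exceed the initial energy; this is asserted by tests.

Why these choices: "stochastic optimization" fixes no algorithm, and
single-proposal Metropolis updates proved too weak to move coherent vertex
groups across the smoothness barrier; scoring all candidates per visit is
what makes curvature guidance effective at moderate problem sizes. The
candidate reach matters: `candidate_count` nearest samples span a radius of
roughly $\sqrt{C/(\rho\pi)}$ at pool density $\rho$, and must cover the
expected correspondence error of the warp (the shifted-bump tests pick
`candidate_count` accordingly). Whether footpoint candidates should be
face-interior points or vertices is unstated in the literature we follow;
face-interior sampling via barycentric jitter is used.

**Prior-weight selection.** `choose_prior_weight()` evaluates a grid of
weights by building correspondences for a training set, fitting a PDM and
comparing compactness (variance fraction of the first $m$ modes,
$m = \min(5, n-1)$ by default — the mode count is a free choice and is
configurable). Weights whose model fit fails are dropped with a warning.

## Point-distribution models

Shapes are aligned by generalized Procrustes analysis with similarity
transforms. Two conventions are worth stating because they are invisible in
most packages:

- the scale gauge keeps the mean's centroid size at the average input
  centroid size, so aligned coordinates remain in mm;
- the model records its **alignment target** (the converged Procrustes
  mean). At a similarity-GPA fixed point, the arithmetic mean of the
  aligned shapes differs from the alignment target by a small scale factor;
  reconstructing a new shape therefore aligns it to the recorded target,
  not to the PCA center. This makes reconstruction of a training member
  with all modes exact (≤ 1e-8 mm, asserted), which a naive
  align-to-the-mean implementation misses.

PCA is the SVD of the centered flattened configurations; at most $n-1$
modes are kept, numerically null directions dropped. Reconstruction reports
both the mean point-to-point distance (the headline error, in mm) and the
RMS distance; only the RMS is guaranteed non-increasing in the number of
modes (nested projections), and the monotonicity test uses it. The default
mode count for reconstruction is the number explaining 95% of variance —
unstated in the study this design follows, so configurable.

**Coupled leave-one-out.** For each operator $o$ and held-out portrait $i$:
a PDM from $o$'s remaining $n-1$ session-mean configurations, and a PDM
from $n-1$ configurations drawn uniformly (seeded, one donor operator per
portrait) from the *other* operators; both reconstruct portrait $i$'s
across-operator consensus configuration. Session means are used as each
operator's per-portrait configuration — the most defensible reading when a
study annotates twice and evaluates against "the mean annotation points" —
and per-session configurations remain available by subsetting the
annotation set. A systematic operator bias (an effect shared across that
operator's whole training set) is exactly what a single-operator PDM bakes
into its mean and cannot remove, which is why the random-sampling PDM wins
under bias; with identical unbiased operators the two schemes coincide
(asserted to 1e-8).

## Landmark-selection evaluation

The quality score of a selection is the **dense mean point variance**: per
dense point and portrait, the RMS deviation (trace form, mm) of the point
across the portrait's operator × session replicate meshes; averaged over
portraits, then over points. Computing the spread *within* portrait removes
population variance, isolating correspondence inconsistency — precisely the
reasoning that makes this a selection-quality score. Two interpretation
decisions are recorded:

- the score is an RMS deviation in **mm**, not mm²; the reported magnitudes
  of such scores are commensurate with per-landmark SDs in mm, and the mm
  reading is the only one consistent with that;
- replicate meshes of one portrait are compared in the world frame without
  Procrustes alignment, because they share the same physical surface; an
  `align = TRUE` flag exists for sensitivity analysis.

Per-landmark prediction error compares, for each landmark, the mean of the
dense meshes' designated vertex across replicates with the consensus manual
annotation, averaged over portraits.

The built-in selections 1–4 are hard-coded from the published per-landmark
membership listing, *not* regenerated from the stated threshold rules,
because the listing contradicts those rules for several landmarks (e.g. a
landmark with operator error 3.23 mm listed in the "operator SD below
0.5 mm" selection). The encoded sets follow the listing verbatim and are
deliberately not reconciled; the threshold rule itself is exposed
separately as `selection_from_thresholds()` (strict inequality, matching
the exclusion phrasing "> 1 mm"; an all-excluding threshold returns an
empty selection with a warning rather than an error, so threshold sweeps
can run unattended).

## The synthetic-face generator

`make_template()` builds a half-ellipsoid face sheet (open boundary, about
140 × 180 mm) with analytic bumps for the nose ridge and tip, brow ridges,
lips and chin, on a regular grid; 73 vertices are designated as landmarks
in the standard topology, bilaterally symmetric about the sagittal plane
(left-side landmarks are mirrored grid vertices of their right-side
partners, so symmetry is exact). The bumps make the designated
high-curvature landmarks (nose 35–45, jaw/ear 63–73) sit in regions of
genuine curvature variation, which the correspondence observation term
needs.

Population variation enters through smooth low-frequency displacement
fields, orthogonalized and scaled to unit per-vertex RMS displacement, so a
mode SD is interpretable in mm and PCA-recovery tests have analytically
known answers. Annotation noise follows the additive model above, with one
deliberate structural choice: operator effects are fixed offsets per
(operator, landmark) shared across portraits and sessions — this is what
makes a single-operator PDM systematically biased and lets the
cross-validation comparison reproduce its qualitative finding.

Default study conditions mirror the design the package addresses: 36
portraits × 6 operators × 2 sessions × 73 landmarks, with per-coordinate
SDs of 1.0 mm (operator), 0.3 mm (day), 2.0 mm (portrait) and 0.5 mm
(residual) in the recovery analyses. Synthetic meshes are a few hundred to
a few thousand vertices rather than the 70k–100k of real scans — all
algorithms are resolution-independent, and this is the scale at which a
full pipeline run is a desk-side computation. Acceptance-style analyses use
a resolution-28 template (841 vertices), 4 portraits × 3 operators × 2
sessions for correspondence evaluation, and the full 36 × 6 × 2 landmark
design (no meshes needed) for the variance-component and cross-validation
studies.

What the generator does **not** emulate — and hence what passing tests do
not show about real data: scanner noise and holes, texture (all-geometry
landmarks only), anisotropic annotation error (real operators err more
along a contour than across it), non-Gaussian operator idiosyncrasies,
correlated errors between neighboring landmarks, and realistic facial
shape statistics (two to six smooth modes stand in for a population). The
package's claims on real data are therefore structural (estimator
correctness, energy behavior, pipeline determinism), not quantitative.

## Numerical choices and degenerate inputs

- TPS: dense solve of the full kernel system; an optional ridge `lambda`
  exists but defaults to 0 (exact interpolation). Degenerate (coplanar)
  configurations are an error, not a warning.
- Closest point: exact per-triangle projection, brute force over faces in
  compiled code; ties by lowest face index make results reproducible.
- Curvature: algebraic sphere fit via QR; rank < 3 neighborhoods and radii
  > 1e6 mm map to curvature 0; neighborhoods with fewer than 4 vertices are
  an error suggesting a larger radius.
- GPA: convergence at relative mean change < 1e-9 (100 iterations cap),
  plus a final re-alignment pass so every aligned shape is exactly optimal
  against the returned mean. Degenerate all-coincident shapes are rejected.
- MRF: all stochastic elements (jitter, visit order, Gibbs draws) flow from
  one integer seed; equal seeds give identical fields. The zero-temperature
  variant is fully deterministic given the candidate sets and is the one
  used when exact equivariance under rigid motion matters.
- Mesh I/O is ASCII (OBJ, PLY "format ascii 1.0") with 9 significant
  digits, round-tripping well below 1e-6 mm; landmark files are
  `index x y z`, 1-based, mm. Internally faces are 1-based (R convention);
  format conventions (OBJ 1-based, PLY 0-based) are handled at the
  boundary.

## Known limitations

Only balanced complete designs are decomposed; the MIVQUE equivalence
claimed for the estimator holds for balanced data only. The MRF optimizer
is a local search over discrete candidates: with too small a candidate
reach it cannot recover large correspondence errors, and its result
depends (reproducibly) on the seed. Dense-correspondence quality scores on
synthetic faces should be compared *between* selections, not read as
absolute mm errors for real scans. Landmark schemes other than the built-in
73-point facial scheme can be used throughout the geometry and PDM code,
but the scheme table, selections and noise-model defaults are specific to
it.
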