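---
title: "From binary trabecular images to fabric-elasticity relationships"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From binary trabecular images to fabric-elasticity relationships}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

fabelast implements a complete trabecular-bone analysis chain: grey-value
micro-CT volumes are turned into clean binary regions of interest (ROIs),
each ROI is characterized morphometrically and mechanically, and the
relationship between morphology and apparent elasticity is quantified with
the Zysset–Curnier fabric–elasticity model, including a two-group
comparison protocol. This vignette explains the models, the numerical
choices, and what the synthetic data generators do and do not emulate.

```{r setup, message = FALSE}
library(fabelast)
```

## Image preprocessing

The pipeline order is fixed: **coarsening, segmentation, cleaning,
morphometry**.

* `select_rois()` cuts three cubic ROIs (default side 5.3 mm) from the
  top, center and bottom slabs of a scan, each centered laterally on the
  slab's grey-value center of mass. Slabs anchor at the image top and
  bottom with the third slab centered at mid-height; when the stack is
  shorter than three slab thicknesses the slabs overlap, since no other
  placement rule is defensible without more information.
* `coarsen()` performs block averaging of the grey values *before*
  segmentation (factor 4 by default, e.g. 14.8 µm to 59.2 µm, emulating a
  clinical HR-pQCT-like resolution). Trailing voxels that do not fill a
  complete block are cropped, keeping every output voxel an exact mean of
  a `factor`³ block.
* `otsu_threshold()` maximizes between-class variance on a 128-bin
  histogram spanning the per-scan min–max range. A study-wide single cut
  is the unweighted mean of per-scan thresholds
  (`average_otsu_threshold()`), computed at the coarsened resolution
  because the segmented objects are the coarsened ROIs. Segmentation uses
  the `values >= threshold` convention; the boundary value is foreground.
* `clean_islands()` keeps the largest 26-connected bone component and
  fills 6-connected marrow pockets fully enclosed in bone. The 26/6
  connectivity pair is the standard choice in bone image analysis; using
  the same connectivity for both phases creates checkerboard ambiguities.

## Morphometry and fabric

Bone volume fraction ρ is a voxel count. Tb.Th and Tb.Sp are
Hildebrand–Rüegsegger local thicknesses of the bone and marrow phases: the
volume-weighted mean diameter of the largest sphere containing each voxel
entirely within its phase, computed from an exact squared Euclidean
distance transform followed by sphere painting. In the discrete
convention used here the diameter is `2*sqrt(r²) - 1` voxels, where `r²`
is the squared center-to-center distance to the nearest opposite-phase
voxel: the subtraction removes the half-voxel overshoot on each side, so
a one-voxel feature has thickness exactly one voxel. Voxels outside the
image belong to neither phase, i.e. the structure is treated as extending
past the border rather than being capped by it. Tb.N uses the plate-model
identity `1/(Tb.Th + Tb.Sp)`, which reproduces the usual relation between
the reported medians of the four quantities; the mid-axis alternatives
differ by a few percent and are not implemented.

The fabric tensor comes from the mean intercept length (MIL) method:
`mil_fabric()` casts a grid of parallel lines (1-voxel grid spacing,
half-voxel sampling step) along 128 quasi-uniform Fibonacci directions on
the half-sphere. MIL(**n**) is the total line length in bone divided by
the number of void-to-bone crossings; directions without intercepts are
dropped and at least 6 usable directions are required for the ellipsoid
fit. A symmetric second-order tensor **H** is fit by least squares to
`1/MIL(n)² = n·H·n`, and the fabric tensor is `M = H^(-1/2)` with
eigenvalues sorted ascending and the trace normalized to 3. The
literature uses several normalizations (trace 3, trace 1, det 1); the
choice only rescales the fabric exponent intercepts, not the degree of
anisotropy `DA = m3/m1`, and is recorded in the output metadata.

The homogeneity gate is the coefficient of variation of the 8 octant
densities, `CV = sd(ρ_octant)/mean(ρ_octant)` with the population
(divide-by-8) standard deviation, since the 8 octants are the complete
population of sub-volumes, not a sample. Odd dimensions are cropped by
one voxel so octants are identical in size.

## Micro-FE homogenization

`homogenize()` converts every bone voxel into a fully integrated (2×2×2
Gauss) linear hexahedron with isotropic tissue properties (default
E = 10 GPa, ν = 0.3 — deliberately identical for every ROI so that
apparent-stiffness differences reflect architecture only). Six load
cases (three uni-axial strains, three pure shears) are applied through
kinematic uniform boundary conditions: every node on the external faces
of the cube is prescribed `u = E·x`. KUBC yields the upper-bound apparent
stiffness among admissible boundary conditions, which the
removing-material monotonicity test exploits.

Numerical choices:

* Matrix-free element-by-element conjugate gradients with a Jacobi
  preconditioner; the single element matrix is precomputed once. Default
  relative residual 1e-6 (cap 20 000 iterations), which leaves the
  solid-cube test exact to at least 6 digits.
* The iteration starts from the affine field `u = E·x`, which is the
  exact solution for a homogeneous cube — the solid-cube case therefore
  converges in zero iterations and porous cases start from a physically
  sensible guess.
* The apparent stress is the volume average of element stresses over the
  *full* cube volume (voids contribute zero), the definition of apparent
  continuum stiffness; for converged solutions it agrees with the
  energy-based route by Hill's lemma, which the dense-solve oracle test
  checks at 16³.
* All 6×6 matrices use Mandel (normalized Voigt) notation, so the matrix
  Frobenius norm equals the fourth-order tensor norm and frame rotations
  are orthogonal 6×6 similarity transforms. Component order is
  (11, 22, 33, 23, 13, 12).
* Only the largest 26-connected component is meshed and it must touch
  all six faces; non-spanning structures raise an error instead of
  producing a near-singular solve.

`rotate_to_fabric()` re-expresses the tensor in the fabric eigenbasis
(ordered m1, m2, m3); `project_orthotropic()` zeroes every coupling term
outside the λ block and the shear diagonal — the 12 non-zero components
(9 independent) of orthotropy — and reports the relative Frobenius norm
of the discarded part. Because the projection is orthogonal, the
discarded part is norm-orthogonal to the retained tensor.

## The Zysset–Curnier regression

The model writes the orthotropic stiffness in the fabric frame as

λ_ii = (λ0 + 2μ0) ρ^k m_i^{2l},  λ_ij = λ0' ρ^k (m_i m_j)^l,
μ_ij = μ0 ρ^k (m_i m_j)^l.

Taking logs makes the system linear: each ROI contributes 12 rows (the
nine λ entries of the symmetrized tensor — both λ_ij and λ_ji — plus the
three shear moduli), and the design has three intercept indicator
columns, ln ρ, and the fabric log term. `fit_zc()` solves it by ordinary
least squares:

* **Free fit** (5 columns): exponentiated intercepts give λ* = λ0 + 2μ0,
  λ0' and μ0, hence λ0 = λ* − 2μ0 (flagged if non-positive; positivity is
  not enforced as a constraint).
* **Restricted fit** (2 columns): with the three constants imposed, the
  responses are shifted by the known log-intercepts and only k and l are
  estimated — the form used to compare exponents between groups under a
  common tissue law.

95% intervals come from OLS normal theory on the log scale
(t-distribution), exponentiated for the constants. A cluster-robust
(by-ROI) covariance option exists but is off by default: the 12 log-rows
of a ROI are treated as independent observations, matching the
methodology lineage of the fit; intervals should therefore be read as
conditional on that convention.

Fit quality is reported as `r2adj`, the squared Pearson correlation of
observed and fitted log-responses adjusted with
`1 - (1-R²)(n-1)/(n-p-1)` (n = log-rows, p = 5 or 2; the adjustment
convention is recorded because other choices exist), and `ne`, the mean
over ROIs of the relative Frobenius norm error of the predicted tensor
(a pooled-quadratic alternative is available via `ne_aggregate`).

`youngs_modulus_curve()` inverts the predicted tensor at isotropic fabric
to engineering constants; E(ρ) is then an exact ρ^k power law, which is
why two fits whose k differ by 1% produce curves within a few percent
over the trabecular range ρ ∈ [0.1, 0.5].

## Cohort statistics

`apply_filters()` flags ρ < 0.5 (above that, the ROI is no longer purely
trabecular and morphometrics are unreliable) and CV < 0.263 (the
published homogeneity limit for the RVE assumption underlying
homogenization); both are strict inequalities. Group comparisons use the
two-sided Mann–Whitney test (exact for tie-free samples of at most 20,
mid-rank normal approximation with continuity and tie correction
otherwise) for morphometric and component-wise contrasts, and a Welch
t-test for the orthotropy norm error ("t-test" without qualification is
read as the unequal-variance form, the safer default).

`match_groups()` pairs each ROI of one group with its closest counterpart
in the other on (ρ, DA). Since no distance metric is canonical, both
variables are standardized by their pooled SD and paired greedily without
replacement in ascending order of Euclidean distance; pair distances are
therefore non-decreasing, the pairing is one-to-one, and both groups end
at the size of the smaller candidate pool. `three_step_fit()` then runs
the comparison protocol: pooled free fit, per-group free fits, and
per-group restricted fits with the pooled constants imposed.

## Synthetic data: what it emulates, what it does not

Because no scan data ship with the package, every stage is exercised on
synthetic inputs with known ground truth.

* `generate_structure()` thresholds an anisotropic Gaussian random field
  (white noise smoothed by per-axis correlation lengths with periodic FFT
  convolution) at the exact order-statistic quantile for the target ρ, so
  the pre-cleaning density is correct to one voxel. Anisotropic
  correlation lengths produce MIL ellipsoids whose long axis follows the
  long correlation axis, giving controllable DA; a linear z-gradient
  drives the octant CV up to and past the exclusion threshold. Cleaning
  keeps the largest component; non-spanning draws are retried under a
  shifted seed. Deterministic plate and rod lattices are kept separately
  as oracle fixtures.
* `generate_zc_dataset()` inverts the fabric-elasticity model: ρ uniform
  on [0.15, 0.5], DA uniform on [1.2, 2.2] mapped to the minimal
  eigenvalue family m = (1−a, 1, 1+a) (trace 3), noise-free tensors from
  the ground-truth parameters, then independent multiplicative lognormal
  noise on each tensor entry with re-symmetrization. The default ground
  truth is `zc_reference_params()` (λ0 = 3959, λ0' = 3253, μ0 = 3413 MPa,
  k = 1.7, l = 0.65), so recovery tests run at the reference operating
  point of the method.
* `generate_cohort()` emulates the study layout: two groups of 28 donors
  with 3 ROIs each (84 ROIs per group). Per-ROI draws are
  ρ ~ N(0.36, 0.07) (clamped to [0.08, 0.93]), DA ~ N(1.68, 0.20)
  (≥ 1.02), CV ~ logN(log 0.07, 0.65), Tb.Th ~ N(0.31, 0.04) mm,
  Tb.Sp ~ N(0.68, 0.11) mm — centered on the medians and interquartile
  ranges typical of femoral-head trabecular bone, with distribution tails
  that intentionally place a few ROIs beyond each filter so every
  exclusion branch is exercised. Group effects default to zero (a null
  cohort). A between-donor random effect is available (`donor_sd_rho`,
  `donor_sd_da`) but defaults to zero: with exchangeable ROIs the
  ROI-level Mann–Whitney test is calibrated (≈5% type-I rate, which the
  test suite verifies over 200 null replicates), whereas with a positive
  donor effect ROI-level tests are anticonservative — a caveat that
  applies equally to ROI-level testing on real cohorts.

What the generators do **not** emulate: plate-and-rod trabecular
micro-architecture (a thresholded Gaussian field has different topology
at equal ρ and fabric), scanner noise spectra and beam hardening,
calibration to mineral density, and any biological coupling between
morphology and tissue properties. Passing tests therefore demonstrate the
correctness of the estimators and the internal consistency of the chain,
not the biological fidelity of the structures.

## Problem sizes and runtime choices

The test suite runs phantoms at 10³–48³ voxels, micro-FE oracle
comparisons at 12³–16³ (where a dense sparse-Cholesky factorization is
feasible as an independent check), the solid-cube validation at 32³,
regression recovery at 200 ROIs, and statistical calibration over 200
null cohorts of 2 × 84 ROIs; these sizes were chosen so the full suite
documents the method's behavior in well under a minute of computation
while still exercising every code path at sizes where the oracles are
exact.

## Known limitations

* KUBC gives the upper bound of the apparent stiffness; periodic or mixed
  boundary conditions are out of scope.
* The solver assumes an isotropic, homogeneous tissue; no grey-value to
  modulus mapping is provided.
* The restricted fit inherits whatever error the imposed constants carry;
  its intervals do not propagate that uncertainty.
* MIL line casting uses nearest-voxel sampling; directions are accurate
  to the sampling step (half a voxel), which is ample for 90³ ROIs but
  coarse below ~16³.
* `lsfit`-based MIL ellipsoid fitting assumes the structure has a
  well-defined interface in every direction; single-phase images are
  rejected.
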