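---
title: "Thin-slice plaque mechanics and vulnerability-index prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Thin-slice plaque mechanics and vulnerability-index prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of the models and numerical
choices behind each stage of the pipeline: what is computed, under which
assumptions, which knobs matter, and what the synthetic cohort does and
does not emulate.

## The problem

A coronary plaque's propensity to rupture is driven jointly by its
morphology — most visibly the thickness of the fibrous cap separating the
lumen from a lipid core — and by the mechanical loading of that cap under
blood pressure. The pipeline quantifies both for matched baseline and
follow-up cross-sections, reduces them to ordinal plaque vulnerability
indices (PVIs), and asks how well the *change* in each index between the
two studies can be predicted from baseline information alone.

Nine baseline risk factors are used throughout: lumen area (LA, mm²),
plaque area (PA, mm²), plaque burden PB = PA/(PA+LA), minimum and mean
fibrous-cap thickness (MinCapT, MeanCapT, mm), and maximum/mean cap
stress (kPa) and strain from the mechanical model (MaxCapS, MeanCapS,
MaxCapSn, MeanCapSn).

## Morphology and the cap profile

Contours arrive as closed polylines in millimetres (a small JSON dialect;
`read_slice()`/`write_slice()`). Areas are plain shoelace sums on the
polylines as given — no smoothing, since any smoothing choice would be
arbitrary at the segmentation resolution.

One hundred evenly spaced (arc-length) points on the lumen, grouped into
four quarters of 25, form the sampling frame ("Four-Quarter
Even-Spacing"). Two conventions had to be fixed where the source
material is silent, and both are deliberately reproducible rather than
clever:

* the first sample sits at the lumen vertex furthest in +x (ties to the
  smaller y), with counter-clockwise traversal, so quarter labels are
  stable across reruns and rigid motions of the frame;
* a sample belongs to the *cap* when the ray from the lumen centroid
  through the point crosses a lipid polygon, and its cap thickness is the
  minimum distance to the nearest lipid border. This matches the visual
  convention "the cap is the lumen arc over the lipid pool". Multiple
  pools simply pool their cap points; calcification between lumen and
  lipid does not interrupt membership (a documented simplification).
  MeanCapT averages over cap points only, not the whole wall.

Slices without a lipid core have no fibrous cap; their cap statistics are
absent and they are excluded from all PVI analyses downstream.

## Zero-load geometry

In vivo the vessel is pressurised and axially stretched, so the imaged
geometry is not stress-free. The zero-load state is recovered by
shrinking: 5% axially for every slice (the usual convention for coronary
arteries), and circumferentially by a per-slice factor found so that
re-pressurising the shrunk slice reproduces the in-vivo lumen area.

Choices worth stating explicitly:

* Shrinking conserves wall volume: the outer contour is rescaled so the
  zero-load wall area equals the in-vivo wall area divided by (1 − 0.05).
* The match criterion is *lumen area*, not pointwise shape — area is
  robust to the small shape noise a coarse search mesh introduces.
* The matching pressure is systolic, because the stress/strain predictors
  are extracted under maximum pressure.
* The search is a bracketed root find on circ_shrink ∈ [0, 0.3]
  (bisection by default; an Illinois/regula-falsi variant saves FE
  evaluations and is used by the batch pipeline), each candidate being
  evaluated with a coarse mesh and few load increments. Tolerance is 1%
  relative lumen area.
* Interior contours (lipid, calcification) follow a radial blend of the
  lumen and outer scalings, which keeps them nested for the star-shaped
  geometries the generator produces.

## The thin-slice mechanical model

The cross-section is modelled as a thin slice in generalized plane
strain: in-plane displacements are the unknowns and the out-of-plane
stretch is prescribed at 1/(1 − 0.05), the inverse of the axial shrink.
This realises the "0.5 mm slab" picture without having to pick
through-thickness boundary conditions that the thin-slice idealisation
does not determine.

Materials are modified Mooney–Rivlin solids on isochoric invariants with
an exponential stiffening term, plus, for vessel tissue, an exponential
fiber term in the isochoric fourth invariant along the local
circumferential direction. Near-incompressibility is enforced by a
volumetric penalty κ(J−1)²/2 with κ = 1000 × the tissue's initial shear
modulus scale (2(c1+c2+D1·D2)); κ is configurable via
`material_params()`. The vessel's negative c1 is accepted as published —
the exponential term dominates within the exercised strain range, and the
initial shear modulus (≈ 24 kPa) is positive.

Numerics, in the order they mattered:

* **Mesh.** A boundary-fitted structured grid (polar transfinite between
  lumen and outer boundary about the lumen centroid), each quad split
  into four crossed triangles with a centre node. Tissue labels come from
  centroid containment, so material interfaces fall along element edges.
  Radial layers are graded toward the lumen (exponent 1.4) where the
  transmural stress gradient is steepest. Crossed triangles plus a
  per-cell mean-dilatation volumetric term (the cell-averaged J drives
  the penalty) avoid the volumetric locking that plain linear triangles
  exhibit near incompressibility; with this combination the inner-radius
  error against the exact tube solution is under 0.1% on meshes as coarse
  as 36 × 4.
* **Loading.** Lumen pressure is a follower load on the deformed boundary
  (scaled by the axial stretch, being per unit reference thickness),
  applied together with the axial stretch in 10 increments by default.
* **Solver.** Newton iteration with an exact follower-load tangent and a
  finite-difference tangent of the analytic internal force per 5-node
  cell; the factorised tangent is reused while the residual contracts
  fast (modified Newton) and a backtracking line search rejects steps
  that invert elements — soft lipid pools otherwise cause overshoot.
  Convergence is 1e-8 relative to the applied load; rigid-body modes are
  removed by Lagrange constraints on mean translation and rotation.
  Divergent increments are halved, at most five times.
* **Stress recovery.** Constant-strain elements carry the field at their
  centroids, which under-reads the wall value in the steep near-lumen
  gradient. Per circumferential column, the innermost three layers are
  extrapolated quadratically (in deformed radius) to the deformed lumen
  ring; cap predictors use these wall values. "Stress" and "strain" as
  scalars mean the maximum principal Cauchy stress and maximum principal
  Green–Lagrange strain — the standard convention in this modelling
  literature, which the source material does not pin down.
* **Verification.** The solver is checked against a semi-analytic
  incompressible thick-wall tube inflation (quadrature + root find,
  `analytic_tube_inflation()`): inner radius within 1%, peak hoop stress
  within 3% at the published vessel constants, plus an
  analytic-vs-finite-difference constitutive check at 1e-5.
* **Mesh convergence.** `mesh_convergence()` refines the element size by
  10% per step until the cap-stress summary changes by less than 2%;
  the metric is MaxCapS (the quantity the indices consume), a choice the
  source material leaves open.

## PVI scoring and calibration

Each index maps its measurement into ordinal categories 1–4 through
three cuts, right-closed as printed: C-PVI (0.36, 2) → 1, (0.26, 0.36] →
2, (0.20, 0.26] → 3, (0, 0.20] → 4 (thin cap = vulnerable); stress and
strain indices ascend instead. Cap thickness at or above the 2 mm bound
scores 1 with a warning. The 0.20 mm category-4 cut (rather than the
histology 65 µm) reflects in-vivo imaging: with 65 µm the thinnest
category would be empty.

Stress/strain cuts can be *calibrated*: an exhaustive search over ordered
triples of midpoints between consecutive sorted values maximises exact
agreement with the C-PVI labels, with ties broken toward (a) better
minimum category occupancy and then (b) smaller cuts. Occupancy enters
only as a tie-break, not a hard constraint — the defensible reading of
"each category had some samples". With prefix sums the search is exact
and fast (≈ 230k triples at n = 114). The analysis driver calibrates the
stress/strain cuts, because FE stress magnitudes shift with mesh resolution while
C-PVI does not; calibration absorbs exactly that kind of scale shift —
which is also why the original stress cuts were defined this way.

The change of an index is Δ = follow-up − baseline and the prediction
target is binary: +1 if Δ > 0, −1 otherwise.

## Prediction

A 50-tree probability forest (√p features per split, leaf size 1 — the
common defaults; only the tree count is dictated) is evaluated by
five-fold cross-validation, folds drawn at slice level without
stratification (re-drawn if a training fold would lack a class, with a
stratified fallback after 20 attempts), repeated 100 times; each slice's
out-of-fold probability is averaged over repeats. ROC/AUC and the
operating point are computed on these averaged probabilities; the cutoff
maximises the Youden index, ties toward higher sensitivity. The sweep
evaluates all 511 non-empty subsets of the nine predictors and ranks by
accuracy (AUC available alongside, since the AUC-best and accuracy-best
indices need not coincide). Determinism: every forest receives a seed
from a small deterministic stream, all single-threaded.

`improvement_report()` differences best-combination vs best-single
accuracies *after* rounding to the printed precision, mirroring how such
tables are reported; pass `digits = Inf` for unrounded arithmetic.

## The synthetic cohort

`generate_cohort()` emulates the study conditions, not any patient: 114
matched pairs from 10 patients; perturbed-ellipse lumens (mean radius
1.6 mm), ~1 mm walls with an eccentric plaque bulge; one lipid pool per
slice whose arc is uniform in [40°, 130°] and whose cap is thinnest at
the arc centre; per-patient diastolic/systolic pressures around
72/139 mmHg. The minimum cap thickness is log-normal with meanlog −0.738
and sdlog 0.563, chosen so the four C-PVI categories split roughly
79/21/7/7 out of 114 — the heavy right-skew the analysis must cope with.

Progression acts multiplicatively on cap thickness with coefficients on
baseline plaque burden and cap thickness plus log-normal noise
(sd 0.10), and a small lumen-area drift. The default coefficients give a
minority of positive ΔC-PVI outcomes (order of 16 of 114, varying with
the seed), produced by a small mean effect rather than label subsampling,
so the class imbalance
has the same mechanistic origin as in real cohorts (slow progression
under medication). Stress/strain predictors are *not* simulated — their
signal arises mechanistically because thinner caps concentrate stress in
the FE stage.

What the generator does not emulate: segmentation noise and reader
variability, multi-pool or circumferential lipid anatomies,
calcification mechanics (an optional inclusion only), patient-level
correlation beyond shared pressures, and cap-thickness changes below
image resolution. Passing tests therefore demonstrate that the pipeline
recovers structure it is designed to recover under controlled
conditions; they are not a clinical validation.

## Problem sizes used by the tests and scripts

The verification suite solves the cylinder fixture at element size
0.15 mm (about 100 × 10 cells) for the oracle comparison, and the
cohort-level checks run the 114-pair cohort with a coarse search mesh
(element size 0.4 mm, 2 increments) and a 0.26 mm final mesh — settings
chosen as the coarsest that leave the shrink round-trip within its 1%
tolerance and the predictor signal intact (stress magnitudes at these
meshes sit a few percent below fine-mesh values; calibration absorbs the
shift). The full-resolution path (0.22 mm final mesh, bisection search,
10 increments) is the default for `slice_features()` and is what
`analysis/03_mechanics.R` uses.

## Known limitations

* The structured annular mesh assumes star-shaped contours about the
  lumen centroid; severely non-convex lumens would need a general
  triangulator.
* Generalized plane strain cannot represent through-thickness bending of
  the 0.5 mm slab; this is inherent to the thin-slice idealisation.
* Constant-strain elements require the wall-extrapolation step for
  boundary stresses; quadratic elements would obviate it at higher cost.
* Fold draws ignore patient clustering (slices are the sampling unit, as
  in the study design the pipeline mirrors); a patient-grouped CV mode
  would be the natural extension.
* Material constants are population values; patient-specific stiffness
  is known to shift absolute stress/strain substantially, which is one
  more reason the indices are calibrated rather than absolute.
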