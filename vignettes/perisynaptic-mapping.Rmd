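---
title: "Mapping punctate ligand binding around synapses: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping punctate ligand binding around synapses: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(perisynmap)
```

This vignette is the package's account of its own methods: the models each
stage implements, the tunable parameters and why their defaults are what
they are, what the synthetic scenes do and do not emulate, and the numerical
choices that a maintainer would otherwise have to reverse-engineer from the
code. The empirical statements here are exactly the ones the test suite and
`scripts/acceptance.R` compute; nothing is quoted from elsewhere.

## The scientific problem

Soluble amyloid-β oligomers bind the neuronal surface within minutes and
impair synaptic plasticity, but *where* they bind relative to the synapse —
inside the cleft, on the postsynaptic density (PSD), or on the membrane
immediately around it — is a nanoscale question that diffraction-limited
imaging cannot answer. Answering it takes several modalities at once
(volumetric super-resolution stacks, single-molecule localization tables,
expansion microscopy, live-cell kinetics), each with its own bespoke
quantification. This package implements those quantifications as one
coherent, seeded, testable pipeline.

## Volumetric segmentation

Puncta are enhanced with a negated anisotropic Laplacian-of-Gaussian:
separable Gaussian smoothing with σ = (2, 2, 1) **pixels** (x, y, z), then a
discrete Laplacian, negated and clipped at zero so blobs become positive
peaks. "Kernel size two pixels" is read as the Gaussian σ, the convention of
the common image-analysis toolboxes; a plain-Gaussian mode is kept behind
`method = "gaussian"` for comparison. A three-class Otsu (exhaustive search
over all cut pairs on a 256-bin histogram) yields two thresholds; the
*higher* one builds the puncta mask, which separates puncta both from
background and from dimmer shaft-level staining. Because the cuts are
positions on the intensity histogram, the mask is invariant under intensity
rescaling — a property the tests assert.

Densely spaced puncta merge under any single threshold. Following the
frame-by-frame convention of the original analysis, each z-slice of the
Gaussian-smoothed (σxy = 1 px) intensity is flooded from its regional maxima
and the watershed lines between catchment basins are subtracted from the
mask. Lines are derived from the basin label image (a pixel whose left/up
4-neighbour carries a different label); the basin-merge tolerance is 5% of
the slice intensity range, which keeps the operation scale-equivariant. The
output mask is always a subset of the input mask.

Labeling uses 26-connectivity in 3D by default. The choice is deliberately
permissive: puncta are compact, and with a 200 nm z-step a 6-neighbourhood
under-connects blobs that tilt across slices. Both connectivities are
exposed. Centers of mass are intensity-weighted by default (binary optional)
and reported in physical nm with the voxel-center convention: voxel
(i, j, k), 1-based, has center ((i−0.5)·p~xy~, (j−0.5)·p~xy~, (k−0.5)·p~z~).

## The distance-shell enrichment statistic

The reference channel's label map defines a distance field: each voxel's
exact Euclidean distance (in nm, honoring anisotropic voxel sizes) to the
nearest reference voxel center, computed by k-d-tree nearest-neighbour
search over the reference voxels — an exact distance transform on the voxel
grid. Ligand puncta are assigned to half-open shells [e~i~, e~i+1~) by the
field value at their containing voxel; the default shell width is two
lateral pixels (64.2 nm at the 32.1 nm SIM pixel this statistic was designed
around).

Raw shell counts confound binding preference with available volume, so they
are normalized by a constrained null: in each simulation, the observed
number of puncta *in each z-plane* is re-placed uniformly at random, without
replacement, among that plane's candidate voxels — voxels within the
placement radius (default 642 nm = 20 lateral pixels) of the reference.
Preserving per-plane counts prevents artifacts from the coarse z-sampling;
sampling at voxel resolution matches the statistic's definition on the voxel
grid. The per-shell ratio of observed to mean-simulated counts is 1 when
binding is uniform within the placement region, above 1 where binding is
enriched. Shells whose expectation is zero are flagged undefined and never
divided.

The number of simulations defaults to 7 (the figure-level convention of
averaging several independent simulations) even though a single simulation
per image reproduces the method's literal description; more replicates only
stabilize the denominator, and both are supported. The acceptance checks use
20.

**Self-consistency.** When puncta are *generated* by the same
per-plane-preserving sampler, the mean normalized density must be 1. The
test suite asserts this per shell, within three standard errors over 20
scene seeds, for two routes: the statistic applied to the placed centers,
and the full pipeline that re-detects the rendered puncta. The acceptance
script reports the placed-centers quantity (t1), which isolates the
normalization: at the stated density (200 puncta around 20 markers), roughly
one punctum in seven falls within the merge range of another, and merged
detections preferentially vacate the thin near shells — a segmentation
effect, quantified separately by the object-recovery tests on
well-separated scenes, not a property of the statistic.

## SMLM preprocessing

Localization tables use nm units with columns frame, x, y, σ (fitted PSF
width), uncertainty, photons, channel; ThunderSTORM-style headers
("x [nm]", "uncertainty [nm]") are accepted on read, and writing uses 17
significant digits so round-trips are bit-exact. Quality filtering keeps
uncertainty < 20 nm (strict) and σ inside closed per-dye windows (100–200 nm
for CF568, 90–190 nm for AF647 in the motivating datasets); the filter is
idempotent and order-preserving.

Two-channel registration fits the displacement (moving − reference) as a
bivariate polynomial of the moving-channel position — degree 2 by default,
enough to capture a smooth full-field distortion of ≤ 100 nm — or as a
Gaussian-kernel locally weighted average of the control displacements.
Design matrices are built on centered, range-normalized coordinates for
conditioning. Under the acceptance conditions (≤ 100 nm distortion, 5 nm
per-channel noise, 100 fitted + 100 held-out beads) the held-out RMS
misalignment lands near 10 nm, comfortably below the 15 nm figure the
method is expected to reach (target t2).

Drift correction renders 500-frame segments as 10 nm 2D histograms,
estimates all pairwise offsets by FFT cross-correlation with sub-bin peak
refinement (intensity centroid over the 3×3 peak neighbourhood), solves the
redundant offset system by least squares with the first segment as
reference, rejects pairs whose residual exceeds 5 camera pixels (5 × 100 nm
— the thresholds deliberately live in different units: correlation bins are
10 nm, the rejection gate is in pixels) and re-solves once, then
interpolates per frame and subtracts. Planted linear drift is recovered
within one bin.

## Nanocluster analysis

Local density at a localization is the number of localizations within a
fixed radius (self-inclusive) over πR². The radius is not part of the
published description; the default of 30 nm is commensurate with the
nanocluster scale set by the α = 11 nm boundary parameter and with ~20 nm
localization precision, and it is exposed. A k-nearest-neighbour variant was
considered and rejected to keep densities in absolute units (nm⁻²).

Synaptic regions are segmented by thresholding at the lower 10% of the
density *range* (d~min~ + 0.1·(d~max~ − d~min~)); the reading "10th
percentile" is available behind `threshold_mode = "percentile"`. When all
densities are equal the range is zero and everything is retained — the
degenerate rule is documented and tested. Survivors are grouped into
connected alpha-complex components: the alpha shape is the union of Delaunay
triangles with circumradius ≤ α (alpha-radius convention), its boundary the
edges used by exactly one kept triangle; α = 100 nm for regions, with
components below 1.5·10³ nm² discarded. Membership, areas and distances are
all derived from the triangles, which handles concave and multi-part shapes
exactly.

Nanocluster detection randomizes the in-region localizations uniformly
across the region (seeded rejection sampling from the bounding box) 20 times
(one randomization reproduces the literal single-randomization rule),
pools the randomized local densities, and sets the threshold at their mean
plus 2 SD. Above-threshold localizations are grouped at α = 11 nm; components
need ≥ 3 members (the smallest set bounding a triangle). Overlap with the
PSD uses exact polygon clipping of the two triangle unions; a cluster is
*overlapping* when the overlap fraction is ≥ 0.23 of its area — the boundary
value itself classifies as overlapping, enforced with a 10⁻⁹ guard against
clipping round-off — in which case its center-to-PSD-edge distance is zero;
otherwise the distance runs from the weighted center (mean of member
coordinates) to the nearest boundary point. The 0.23 threshold is treated as
a fixed constant of the method. All of these statistics are rigid-motion
invariant, which the tests check to 10⁻⁹ relative.

## Expansion-microscopy axis mapping

Synapse candidates are mutually nearest pre/postsynaptic object pairs that
have at least one ligand punctum within a Chebyshev window of the pair
midpoint — 20 pixels in x-y and 3 in z by default, with physical-unit
overrides since the effective pixel size scales with the expansion factor.
The published workflow also curated pairs manually for clean axial
separation; reproducibility forbids a human step, so an automatic criterion
stands in: the pre/post separation must exceed twice the mean marker-object
radius (estimated from voxel counts), adjustable or disableable. Each
punctum then gets cylindrical coordinates about the post→pre axis with
origin at the midpoint: z = (p − origin)·û (positive toward the presynaptic
side), r the perpendicular distance. Axial histograms use half-open bins
centered on zero; the bin width and the radial cutoff r~max~ are required
parameters with no silent defaults, since no canonical values exist.
Distances are reported in post-expansion nm by default; dividing by the
expansion factor (nominally 4) is an explicit option.

## Kinetics

Compartment traces integrate background-subtracted intensity (Σ(I − b̄),
with b̄ the per-frame mean over a background ROI) over a PSD mask (synaptic)
and over cell-minus-PSD (extrasynaptic); the two compartments partition the
cell mask by construction. Association fits use
F(t) = baseline + (plateau − baseline)(1 − e^(−t/τ)) with the baseline fixed
at the pre-addition F/F₀ = 1 — the published fits are single exponentials of
F/F₀ with no offset term, so freeing the baseline would change the model
class. τ is reported in minutes. When the fitted amplitude is
indistinguishable from the residual noise the fit is flagged not converged
instead of returning an arbitrary τ. The synthetic trace generator's
association closed form starts at 0 by default (its stated closed form);
recovery simulations set `baseline = 1` on both sides so generator and
fitter share a model class — the discrepancy between the two conventions is
deliberate and surfaced as an explicit argument.

Washout loss is 100·(1 − F(t~w~ + h)/F(t~w~)), scale-invariant, with an
optional photobleach control subtracted in percentage points (a control
fraction of 0.022 turns a 13.2% raw loss into 11.0%). FRAP normalizes to the
prebleach mean, fixes the bleach depth F~b~ at the first postbleach value,
and fits F(t) = F~b~ + (F~∞~ − F~b~)(1 − e^(−kt)); the mobile fraction is
(F~∞~ − F~b~)/(1 − F~b~), clipped to [0, 1] with a warning, and the rate k
is per minute. Published FRAP "recovery rates" are sometimes quoted in
minutes rather than min⁻¹; both k and τ = 1/k are returned so either
convention can be read off.

## Synthetic scenes: what they emulate, and what they do not

Every generator is driven by one seed (RNG state restored afterwards) and
returns ground truth verifiable by brute force — distances, memberships,
drift offsets — with zero tolerance where construction is exact. Rendered
puncta are isotropic-in-nm 3D Gaussians truncated at 3σ: the simplest PSF
surrogate the segmentation must tolerate. Noise is additive Gaussian on
intensities and Gaussian jitter on localizations, matching the
precision-filtered regime of quality-controlled SMLM data. Defaults encode
the study conditions of the motivating experiments: 32.1 nm / 200 nm SIM
voxels with 8–13 slices, 642 nm placement radius, 20 nm-class localization
precision, ≤ 100 nm channel distortion, 500-frame drift segments, τ ≈ 3.6
min binding, ~13% washout loss, FRAP mobile fractions of 0.06–0.25 at
~0.15 min⁻¹.

They do **not** emulate structured-illumination reconstruction artifacts,
dipole emission, camera EM-gain statistics, fluorophore blinking kinetics,
or spatially correlated backgrounds. Passing tests therefore demonstrate
that the *analysis* is correct and calibrated under its own assumptions —
they cannot certify behaviour on raw microscope data whose noise violates
those assumptions.

Two generator details matter for self-consistency experiments.
`gen_sim_scene(placement = "centers")` places enriched puncta relative to
marker *centers* (truth checkable by center-to-center distances);
`placement = "reference_field"` segments the rendered marker channel first
and samples the same candidate voxels the analysis null uses — the right
construction when the question is whether the statistic normalizes to 1.
And `gen_smlm_scene(in_psd_target = 0)` excludes background from the PSD
polygon, since a zero in-PSD fraction is otherwise unattainable under
field-uniform background.

## Numerical choices and degenerate inputs

* Distance fields are exact (k-d tree), so the 1-Lipschitz property holds to
  float precision; empty references are an error, not an empty field.
* Puncta outside the image are tallied with a warning, never silently
  dropped or clamped.
* Otsu thresholding requires ≥ 3 distinct intensities; constant images are a
  degenerate-histogram error.
* Delaunay triangulation (via `deldir`) treats exactly collinear triangles
  as having infinite circumradius, excluding them from alpha complexes.
* Polygon clipping runs in scaled integer arithmetic; areas are exact to
  ~10⁻¹¹ relative, and the single place where that matters — the ≥ 0.23
  overlap rule — carries an explicit 10⁻⁹ guard.
* Uniform sampling in a region uses rejection from the bounding box, seeded;
  for very thin regions this is slow but correct.
* Fits report `converged = FALSE` with a diagnostic rather than silent
  numbers whenever the parameter is unidentifiable (flat association trace,
  no detectable bleach).

## Problem sizes

The test suite and acceptance script run at desk scale, chosen as the
smallest sizes at which the statistical claims are meaningful: 128×128×8
scenes (12 markers / 120 puncta) over 20 seeds for the per-shell null
consistency checks; 256×256×8 scenes (20 markers / 200 puncta, 20 null
simulations, 20 seeds) for the reported t1; 200-bead fields for calibration;
2000-frame / 60-emitter streams for drift; 100 noisy traces for τ recovery;
400 + 100-point scenes for nanocluster recall. The whole suite runs in
about 80 s on one CPU.

## Known limitations

* The per-slice watershed cannot split puncta that merge only across
  z-planes; at high puncta density (mean spacing within ~2 PSF widths)
  detected counts drop by ~10–20% and near-reference shells lose
  preferentially (see the self-consistency discussion above).
* The uniform null is defined on the voxel grid; continuous point-process
  nulls, Ripley's K and pair-correlation analyses are out of scope.
* Alpha shapes are 2D; the dSTORM analyses are planar by design.
* FRAP fitting is pure-exchange single-exponential; diffusion-dominated
  recovery and bleach-spot geometry corrections are not modeled.
* The ExM pairing criterion replaces manual curation with a geometric rule;
  on real data the rule's separation factor may need tuning per expansion
  factor.
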