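# perisynmap

Quantitative mapping of where a punctate fluorescent ligand — the motivating
case is amyloid-β oligomers (Aβo) binding the neuronal surface — sits
relative to synaptic structures, at nanoscale resolution and across imaging
modalities. The package is for microscopists and image analysts who need the
bespoke quantification steps of perisynaptic-localization studies as tested,
reusable R functions rather than one-off scripts:

* **3D puncta segmentation** for volumetric (SIM/ExM-style) stacks:
  anisotropic Laplacian-of-Gaussian enhancement, three-class Otsu
  thresholding, per-slice watershed splitting of merged puncta, 3D labeling
  with intensity-weighted centers of mass in physical nm.
* **A distance-shell enrichment statistic.** With reference objects
  \(PSDs, say\) segmented, every voxel carries its exact anisotropic
  Euclidean distance to the nearest reference voxel. Ligand puncta are
  counted in half-open distance shells, and the counts are divided by their
  expectation under a constrained null: the same number of puncta per
  z-plane re-placed uniformly at random among the voxels within 642 nm of
  the reference. The normalized density is 1 when binding has no spatial
  relationship to the reference, > 1 when binding is enriched at that
  distance.
* **SMLM preprocessing**: ThunderSTORM-style localization CSV IO, quality
  filtering (uncertainty < 20 nm; per-dye σ windows), bead-based two-channel
  registration (2D polynomial or locally weighted displacement fields), and
  redundant cross-correlation drift correction (500-frame segments, 10 nm
  bins, residual-threshold rejection).
* **Nanocluster analysis** of localization coordinates: fixed-radius local
  densities, alpha-shape synaptic-region segmentation (α = 100 nm, area ≥
  1.5·10³ nm²), in-PSD fractions, nanocluster detection against a
  uniform-randomization density threshold (mean + 2 SD), α = 11 nm cluster
  boundaries, exact-area PSD-overlap classification (overlapping when ≥ 0.23
  of the cluster area), and center-to-PSD-edge distances.
* **Expansion-microscopy axis mapping**: pairing of pre/postsynaptic
  objects, cylindrical (z, r) coordinates on the post→pre axis (positive z =
  presynaptic), axial histograms.
* **Binding kinetics**: compartmental background-subtracted intensity
  traces, single-exponential association fits
  `F(t) = 1 + (plateau − 1)(1 − e^(−t/τ))`, washout loss with photobleach
  control, FRAP mobile fraction and recovery rate, window-averaged F/F₀.
* **Synthetic-scene generators** with seeded ground truth for every one of
  the above, so the whole pipeline is verifiable without microscope data.

## Worked example

Generate a two-channel volume in which half of 40 ligand puncta are planted
within 250 nm of 12 synaptic markers, then run the full enrichment pipeline
(segmentation of both channels, distance field, shell counts, 20-simulation
null):

```r
library(perisynmap)

sc <- gen_sim_scene(shape = c(128, 128, 8), n_markers = 12, n_ab = 40,
                    enriched_fraction = 0.5, enrichment_radius = 250,
                    min_separation = 300, seed = 42)
prof <- analyze_enrichment(sc$image, "marker", "ab", n_simulations = 20, seed = 1)
round(as.data.frame(prof)[, 1:5], 2)
#>    shell_lo shell_hi observed expected ratio
#> 1       0.0     64.2        2     0.85  2.35
#> 2      64.2    128.4        4     0.60  6.67
#> 3     128.4    192.6        8     0.85  9.41
#> 4     192.6    256.8        7     4.15  1.69
#> 5     256.8    321.0        0     3.15  0.00
#> 6     321.0    385.2        0     3.30  0.00
#> 7     385.2    449.4        1     5.75  0.17
#> 8     449.4    513.6        3     6.15  0.49
#> 9     513.6    577.8        3     6.05  0.50
#> 10    577.8    642.0        0     8.95  0.00
```

The planted enrichment is read directly off the `ratio` column: ligand
density is 2–9× the uniform expectation within ~250 nm of the markers and
below 1 farther out, exactly as constructed (the other half of the puncta is
uniform over the volume, which dilutes but does not erase the far-shell
deficit). `attr(prof, "ab_objects")` holds the segmented puncta — here all
40 planted puncta are recovered.

FRAP kinetics work the same way, from trace to fit:

```r
tr <- gen_traces("frap", list(mobile_fraction = 0.25, rate = 0.15,
                              bleach_depth = 0.3, noise_sd = 0.02),
                 n_points = 25, dt = 60, seed = 3)
fit <- fit_frap(tr, attr(tr, "bleach_frame"))
#> mobile fraction 0.287, rate 0.129 / min (tau 7.7 min), bleach depth 0.29
```

i.e. with realistic noise a single 25-minute trace recovers the planted
mobile fraction of 0.25 and rate of 0.15 min⁻¹ to within the expected
single-trace scatter; the recovery simulations in the test suite quantify
this over many seeds.

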