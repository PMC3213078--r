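---
title: "Automated 3D/4D dendritic spine morphometry: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated 3D/4D dendritic spine morphometry: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`spinemorph` is an open implementation of fully automated dendritic spine
morphometry for fluorescence z-stacks of cultured neurons: it traces a
dendrite from a user-supplied starting point, detects spine protrusions
under explicit geometric constraints, measures head width, neck width,
length and head volume for each spine, classifies spines as stubby,
mushroom or thin, links protrusions across a time-lapse series, and
quantifies remodeling. Because public reference images with ground truth do
not exist for this task, the package ships a synthetic phantom generator
that renders dendrite-plus-spine volumes with analytically exact truth
tables; the entire validation strategy is built on these phantoms.

This vignette records the models, the tunable parameters, the numerical
choices, and the limitations — the things a user should know before
trusting numbers on real data.

# The imaging model and its parameters

The pipeline expects deconvolved widefield or confocal z-series of neurons
expressing a bright, spine-filling label (an actin-binding-peptide fusion
such as Lifeact works well because spines are actin-rich). The default
geometry mirrors a 60x/1.4 NA acquisition: in-plane pixels of 0.1075 um and
a z-step of 0.15 um. Voxel centers sit at `(i - 0.5) * voxel_size` with the
origin at the volume corner; arrays are indexed `[z, y, x]` internally and
all user-facing coordinates are `(x, y, z)` micrometers.

Two published parameter sets are wired in as modes of `analysis_config()`:

| parameter | fixed mode | live mode | meaning |
|---|---|---|---|
| `min_dendrite_end_diameter` | 0.75 um | 0.75 um | minimum local diameter of the dendrite path |
| `min_spine_end_diameter` | 0.215 um (2 pixels) | 0.3 um | minimum local diameter at a spine tip |
| `max_spine_length` | 5 um | 15 um | longest protrusion assigned as a spine |
| `stubby_length_max` | 1 um | 1 um | stubby/thin length boundary |
| `class_ratio_threshold` | 1.5 | 1.5 | head/neck ratio for mushroom |
| `tracking_gate` | 1 um | 1 um | maximum match cost between time points |

The live mode's longer length bound deliberately includes dendritic
filopodia, which are abundant in younger cultures. Three further knobs are
our own: `head_fraction` (0.5) fixes the distal fraction of the spine path
searched for the head maximum, `smooth_window` (0.5 um) the moving-average
window on the centerline, and `min_protrusion` (0.3 um) the minimum
distance a spine's surface must stick out beyond the dendrite surface —
a guard that suppresses one-to-two-voxel skeleton twigs on the shaft, at
the cost of blindness to bumps shallower than ~0.3 um.

# Segmentation and tracing

**Threshold.** The "automatic threshold" is Otsu's method on the 256-bin
intensity histogram of the volume; a numeric `threshold_method` overrides
it. The foreground component containing the starting point (26-connectivity)
is the neuron mask; disjoint bright debris is discarded by construction.

**Isotropic resampling.** Medial-axis methods are biased by anisotropic
voxels, so the *intensity* volume is linearly resampled along z to the
in-plane spacing and re-thresholded. Resampling intensity rather than the
binary mask preserves partial-volume boundary information that a 0/1
interpolation destroys; empirically this halves the boundary error of
sub-micron structures.

**Skeletonization.** The curve skeleton is extracted by distance-ordered
homotopic thinning: foreground voxels are deleted in increasing order of
the Euclidean distance transform (EDT; Felzenszwalb–Huttenlocher exact
transform with per-axis spacing) whenever deletion preserves topology
(simple-point test for the (26, 6) adjacency pair) and the voxel is neither
a curve endpoint nor an *anchor*. Anchors are strict local maxima of the
EDT over the 26-neighborhood, i.e. the distance ridge. Anchoring matters:
naive directional thinning lets deletions cascade along two-voxel-wide
structures and can consume an even-diameter tube end to end. Because the
EDT of a discrete tube has plateaus (a tube whose axis falls between voxel
planes has a 2x2 bundle of equal-distance voxels), a deterministic
sub-resolution perturbation (< 1e-6 um, a hash of the voxel index) breaks
ties so that the anchored ridge is sparse and the skeleton collapses onto a
single connected line. The mask is replicate-padded before the transform so
a dendrite cut by the volume faces is skeletonized to the face instead of
retracting by one radius.

**The dendrite path.** Skeleton voxels become an igraph graph (26-neighbor
edges weighted by physical length). The dendrite is the maximal geodesic
path from the starting point through voxels whose local diameter (twice the
EDT) is at least `min_dendrite_end_diameter`; ties between equal-length
routes are broken toward larger radius by an infinitesimal radius-dependent
edge penalty (the dendrite is the thickest structure in the field). The
path is smoothed by a moving average over `smooth_window`; the per-point
radius is read from the best EDT value in each voxel's 26-neighborhood,
because the thinned line can sit one voxel off the true medial axis and the
plain on-path EDT biases radii low. On straight and sinusoidal phantom
tubes the traced length is within 2% of the analytic arc length, and the
radius within one in-plane voxel.

# Spine detection and morphometry

Skeleton branches leaving the dendrite path ("branch level 2") are
enumerated as connected components of the skeleton after removing the path.
Each branch is kept as a spine iff

1. its length from the dendrite surface to the tip is at most
   `max_spine_length` (longer protrusions are counted and logged),
2. its tip local diameter is at least `min_spine_end_diameter` (taken as
   the maximum local diameter over the distal 0.25 um, since the endpoint
   voxel's own EDT is about one voxel whatever the tube width), and
3. its surface protrudes at least `min_protrusion` beyond the dendrite
   surface.

Measurement follows the operational definitions of the manual protocol the
method replaces: *length* from the dendrite shaft to the spine tip, *head
width* at the maximum width of the spine tip, *neck width* at the minimum
along the spine. Concretely:

* **Length** runs from the point where the branch path crosses the dendrite
  surface (local excess distance over the traced radius, interpolated
  between path points) to the skeleton endpoint, plus the endpoint's EDT
  radius (the endpoint sits about one radius short of the physical tip).
  The branch polyline is lightly smoothed (5-point moving average) to
  remove voxel staircase inflation.
* **Head width** is the maximum local diameter over the distal
  `head_fraction` of the surface-to-tip path, read from the neighborhood
  EDT maximum, and refined by the maximal inscribed sphere of the head
  region (below) when that is larger — this protects against the skeleton
  hugging the side of a large head.
* **Neck width** is the minimum of a 3-point running mean of the
  neighborhood-EDT diameter profile between the surface crossing and the
  head center. The running mean suppresses single-voxel dips that would
  otherwise make the minimum statistic fragile.
* **Head volume** is a geodesic watershed at the neck minimum: every mask
  voxel in a crop around the spine is assigned to its geodesically nearest
  path point, and the head is everything assigned beyond the distal end of
  the neck-minimum plateau, completed by the Euclidean ball around the head
  center back to the junction (voxels in the collar around the neck
  belong to the head but are geodesically nearer to neck path points), with
  an analytic correction subtracting any cylindrical stretch of neck that
  discretization sweeps in. No public definition of an automated
  head-volume exists to copy, so this one is stated fully and validated
  against analytic phantom spheres.

On noiseless phantoms at the default resolution, the population-mean
absolute errors are about 0.04 um for head width, 0.03 um for neck width,
4–5% for length and 9–14% for head volume, with 100% detection precision
and recall for 20-spine, 50-um benchmarks, both noiseless and at
foreground SNR 10. Worst single-spine errors are larger — up to ~18% length
error for sub-micron stubby bumps and ~25% volume error for 0.5-um heads —
which is the expected scale of discretization at 5-voxel structures.

# Classification

With r = head width / neck width and L the length in um:

* mushroom: r ≥ 1.5 and L ≤ max length;
* stubby: r < 1.5 and L ≤ 1;
* thin: r < 1.5 and 1 < L ≤ max length;
* excluded: L > max length.

The three classes partition the valid domain; the boundaries are exact
(L = 1 is stubby-side, r = 1.5 is mushroom-side), with a relative epsilon
of 1e-9 on the ratio so that inexact divisions such as 0.3/0.2 still land
mushroom-side. Published renderings of this scheme are inconsistent about
the ratio's orientation (some print neck/head with the same 1.5 threshold,
which would make necks wider than heads the maturity criterion); we use
head over neck, the only orientation consistent with measured spine
geometry — population medians put heads at roughly four times the neck
width — and with mushroom being the majority class in mature cultures.
Likewise, where printed formulas let the stubby and thin length ranges
overlap, the prose definitions above win.

# Tracking and remodeling analytics

Spines are linked between consecutive time points by minimum-cost
one-to-one assignment (an O(n³) Hungarian solver, verified against
brute-force enumeration) on attachment position:

cost = |Δ arclength| + 0.5 um × |Δ azimuth| / π,

with azimuth wrapped to [-π, π] and pairs costing more than the gate left
unmatched (each unmatched spine carries gate/2, so a pair is matched
exactly when that is cheaper than leaving both free). Anchoring the match
on the attachment rather than the tip makes identity robust to tip motion;
the default gate of 1 um is far above the 0.1 um frame-to-frame jitter of
the phantom series and below typical inter-spine spacing.

Tracks are contiguous by construction (one appearance, at most one
disappearance). Fates follow presence at the series ends: stable (first and
last), pruned (first only), new (last only), transient (neither). Transient
protrusions get their own label rather than being folded into new or
pruned; mid-series gaps are not bridged. Stability is judged at the series
ends only, not at every intermediate point — intermediate dropouts would
close a track and the remainder would re-open as new.

Transition fractions condition on presence at t = 0 (newly formed spines
are excluded); the outcome of a t0 protrusion is its class at last presence
if it survives to the series end, else "pruned". A class absent at t0
yields an undefined (NA) row, never zeros. The incidence table expresses
each (initial class, outcome) cell as a fraction of all t0 protrusions.
Accounting identities — t0 count = stable + pruned, end count = stable +
new — are asserted on every run. `fate_group_geometry()` reports the t = 0
geometry means of stable / remodeled / pruned groups for one initial class,
the fate-predictor analysis.

# Validation statistics

* `regress_counts()` — ordinary least squares with free intercept and a
  two-sided t-test on the slope (free intercept because the agreement
  statistic it reproduces did not state a forced origin).
* `ks_two_sample()` — two-sample Kolmogorov–Smirnov D with the asymptotic
  p-value, appropriate at the hundreds-of-spines sample sizes it is used
  at; exact small-sample p-values are out of scope.
* `summary_stats()` — sample SD (n−1), CV = SD/mean (flagged undefined for
  zero means), and *adjusted Fisher–Pearson* skewness, the default of the
  SPSS-family software in which the original statistics were computed.
* `score_detection()` — greedy one-to-one nearest matching of detected to
  true attachment points under a tolerance (default 0.5 um), yielding
  precision, recall and per-spine geometry errors.

Group-comparison tests on biological data (ANOVA, Kruskal–Wallis,
Mann–Whitney and post-hoc families) are deliberately not re-implemented:
the per-spine tables export to CSV, and any statistics environment does
those off the shelf. The package's value is upstream of them.

# The phantom generator

`phantom_spec()` renders a bright tube (default radius 0.6 um, diameter
comfortably above the 0.75 um traceability minimum) crossing the field of
view, carrying spines built from a neck capsule plus a spherical head —
with head diameter equal to neck diameter this degenerates to the
round-capped protrusions used for thin and stubby shapes. Rendering
computes the exact signed distance to the union of primitives; boundary
voxels are supersampled 8x (2x2x2) for partial-volume antialiasing, which
matters because 0.2 um necks are sub-voxel in places. Foreground is 10x
background (100 vs 10) before noise, approximating a well-expressing
labeled neuron after deconvolution. Optional Gaussian PSF blur and Gaussian
or Poisson noise are applied after rasterization and never alter the truth
table. Imaging SNR was not reported for the original acquisitions, so the
noise defaults (e.g. Gaussian sd = 10, i.e. foreground SNR 10) are our own
benchmark conditions, not a claim about any instrument.

`rasterize_series()` adds time: by default 13 points at 5-minute intervals
(one hour of imaging), per-spine scripted events (appear, prune, morph) and
isotropic jitter of 0.1 um per time point applied to each attachment —
below half the tracking gate, so identity tests are well posed. The truth
log has one row per spine per time point; a pruned spine never reappears
under the same id. The generated truth class always equals
`classify_spines()` applied to the true geometry (generator–classifier
consistency is a tested invariant).

`standard_phantom()` freezes the benchmark population used throughout the
tests: spines cycling stubby/mushroom/thin, evenly spaced with
golden-angle azimuths, geometry drawn from class-typical ranges consistent
with published ultrastructural population statistics (mushroom heads
0.5–0.7 um on 0.18–0.28 um necks, thin protrusions 1.5–3.5 um long and
0.24–0.3 um wide, stubby bumps 0.5–0.95 um long).

What the phantoms deliberately do **not** emulate: optics-accurate PSFs,
photobleaching, dendrite branch points and crossing neurites (the analysis
protocol selects regions free of them), background autofluorescence
texture, and segmentation-relevant labeling heterogeneity. Passing on
phantoms therefore demonstrates algorithmic correctness at realistic
geometry, contrast and noise — not robustness to every artifact of real
cultures; on real data the operator remains responsible for ROI selection
and for checking the trace overlay (`plot()` on an analysis object).

# Problem sizes and runtime

The shipped validation uses: a 50 um, 20-spine benchmark (noiseless and
foreground SNR 10); a 13-time-point, 10-spine tracked series with four
scripted class conversions and three prunings; ten replicate 3-time-point
series of 12 mushrooms for fate-group parameter recovery (pruned mushrooms
generated with 0.1 um thinner necks, recovered within two standard errors);
and eight small phantoms for count-agreement regression. A single 50-um
volume (about 4 million voxels) analyzes in a few seconds; the full test
suite runs in under two minutes on one core.

# Known limitations

* Geometry at or below two pixels (0.215 um) is not resolvable: thin necks
  quantize to the voxel grid, and some spine heads are indistinguishable
  from short wide necks — a physical limit of light microscopy, not of the
  implementation.
* Single-spine worst-case errors (short stubby lengths, 0.5-um head
  volumes) reach ~18–25% at the default resolution; population means are
  several-fold tighter. Studies hinging on individual sub-micron spines
  should use the per-spine `quality` flag and inspect overlays.
* Branched (bifurcated) spines are measured along their longest tip path;
  branching dendrites, somata and multi-neuron fields are out of scope —
  the tracer follows a single unbranched dendrite segment.
* Tracking has no gap closing: a detection dropout splits a track into a
  pruned and a new piece.
* The dendrite path tie-break and the head/neck partition
  (`head_fraction`) are stated conventions; alternative conventions would
  shift absolute values slightly but consistently across conditions.
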