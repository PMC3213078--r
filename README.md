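# spinemorph

Automated 3D and 4D dendritic spine morphometry for fluorescence
microscopy of cultured neurons.

Dendritic spines — the actin-rich protrusions carrying most excitatory
synapses — are routinely scored by hand: an experimenter marks each spine
in a z-stack and measures its head width, neck width and length with a
ruler tool. That is slow, biased and poorly reproducible. `spinemorph`
replaces the manual workflow with a fully automated one:

1. **Trace** — segment the labeled neuron (Otsu threshold, seeded
   connected component), resample to isotropic voxels, extract a 3D curve
   skeleton by distance-ordered homotopic thinning, and follow the maximal
   geodesic path from a user-supplied starting point through skeleton
   voxels of local diameter ≥ 0.75 um: the dendrite centerline with a
   per-point radius profile from the Euclidean distance transform.
2. **Detect** — every skeleton branch leaving the dendrite path (branch
   level 2) is a spine iff its surface-to-tip length ≤ L_max and its tip
   local diameter ≥ d_min. Two published parameter sets are built in:
   fixed mode (d_min = 0.215 um, L_max = 5 um) and live mode
   (d_min = 0.3 um, L_max = 15 um, admitting filopodia).
3. **Measure** — length from the dendrite surface to the tip; head width =
   max local diameter over the distal half of the spine path; neck width =
   min local diameter between surface and head; head volume by geodesic
   watershed at the neck minimum. Local diameter is twice the distance
   transform.
4. **Classify** — with r = head width / neck width:
   mushroom if r ≥ 1.5 and length ≤ L_max; stubby if r < 1.5 and
   length ≤ 1 um; thin if r < 1.5 and 1 < length ≤ L_max. Spine density is
   reported per 10 um of dendrite.
5. **Track (4D)** — spines are linked across time points by optimal gated
   assignment on attachment position (cost = |Δarclength| +
   0.5 um·|Δazimuth|/π, gate 1 um), given fates (stable / new / pruned /
   transient), class-transition fractions, remodeling incidence, and
   fate-group geometry (the t = 0 geometry of stable vs remodeled vs
   pruned spines).

Because no annotated reference images exist for this task, the package
also ships a **phantom generator**: antialiased synthetic dendrites
bearing parameterized spines of the three classes, with optional PSF blur,
noise, scripted remodeling events and analytically exact ground truth.
Every stage of the pipeline is validated end-to-end against these
phantoms, and `score_detection()`, `regress_counts()`, `ks_two_sample()`
and `summary_stats()` provide the agreement and distribution statistics
used for method validation.

## Worked example

Render a 15 um phantom dendrite carrying one canonical spine of each class
(a 0.6 um mushroom head on a 0.2 um neck, a 3 um thin protrusion, a 0.8 um
stubby bump), analyze it, and score the result against the generator's
truth:

```r
library(spinemorph)

spec <- phantom_spec(
  field_of_view = c(15, 9, 9), seed = 42,
  spines = list(spine_spec(5,  0,    1.5, 0.6,  0.2),   # mushroom
                spine_spec(8,  pi,   3.0, 0.3,  0.25),  # thin
                spine_spec(11, pi/2, 0.8, 0.45, 0.4)))  # stubby
ph  <- rasterize(spec)
fit <- analyze_spines(ph$volume, start = c(0.1, 4.5, 4.5))
summary(fit)
#> spine_analysis: 3 spines on 15.0 um of dendrite (2.00 per 10 um)
#>   classes: stubby = 1, mushroom = 1, thin = 1
#>   head_width   median 0.430, mean 0.418, range [0.215, 0.608]
#>   neck_width   median 0.215, mean 0.287, range [0.215, 0.430]
#>   length       median 1.613, mean 1.882, range [0.845, 3.189]
#>   head_volume  median 0.067, mean 0.086, range [0.061, 0.129]

fit$spines[, c("id", "length", "head_width", "neck_width", "head_volume", "class")]
#>   id length head_width neck_width head_volume    class
#> 1  1  1.613      0.608      0.215      0.1292 mushroom
#> 2  2  3.189      0.215      0.215      0.0671     thin
#> 3  3  0.845      0.430      0.430      0.0609   stubby

score_detection(fit$spines, ph$truth)
#> detection_score: TP 3, FP 0, FN 0; precision 1.000, recall 1.000
#>   mean |error|: head 0.038 um, neck 0.027 um, length 0.116 um
```

All three spines are found and classified correctly; the mushroom's head
reads 0.61 um against a true 0.60, its neck 0.215 um (two pixels) against
a true 0.20, and its head volume 0.129 um³ against the analytic sphere
volume 0.113 um³. The measured values in this README are the output of the
code shown.

For time-lapse data, run `analyze_spines()` per time point and pass the
list to `track_spines()`; `transitions()` and `fate_group_geometry()`
produce the remodeling summaries. A thin command-line front end
(`inst/scripts/spinemorph`) wraps the same functions as `simulate`,
`analyze`, `track` and `report` subcommands for shell pipelines.

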