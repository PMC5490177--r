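---
title: "Wing morphometrics: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Wing morphometrics: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wingmorph)
```

wingmorph measures drosophilid wings from grayscale photographs and
identifies the species from the measurements. This vignette explains the
three models at the package's core — the template-matching landmark
detector, the fixed-endpoint active contour, and the Mahalanobis
discriminant with a chi-square rejection rule — together with the tunable
parameters, the numerical choices, and what the synthetic benchmark does
and does not demonstrate.

## Landmark detection by exemplar template matching

A wing carries 13 homologous key points, labelled `a`–`m`; most are vein
intersections, `k` is the costal-fringe boundary. The user clicks three
anchors (`a`, `h`, `k`) on a query image $I$. For every exemplar wing
$D_m$ in an annotated library, the unique affine transform $Q_m$ mapping
the exemplar's anchors onto the clicked anchors is solved exactly (three
point pairs, six unknowns). Each remaining key point $j$ of $D_m$ maps to
a predicted neighbourhood $(x'_j, y'_j)$ in the query frame.

Around that location the detector slides a square template taken from the
warped exemplar against the query, over all integer shifts
$|c_x|, |c_y| \le 15$ and five template rotations
$\theta \in \{-10^\circ, -5^\circ, 0^\circ, 5^\circ, 10^\circ\}$. Both
patches are range-normalized to $[0, 255]$ — the query patch separately at
every candidate shift — and the score is the Euclidean norm of their
pixel-wise difference (minimizing this norm is the same as minimizing the
summed squared differences). The global minimizer over shifts, angles and
exemplars gives the prediction $(x'_j - c_x^*,\; y'_j - c_y^*)$. Ties are
broken lexicographically by (exemplar, angle, shift), so runs are
deterministic.

Only pixels near the annotated key points of each exemplar are ever
warped: exemplars keep a small per-landmark patch cache (default
half-size 64 px) instead of the full raster, which is what makes a
100-exemplar search affordable.

Parameter defaults, all in pixels at the reference image resolution
(1936 × 1288) and scaled linearly with the resolution ratio recorded in
the annotations: template half-size 24 (49 × 49 patch — much wider than a
vein, narrower than the inter-vein spacing), shift radius 15, patch cache
64. The shift grid is integer-valued; no sub-pixel refinement is
attempted, which bounds the quantization error at about 0.4 px RMS and is
consistent with the few-pixel deviations the method achieves overall.

## The gradient image

The snake needs a raster that is bright on vein centrelines with a smooth
decay away from them. It is built in five standard steps: Gaussian blur
(σ = 2 px) and inversion, so the dark veins become bright; Sobel gradient
magnitude of the blurred image, thresholded by Otsu's method; dilation of
the edge map with a disc (radius 2 px) and complementation; an exact
Euclidean distance transform of that mask, linearly rescaled to
$[0, 255]$ and inverted; and finally the pixel-wise sum of the
blurred-inverted image and the inverted distance field, linearly rescaled
to $[0, 255]$. The real-valued sum with a global rescale avoids the
saturation artifacts that clipped 8-bit addition would introduce. The
orientation of the distance transform was chosen so that the result is
bright near veins; the test suite verifies the resulting ridge ordering
(centreline > 5 px off > 15 px off) on generated wings.

## Arc tracing with a fixed-endpoint active contour

Five vein arcs are measured: `fg`, `gh`, `jl`, `kl`, `lm` (`jl` runs
along the costa from the tip through `k`). An arc is a polyline of $n$
segments whose endpoints are pinned to the detected key points. With
vertex intensities $P_i$ sampled bilinearly, the energy is

$$L = \frac{\langle P\rangle}{2}\sum_{i=1}^{n} l_i\!\left[
  \frac{1}{P_{i-1}+\varepsilon} + \frac{1}{P_i+\varepsilon}\right]
  \;+\; \alpha \sum_{i=1}^{n} (l_i - l_0)^2,$$

where $l_i$ are segment lengths, $l_0 = \lVert p_a - p_b\rVert / n$ is the
equilibrium length, and $\langle P\rangle$ is the mean endpoint intensity,
frozen at initialization (the endpoints never move, so updating it would
change nothing). The first term is small along bright paths and invariant
under multiplying $P$ by a constant; $\varepsilon$ keeps it finite on
zero-intensity pixels. Interior vertices descend the gradient of $L$,
computed by central finite differences (step 0.25 px) of the terms local
to each vertex — mathematically identical to differencing the full
objective, since a vertex only touches its two adjacent segments. If a
step would increase $L$, the step size is halved for that step (up to 8
times), which preserves the descent direction while keeping $L$
non-increasing; evolution stops when the largest vertex displacement
falls below 0.01 px. The arc length is the sum of segment lengths of the
converged polyline.

Defaults: $n = 32$, $\alpha = 0.05$, $\varepsilon = 10^{-6}$,
$\eta = 0.2$, `max_iter = 800`, `tol = 0.01`. These were calibrated once
on the synthetic suite: with 500 iterations the slowly-descending costal
arcs (`jl`, `lm`) were still a few pixels short of their resting
position, and 800 iterations lets them settle; the other values are
unremarkable and fully configurable. Note that the energy samples $P$ at
vertices only, not along segments — long segments under-sample the field,
which is mitigated by using enough segments.

Initialization matters more than the optimizer. Straight chords work for
`fg`, `gh`, `jl` and `kl`, which are nearly straight. Arc `lm` has
another vein running parallel just below it, and a straight (or naively
mapped) initialization tends to lock onto the wrong vein — a failure mode
the test suite reproduces deliberately on a two-vein fixture. The package
therefore ships a reference wing template whose `lm` polyline is stored
displaced *outside* the wing margin; mapped through the anchor affine and
snapped to the detected endpoints, the initial curve approaches the
costal vein from the artefact-free outside. The reference wing is
synthetic (generated from the canonical wing genome, with `k` equidistant
to `j` and `l` within 5%, the property that keeps mapped arcs from
warping badly); no photographic template is redistributed.

## Morphometric variables

The wing centroid is the area-weighted centroid of the octagon
`a, h, i, j, k, l, m, b`, computed by fan-triangulating from `a` with
signed areas. Any triangulation of a simple polygon yields the same
area-weighted centroid — the package verifies its fan against the
closed-form shoelace centroid over random octagons — so the choice of
split is immaterial. Thirteen centroid distances are normalized by the
wing length $\lVert a - j\rVert$, and three classical indices are added:
costal index `lm/jl`, C3 fringe `kl/jl`, 5X index `gh/fg`. The resulting
16-vector is invariant under similarity transforms of the wing,
reflection included.

## Species identification

Each (species, sex) group with at least `min_group_size = 12` members
(and more members than variables) contributes a sample mean and sample
covariance (n − 1 denominator) on the chosen feature subset; with the
study's per-sex sample counts, two under-sampled female groups drop out
and 28 groups remain. A query is assigned to the group minimizing the
squared Mahalanobis distance $D^2 = (x-\hat\mu_i)^\top
\hat S_i^{-1} (x-\hat\mu_i)$, evaluated through a Cholesky solve rather
than an explicit inverse. If the minimum $D^2$ exceeds the
$\chi^2_p$ quantile at the 0.1% level ($p$ = number of variables; 22.458
for the default six-variable subset), the sample is labelled `unknown`.
Reading the chi-square degrees of freedom as the number of variables is
the only sensible resolution of the rule's notation, and the calibration
test pins the semantics: draws from a fitted group's own Gaussian are
rejected at 0.1% within Monte-Carlo error.

The default subset (`d_e`, `d_f`, `d_g`, `d_m`, `costal_index`,
`c3_fringe`) can be re-derived with `subset_search()`, which enumerates
all $\sum_{k=2}^{16}\binom{16}{k} = 65\,519$ subsets and ranks them by
leave-one-out accuracy. Leave-one-out refits are done by rank-one
downdating of the group mean and scatter (tested to agree exactly with
naive refitting), and a sampling mode keeps desk-scale runs short.

## The synthetic wing generator

The study's photographic dataset is not redistributable, so every test
surface runs on generated images with exact ground truth. A wing genome
fixes 13 canonical key points (reference frame 1936 × 1288), quadratic
Bezier vein strokes between them, vein width (6 px) and darkness (drop
120 below a background of mean 210, sd 8), pose, noise, and an artefact
model. Rendering is deterministic per seed: stroke centrelines are
rasterized, an exact distance transform gives an anti-aliased Gaussian
vein profile, then background noise and artefacts are composited.

Two hazards are mandatory generator features because they exercise the
documented hard cases: a decoy vein parallel to and 60 px below the
costal `lm` section, and bright air-bubble rings plus dark dust specks
placed above the wing (probability 0.2 each) — artefacts above `lm` are
exactly where the out-of-wing initialization can be ambushed.

Exemplar libraries draw per-wing shape jitter (per-key-point Gaussian,
sd 2 px at reference scale), pose jitter (rotation ±15°, scale 0.9–1.1,
small translation), and derived seeds. Anchor clicks are jittered with
the bundled per-landmark annotator covariance matrices, which summarize
the spread of repeated manual annotations (landmarks `a`, `b`, `c`, `k`,
`m` are genuinely hard to click consistently); covariances scale with the
square of the resolution ratio.

The benchmark conditions are a 100-exemplar library and 50 held-out
queries rendered at scale 0.5 (canvas 968 × 644) — chosen once so the
full study-sized search runs comfortably on a single CPU; unit tests use
scale 0.25. Against these conditions the suite checks that at least 85%
of predicted landmarks fall within the 2-standard-deviation criterion of
their annotator covariance and that every traced arc's area error
(enclosed area divided by true arc length) stays below 5 px. Those two
thresholds are calibration targets of this package's generator, not
claims about photographic data. What the synthetic suite does not
emulate: membrane texture, uneven illumination, species-specific shape
families, focus blur — so passing it demonstrates the algorithms, not
field performance.

## Degenerate inputs and numerical conventions

Coordinates are 0-based with pixel centres at integers, x along columns,
y along rows; all interpolation is bilinear with border replication.
Collinear anchors (triangle area ≤ 10⁻⁶ px²) are a hard error. Constant
patches normalize to all zeros. A flat image yields an empty edge map
(warning) and no distance-transform support (error). Octagons that
self-intersect trigger a warning but the signed-area formula still
applies. The evaluation's "2 standard deviations of a covariance matrix"
is read conservatively as twice the square root of the largest
eigenvalue; `sd_mode` exposes mean-diagonal and Mahalanobis readings.
The area between two curves is computed by closing the loop (prediction
forward, truth reversed), splitting at self-crossings, and summing
unsigned lobe areas, so crossing errors accumulate instead of
cancelling.

## Known limitations

Detection requires the three anchor clicks; no anchor-free mode exists.
Landmarks are predicted independently, with no joint shape constraint.
The snake will follow the wrong vein if initialized nearer to it, and
artefacts just above the wing can trap the `lm` contour; corrections are
applied through override tables rather than a GUI. Accuracy degrades at
reduced resolution faster than the parameter scaling alone can
compensate, since the integer shift grid and vein width shrink together.
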