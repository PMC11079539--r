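---
title: "Phase-shift fringe profilometry for lesion measurement: models and methods"
author: "fringe3d"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phase-shift fringe profilometry for lesion measurement: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The measurement problem

Endoscopic size estimates of gastrointestinal lesions are unreliable: the
fisheye optics distort apparent sizes, and the stomach wall is curved, so
the clinically relevant quantity — the distance *along the mucosal
surface* between two points, or the largest surface-path diameter of a
lesion — cannot be read off a 2D image. A structured-light measurement
head (a camera plus a small stripe projector at a known baseline) resolves
this by triangulation: a sinusoidal stripe pattern is projected onto the
tissue and shifted in N known phase steps; the per-pixel phase of the
observed intensity encodes where the surface cuts each projector plane,
which yields a metric 3D surface and, from it, path lengths and lesion
diameters on the curved wall.

`fringe3d` is a software digital twin of such a rig. It contains

* a **simulator**: analytic test surfaces (flat plane, half-pipe jig,
  lesion bumps, marker grids) rendered into phase-shifted fringe stacks
  with controlled Gaussian intensity noise;
* a **reconstruction engine**: N-step wrapped-phase estimation, temporal
  or spatial unwrapping, and per-pixel ray/plane triangulation into a
  metric height map;
* a **measurement layer**: surface profiles, path lengths, virtual base
  surfaces, lesion segmentation, and automatic major/minor diameters;
* an **evaluation harness** replicating two validation experiments — a
  marker-grid height-accuracy study on a curved tissue analog, and a
  section-length study on a lesion-bearing curved scene.

Everything a physical validation would obtain from a reference
measurement microscope is obtained here from the analytic scene itself,
which is exact.

## Geometry and the rig model

The rig (`make_default_rig()`) is an ideal pinhole camera at the origin
looking along +z, with the projector at `(d, 0, 0)`, `d = 60` mm. The
reference plane sits at the standard height `L = 470` mm, where the field
of view is 79 × 66 mm; the default image is 790 × 660 px, i.e. 0.1 mm/px
on the reference plane. The working range is 450–490 mm. The projected
pattern has about 15 stripe periods across the field, so the
reference-plane fringe frequency is `f0 = 15 / 79` cycles/mm. Heights are
reported as `h = L − z`: positive toward the camera (protruding).

Every unwrapped phase value corresponds to a plane through the projector
centre whose trace on the reference plane is a straight stripe line
(`phase_plane()`). Reconstruction intersects each pixel's viewing ray
with its phase plane (`triangulate_pixel()`, vectorised in
`reconstruct_height_map()`). At the image centre this exact intersection
coincides with the classical phase-to-height conversion

    h = L * dphi / (dphi + 2 pi f0 d),    dphi = Phi_ref − Phi,

which the tests use as an independent cross-check; off-centre the exact
ray/plane form is the correct one.

Two **scan directions** are supported. The paper-style experiments scan
once with stripes crossing the curvature ("orthogonal") and once along it
("parallel"). A pattern rotated 90° with an unmoved projector would have
its phase gradient perpendicular to the baseline and carry no
triangulation information, so `scan_direction = "y"` rotates the whole
projector assembly: projector at `(0, d, 0)`, phase varying along y. This
is the physically meaningful reading of scanning in two directions.

Lens distortion, photometric calibration and endoscope mounting are out
of scope; the camera is an ideal pinhole because the modelled rig uses a
long-focal industrial lens, not the endoscope fisheye.

## The simulator

Scenes are single-valued analytic depth fields `z = f(x, y)` with an
albedo field. The half-pipe jig (`half_pipe_surface()`, inner radius
21 mm, crest at 455 mm by default so the whole pipe sits inside the
working range) emulates the curvature of the stomach wall; lesions are
raised-cosine bumps (`add_lesion()`, C¹ at the rim) or truncated
Gaussians; the default stomach-analog lesion is a 10 mm-footprint,
3 mm-high cosine bump, placed at the crest. Marker grids
(`marker_grid()`, default 11 × 8 at exactly 5 mm pitch — 88 points
spanning 50 × 35 mm inside the stated 50 × 45 mm extent; an exact
rectangular grid of 88 points over the full extent does not exist) are
painted as 1 mm dark discs (graphite absorbs; `add_markers()` multiplies
the albedo by 0.05).

Rendering (`render_fringe_stack()`) finds each pixel's surface point by
fixed-point iteration on the depth field, evaluates the projected phase
there, and emits `I_k = albedo * (A + B cos(phi + 2 pi k / N)) + eps`
with `A = 128`, `B = 100`, `eps ~ N(0, noise_sd)` i.i.d. per pixel and
frame, seeded. The noise model is additive Gaussian intensity noise only
— no speckle, specularity, shadowing, occlusion, defocus, or colour
effects. The default `noise_sd = 2` (on `B = 100`) was chosen once as a
plausible industrial-camera noise floor giving a phase noise of about
`sqrt(2/N) * noise_sd / B ≈ 0.014` rad, i.e. ~0.1 mm single-pixel height
noise on this geometry; the harness's precision results must be read as
*this* noise model's consequences, not as a claim about any physical
camera.

What the synthetic data deliberately does not emulate: tissue texture and
albedo variation (apart from markers), organ motion, gamma/nonlinearity
of a real projector, interreflections, and depth-of-field. Passing the
in-silico experiments therefore demonstrates the correctness and noise
behaviour of the *algorithms*, not field performance on tissue.

## Phase recovery and unwrapping

`wrapped_phase()` is the standard N-step least-squares estimator
(`N >= 3`, offsets `2 pi k / N`): `phi = atan2(−S, C)` with
`S = sum I_k sin delta_k`, `C = sum I_k cos delta_k`, modulation estimate
`B = (2/N) sqrt(S² + C²)` and mean `A`. Four steps is the default: the
smallest N with first-order robustness to detector nonlinearity and the
standard choice in practice.

**Validity.** A pixel is valid when `B/A >= 0.1` *and* `B >= 10`
intensity units. The relative test alone cannot reject dark markers — an
albedo drop scales A and B together — so the absolute floor is what
actually removes graphite dots and deeply shadowed pixels; the relative
test removes grazing-incidence and saturated regions. This is why marker
heights must be read beside the dot (`marker_height()`, the ±1.5 mm
two-point average along the half-pipe axis, where the surface is
constant; odd-symmetric surface terms cancel in the average).

**Unwrapping.** The default is temporal two-frequency: a second,
one-stripe pattern (`frequency_ratio = 15`) pins the fringe order per
pixel, `k = round((ratio * phi_low − phi_high) / 2 pi)`, with no spatial
error propagation. One subtlety: a one-stripe pattern spans exactly 2π
across the field, so its wrapped value is branch-ambiguous at the field
edge. Since an in-range surface can shift the low phase from its
reference-plane value by far less than π, the implementation pins the
branch of the measured low phase to the analytic reference low phase
before forming `k`. A quality-guided flood-fill spatial unwrapper (seeded
at the highest-modulation pixel, max-heap frontier, per-region with a
warning when the valid mask is disconnected) is kept for single-frequency
input; its global offset is anchored to the temporal estimate when a low
stack exists.

The reference phase is computed analytically from the rig rather than
from a captured flat-plane stack: the digital twin's reference plane is
exact, and a measured reference would only add noise. Heights outside
±30 mm are flagged invalid (range guard), and no valid output pixel ever
derives from an invalid input pixel.

## Smoothing: scale choice matters

`smooth_height_map()` is masked normalized Gaussian convolution
(invalid pixels neither give nor receive). Smoothing is applied only on
request, because it trades noise against shape fidelity:

* Without smoothing, a polyline path length over noisy samples is
  *biased upward* (each segment gains `~ delta² / (2 step)` from noise of
  SD `delta`); at 0.1 mm stations and ~0.1 mm height noise this inflates
  a 14 mm section by >20 % — unusable.
* With smoothing of scale `sigma`, the surface is flattened by
  `~ sigma²/2` times the local Laplacian; for the gentle 21 mm base and a
  10 mm lesion, `sigma = 0.3` mm (the default, matching the filtered
  protocol of the replicated study) biases lengths well under 1 %.
* For *steep small* lesions (5 mm footprint, 3 mm height, curvature
  ~2.4 /mm) the 0.3 mm filter removes ~5 % of the arc. Diameter
  measurements of fine structures therefore use `sigma` of one pixel
  pitch (0.1 mm), the smallest scale that still suppresses
  noise-on-noise inflation; the rule is to keep `sigma² * curvature`
  small.

## The measurement layer

`extract_profile()` samples a straight lateral segment at
`ceil(len/step)+1` stations by bilinear interpolation (the pixel grid is
regular in image space, not lateral space, so the lateral-to-pixel map is
inverted iteratively through the reconstructed depth). Invalid runs of at
most 3 stations are bridged linearly; longer gaps raise an
unmeasurable-section error naming the gap. `path_length()` is the 3D
polyline length — by construction at least the chord.

`fit_virtual_surface()` reconstructs the healthy base under a lesion: a
total-degree-D bivariate polynomial (default D = 2; curvature is the
leading structure of a stomach wall at this scale) least-squares fitted
over an ROI annulus, the central 0.6-scaled zone excluded as
lesion-contaminated, coordinates centred/scaled for conditioning.
`extract_lesion()` thresholds the residual `h − fit` at 0.5 mm (default;
clinically negligible elevations stay out, and the threshold sits well
above the post-smoothing noise floor) and keeps the largest 8-connected
component, or the component containing a seed point; depressed lesions
use the sign flag.

`lesion_diameters()` implements the clinical "largest diameter": chords
through the mask centroid are scanned over 180 directions at 1° steps;
the direction with the longest masked extent (ties to the smaller angle)
is the major axis and its *surface path length* (not the chord) is the
major diameter; the perpendicular gives the minor. Diameters are measured
on the lesion surface; the footprint chords are also reported. The
measured-along-the-surface convention was chosen over
measured-on-the-base-surface because it matches how a resection margin
follows the mucosa over the lesion.

`base_path_from_flanks()` reproduces the hidden-base estimate: a 1D
polynomial fitted to the profile's flank heights, its arc length
integrated across the lesion span — with flat flanks this is the chord, a
tilted plane gives `span/cos(tilt)` exactly, and a degree-2 fit tracks
the half-pipe arc to better than 1 %.

## The evaluation harness and the problem sizes used

`height_accuracy_experiment()` builds the 21 mm half-pipe with the
88-marker grid, renders both fringe frequencies once per scan direction,
adds fresh seeded noise per repeat, reconstructs, reads every marker
height by the ±1.5 mm rule, and compares against the analytic truth. It
reports the per-point error table, pooled and per-direction population
SD, 3σ, R² of measured vs true heights, and a 0.1 mm-bin histogram. The
default study (30 repeats × 88 markers) yields 2640 data points per
direction, mirroring the replicated protocol; both directions are pooled
in the summary unless a single direction is requested.

`length_accuracy_experiment()` measures three sections on the
stomach-analog scene — A across the lesion over the curvature, B along
the pipe axis, C the base under the lesion from a degree-2 flank fit
(lesion span stated in chord coordinates, converted to arc internally) —
each against the adaptive-quadrature ground truth, plus a lateral check:
markers on a flat scene are localized as centroids of the
modulation-deficit blobs and compared with the generating grid.

All randomness derives from a single master seed (sub-seeds drawn once),
so every report is reproducible bit-for-bit; rendering restores the
caller's RNG state. The package's own acceptance run
(`scripts/acceptance.R`) uses the full-resolution 790 × 660 rig for all
experiments; the test suite uses a 158 × 132 (0.5 mm/px) version of the
same optics for most unit checks and the full rig where a claim depends
on resolution. These sizes were chosen as the smallest grids that keep
sub-pixel effects (bilinear kinks, marker quantization) below the bounds
being asserted.

## Numerical choices and degenerate inputs

* Ray/surface intersection: fixed-point iteration on depth, tolerance
  1e-10 (the depth field is a contraction for near-axis viewing of
  shallow scenes); noiseless end-to-end reconstruction is exact to
  ~1e-13 mm.
* `true_path_length()`: adaptive quadrature (rel. tol 1e-9) of
  `sqrt(1 + z'²)` with central-difference slopes; if the quadrature
  rejects an integrable slope singularity (the vertical wall of a
  full-width half-pipe section), it falls back to a 2^17-segment
  polyline (error O(step^1.5) at a sqrt-type singularity).
* Triangulation flags, never aborts: near-parallel ray/plane pixels,
  non-forward intersections and out-of-guard heights are marked invalid.
* Wrapped phase uses the `(-pi, pi]` convention (`atan2` output −π is
  mapped to +π).
* Ties in the diameter direction search go to the smaller angle; the
  major ≥ minor contract is enforced by swapping if the perpendicular
  surface path exceeds the maximal-chord one (possible on skewed bases).
* Profiles with fewer than 2 valid stations, empty lesion masks (the
  error reports the maximum residual seen) and rank-deficient polynomial
  designs raise structured errors.

## Known limitations

* Single-valued surfaces only: no occlusion or overhangs, so steep walls
  are represented but measured at grazing incidence (excluded from
  accuracy claims beyond 75° incidence).
* The graphite-marker model is a hard albedo disc; real markers have
  soft edges and specular glints, so real lateral-localization error
  will exceed the in-silico figure.
* The noise calibration is a modelling choice; precision figures scale
  accordingly (height noise is linear in `noise_sd` until fringe-order
  errors appear).
* Phase-error compensation for projector gamma, interreflection handling
  and real-time performance are out of scope.
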