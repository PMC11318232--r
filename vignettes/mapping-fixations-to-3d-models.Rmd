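---
title: "Mapping mobile eye-tracking fixations onto 3D models: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping mobile eye-tracking fixations onto 3D models: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

A head-mounted eye tracker reports gaze as 2D coordinates in its
world-camera video. When the participant moves freely around a physical
stimulus, every frame is a different viewpoint, so fixations from
different moments — let alone different observers — cannot be compared
directly. Photogrammetry solves the viewpoint problem: a
structure-from-motion (SfM) reconstruction built from reference
photographs *and* the fixation frames places every camera, including the
world camera at each fixation, in one model coordinate system, alongside a
triangle mesh of the stimulus. What remains is the transfer step this
package implements: turn each 2D gaze sample into a 3D ray (the *visual
beam*) anchored at its frame's reconstructed camera pose, and intersect
that ray with the mesh.

The package deliberately consumes the reconstruction rather than
producing it. Feature matching, sparse/dense reconstruction and surface
meshing are mature external tools; their outputs (an NVM scene file and a
PLY mesh) are the package's inputs. Fixation *detection* is likewise
upstream: the fixation table arrives with whatever dispersion/duration
criteria the vendor software applied.

## Camera model and beam construction

Each registered image contributes a pinhole camera: focal length $f$ in
pixels, unit quaternion $q$ (WXYZ) encoding the world-to-camera rotation
$R$, camera centre $\mathbf{c}$ in model units, and a single radial
distortion coefficient $k$. This is exactly the per-camera content of the
`NVM_V3` export, which stores the camera *centre* (not a translation
vector) and no principal point — the principal point is therefore taken at
the image centre, the exporting tool's own convention. The camera frame
follows the computer-vision axes: x right, y down, z forward.

Normalised gaze positions are converted to pixels as
$u = n_x w$, $v = (1 - n_y) h$. The vertical flip is applied by default
because the common eye-tracker export convention puts the normalised
origin at the bottom-left while image pixels count from the top-left.
This choice is observable: with the wrong flip, every mapped fixation
mirrors vertically, which the synthetic dot test detects immediately. It
is still exposed as a switch (`flip_y = FALSE`, CLI `--no-flip-y`) for
exports that already use top-left coordinates.

Radial distortion follows the one-coefficient model
$r_d = r_u (1 + k\,r_u^2)$ in focal-normalised coordinates about the
principal point. Observed (distorted) pixels are undistorted by the
fixed-point iteration $r_u \leftarrow r_d / (1 + k\,r_u^2)$, tolerance
$10^{-10}$, at most 50 iterations — for the small $|k|$ typical of SfM
exports this converges in a handful of steps, and $k = 0$ is an exact
identity. Distortion handling can be disabled (`--no-distortion`) since
pipelines differ in whether the gaze estimate already lives in an
undistorted image.

The beam is then
$\mathbf{d} \propto R^\top \big((u - c_x)/f,\ (v - c_y)/f,\ 1\big)^\top$,
origin $\mathbf{c}$. The inverse operation — projecting a model point to a
pixel, used by overlays and by every round-trip test — is the exact
algebraic inverse followed by forward distortion. A configuration switch
allows interpreting foreign NVM files whose quaternions encode
camera-to-world instead.

One beam per fixation: binocular vergence (two-ray) mapping is out of
scope, and the single `(norm_x, norm_y)` pair carried by the fixation
table is used as-is, with no aggregation over the fixation's frames.

## Ray–mesh intersection

Single triangles are tested with Möller–Trumbore against the closed
triangle region; the mesh query returns the hit with minimal ray parameter
$t$. Numerical choices, all exposed or tested:

* $t$-epsilon $10^{-9}$ model units rejects self-hits when a beam starts
  on a surface (configurable).
* Barycentric tolerance $10^{-9}$ admits edge and vertex hits; watertight
  adjacent-edge semantics are not guaranteed at the single-triangle level.
* Exact $t$-ties between adjacent faces resolve to the lowest face index,
  making outputs deterministic.
* Both triangle sides are hittable by default — gaze can land on any
  rendered surface — with backface culling available by flag.
* Zero-area faces are counted once and can never be hit.
* Occlusion semantics are geometric: a beam grazing a silhouette maps to
  the nearest surface the ray actually crosses, whether or not a human
  would call it "visible".

The accelerated path prunes faces with a vectorised slab (AABB) test
before running the exact triangle test on survivors. Its contract is
exact agreement with the exhaustive all-faces scan — the tests compare
face index and $t$ to $10^{-9}$ on thousands of random rays — so the
accelerator is a pure optimisation, never a semantic choice. At this
package's problem sizes (meshes up to a few thousand faces, thousands of
rays) the vectorised R implementation is comfortably fast; no compiled
code is needed.

## Pipeline semantics

**Frame assignment.** Each fixation gets the frame whose timestamp is
nearest its *start* timestamp; numerically tied distances (within
$10^{-9}$ relative) resolve to the earlier frame. Start-based selection is
the default because the start is always defined, while midpoint selection
(`timestamp_mode = "mid"`) depends on duration conventions; both are
available. Fixations outside the video span by more than one frame
interval are flagged, never dropped.

**Registration by name.** The scene is expected to already contain poses
for the fixation frames, joined by image file name (exact, or ignoring
the extension). This replaces the interactive step of re-running sparse
reconstruction with the fixation frames added: reconstruction is out of
scope, and the name-join is the minimal faithful interface to it. A frame
with no pose yields status `frame_not_registered` — the row that a user
would map manually; the marked frame image produced by the overlay tool
supports exactly that fallback. No interactive mapping tool is provided.

**Row conservation.** Every fixation produces exactly one projection
record, in fixation order; the three statuses partition the rows, and all
eye-tracker columns pass through untouched. The CSV spells the miss
status with the fixed literal `no intersection between fixation vector
and model`, which downstream tools can key on. The pipeline contains no
randomness; reruns on identical inputs are byte-identical.

## The synthetic harness

The generator emulates a desk-scale recording session in model units of
one metre, so centimetre-scale figures transfer directly:

* **Stimulus**: a closed UV sphere or ellipsoid (or an icosphere for
  face-count-controlled tests), bounding-box height 0.36 by default — a
  36 cm statuette.
* **Reference ring**: 43 cameras per ring at two heights (86 total),
  evenly spaced in azimuth, each aimed exactly at the stimulus centroid —
  the layout of reference photographs taken while circling a stimulus.
* **Dot targets**: four surface dots of radius 0.0125 (2.5 cm diameter)
  by default, sampled area-uniformly and resampled until
  non-overlapping; a vertex-coloured mesh copy marks them red.
* **Observers**: one world-camera pose per fixation at a chosen
  standpoint, aimed at the centroid; the gaze pixel is the target's exact
  projection perturbed by an isotropic angular error with total standard
  deviation `noise_deg` (two independent normal components of
  $\sigma/\sqrt{2}$ each). The default 0.6° is the accuracy figure
  typically quoted for a calibrated mobile tracker. Fixation rows carry
  timestamps on a 30 fps world-frame clock, 150 ms durations (above the
  usual 30 ms detector floor) and zero dispersion, so an upstream
  detector with the usual 3° dispersion cap would accept them. The world
  camera is 1280×720 with a 60° horizontal field of view
  ($f \approx 1108.5$ px).

With these conventions the small-angle prediction is testable in closed
form: at standpoint distance $L$ and angular noise $\sigma$, the mapped
miss distance is approximately Rayleigh with scale $\sigma L / \sqrt{2}$,
giving mean $\sigma L \sqrt{\pi}/2 \approx 0.886\,\sigma L$ — within the
15 % band around $\tan(\sigma) L$ that the calibration test asserts, and
doubling when either $\sigma$ or $L$ doubles. The on-dot rate follows the
Rayleigh tail $1 - \exp(-\rho^2 / (2 (\sigma L/\sqrt{2})^2))$ for dot
radius $\rho$, checked against a 99 % binomial band. Dot scoring uses
Euclidean (not geodesic) distance to the dot centre; with dot radii far
below the surface curvature radius the difference is negligible, which
the placement defaults guarantee.

Every generator is deterministic given its parameters and seed.
Visibility of each target from its standpoint is verified by a ray test
whose tolerance defaults to half the median mesh edge length — the slack
needed when targets lie on the smooth surface that a faceted mesh only
approximates.

What the harness does *not* emulate: photogrammetric reconstruction
error (pose noise can be injected by perturbing the scene table, but SfM
failure modes are not modelled), real image content (frame images are
flat renders used only by overlay tests; geometry tests run image-free),
human manual mappers beyond an isotropic pixel-error model, and real
saccade/fixation dynamics. Passing tests therefore demonstrate the
correctness of the *transfer* chain — pose consumption, beam geometry,
intersection, bookkeeping, formats — not the quality of any particular
reconstruction or tracker calibration.

## Problem sizes and runtime choices

The shipped tests and the acceptance script use sizes chosen to exercise
the properties well inside a single-core minute-scale budget: 20 poses ×
1000 points for the projective round trip; a 1280-face icosphere plus ten
50-face random meshes with 100–1000 rays each for accelerator agreement;
500 fixations for the 0.6° calibration (200 per level for the linearity
check); 100 randomised scenes and meshes for format round trips. Spheres
of resolution 14–24 (≈ 700–2200 faces) stand in for reconstructed
surfaces throughout.

## Known limitations

* One radial coefficient only; strong wide-angle/fisheye lenses need
  undistortion upstream.
* The NVM reader handles the camera block of `NVM_V3` and ignores feature
  points; PLY support covers vertex/face elements with optional vertex
  colour, ascii and binary-little-endian.
* No AOI/VOI statistics, heat maps, scanpath rendering or real-time
  operation: this is a post-hoc transfer tool.
* Real SfM scenes have arbitrary scale; the package never assumes units
  for them. Metric statements (dot sizes, noise-to-distance laws) apply
  to the synthetic scenes, which fix one unit = one metre.
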