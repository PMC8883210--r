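---
title: "Measuring finger contacts from post-touch thermal imaging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring finger contacts from post-touch thermal imaging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thermaltouch)
```

## The measurement problem

Human skin rests around 29.1 °C against a room at about 25.4 °C, so a
grasp deposits a transient warm patch of roughly +3–4 °C wherever a
finger pressed the surface. For a short window after the hand withdraws,
long-wave infrared cameras see those patches directly, including ones
that were occluded by the hand itself during the interaction.
`thermaltouch` converts multi-camera radiometric frames of this
afterglow, plus a 3D scan of the scene and a mesh model of the object,
into contact points `(X, Y, Z)` with radii `r'` in millimeters in the
object's own coordinate frame.

The package assumes: a rigid object with a known triangle mesh; a static
rig of calibrated infrared cameras sharing a reference ("scanner")
frame; frames whose pixel values map linearly to temperature; and an
interaction recent enough that the signatures are still above the
detection threshold. It does not model heat conduction over time, finger
identity, grasp taxonomy, or contact-area extents.

## Pipeline and model choices

**Ambient and detection.** Ambient temperature is the per-frame median —
robust as long as heated regions are a minority of pixels. Detection
thresholds at `ambient + threshold_excess` (default 1.0 °C), labels
8-connected components, and filters by area (default 9 px² to 10 % of
the frame) and circularity `4πA/P²` with the perimeter counted as
boundary pixels (pixels with a 4-neighbor outside their component).
These conventions are pinned so the detector is bit-reproducible. The
center is the excess-weighted centroid, sub-pixel by construction; the
radius is that of the equal-area disk. The circularity floor (0.5)
exists to reject elongated streaks such as specular reflections on
shiny surfaces, the detector's main real-world false-positive source.
With boundary-pixel counting, rasterized disks score slightly *above* 1
(diagonal boundary steps count as one pixel), so the floor is
conservative for compact blobs.

**Calibration target.** The rig is calibrated on a 4 × 11 asymmetric
circle grid, 20.0 mm pitch, 15.0 mm circles, imaged thermally: the
coated board is warmed ~10 °C above the room while the bare-metal
circles reflect the colder surroundings and image as cold disks. The
lattice convention is fixed as: column `c` at `x = c · spacing`, row `r`
at `y = r · spacing`, odd columns offset by `+spacing/2`; ordering is
row-major. Grid labeling aligns whitened detected centers to the
whitened canonical lattice over a rotation/reflection grid, assigns
points by Hungarian matching, and refines with a projective fit. One
subtlety: the lattice is mirror-symmetric left-right, so a
reversed-orientation homography fits a mirrored labeling exactly; since
a physical target is only ever seen from its front face, the fitted
homography's orientation sign disambiguates, and a mirrored solution is
re-indexed through the lattice's mirror automorphism. Circle centers are
blob centroids, not ellipse fits; the perspective eccentricity bias is
below 0.1 px at working distances and is accepted.

**Calibration solve.** Per camera, homographies from ≥3 target poses
give closed-form intrinsics (with a zero-skew prior to keep the minimal
three-view case well conditioned), decomposed extrinsics, and a joint
Levenberg–Marquardt refinement of intrinsics plus per-pose extrinsics.
Cameras are chained into one rig through shared target poses
(breadth-first over the shared-pose graph, averaging over multiple
shared poses); the reference camera stands in for the scanner frame.
Lens distortion is not estimated by default — the synthetic study
conditions use distortion-free cameras, and the distortion model
(5-parameter radial–tangential, order `k1 k2 k3 p1 p2`) is exercised in
the projection layer itself. On exact synthetic observations the solve
recovers parameters to machine precision; through the full
render-detect-solve chain, the ~0.1 px systematic centroid bias of
rasterized circle edges propagates to ≈0.3 % focal error and a few mm of
chained translation, which the reachable (nearly coplanar) pose set
amplifies. Both regimes are tested.

**Localization.** The object pose is point-to-plane ICP between the
scene cloud and the mesh *surface* (exact closest points on triangles,
not vertex nearest neighbors, so coarse tessellation does not bias the
fit). Correspondences beyond `correspondence_radius` (10 mm default) are
rejected; the linearized 6-DoF update is solved in normal equations;
convergence is a pose-update below `convergence_tol` (10⁻³ mm
equivalent). Registration *fails* — an error, not a silent bad pose —
when the converged inlier fraction is below 0.3, the desk-scale analogue
of a localization miss. ICP needs an initial pose inside its convergence
basin (validated to 10 mm / 10°); global pose retrieval is out of scope,
and a known pose can be supplied directly. Rotationally symmetric
objects admit symmetry-equivalent poses; the built-in test meshes are
all asymmetric for this reason.

**Z-buffer and back-projection.** Visibility uses a per-camera depth map
at sensor resolution, computed by first-hit ray casting per pixel
(equivalent to rasterization, and exact under lens distortion since rays
come from the calibrated unprojection). Depth under a sub-pixel blob
center is bilinear over its finite neighbors; a center whose entire
neighborhood is off-object is discarded (the boundary rule). The
back-projected point must snap to the mesh within `snap_tol` (2 mm) —
wide enough to absorb calibration and localization error, tight enough
that background hits cannot attach to the object. The incident angle is
taken between the camera's Z-axis and the flat-shaded normal of the
containing face; the per-pixel viewing ray is a defensible alternative
reading, but the fusion rule only *ranks* angles, and the Z-axis
convention is simpler and fixed here.

**Fusion.** Candidates within 9 mm of each other merge by single-linkage
clustering — the deterministic, order-independent reading of "within
9 mm of each other" — and each cluster keeps its smallest-incident-angle
member (ties: camera name, then smaller radius). Candidates from the
same camera participate like any others, so same-finger double
detections merge too. Fusion is idempotent, and the number of fused
points is non-increasing in the merge radius.

**Evaluation.** Recovered and true contacts are matched one-to-one by
Hungarian assignment under a 9 mm cap (a greedy matcher can steal a
neighbor's only match; the optimal assignment cannot). Conventions:
empty recovery gives precision 1; empty truth gives recall 1.

## The synthetic scene generator

The generator defines the study conditions under which the pipeline is
validated: ambient 25.4 °C, contact peak 29.1 °C, calibration contrast
10 °C, sensor noise σ = 0.05 °C (the sensor noise of the real rig is not
documented; 0.05 °C is typical of cooled microbolometer imagery and is
config-exposed). Scenes use a 4-camera ring (radius 520 mm, height
380 mm, 320 × 256 px, f = 800 px, distortion-free) looking at the
origin, one of three procedural asymmetric meshes (a notched box, an
L-bracket, a low-poly jug with handle), a random pose within ±30° / ±30
mm, and 3–6 contacts of 4–6 mm radius at random surface points separated
by >20 mm, each required to be visible from at least two cameras at a
viewing angle steeper than 70° — grazing views do not produce a usable
signature, so a contact no camera sees squarely is not a valid
measurement condition.

Heat patches are rendered as the camera projection of an isotropic
Gaussian patch (spatial σ = `decay · radius` mm) living on the surface
tangent plane: the image-space footprint has covariance `J Σ Jᵀ` for the
projection Jacobian `J`, so it is an ellipse under oblique viewing and
reduces to an isotropic σ of `decay · radius · fx / depth` px at normal
incidence. The amplitude is `peak − ambient`, and a patch is rendered
only when its surface point is unoccluded per the depth map (1 mm depth
tolerance). An earlier isotropic image-space formulation proved wrong
under foreshortening: it kept the full bump width while compressing the
spacing between neighboring contacts, merging patches in the image that
a physical surface would keep separate. The bump is also clipped to
pixels whose depth lies
within the patch's own depth extent (`3 · decay · radius + 1` mm of the
contact depth): heat belongs to the touched patch, so it must not bleed
across internal depth discontinuities onto unrelated surfaces of the
same silhouette, nor span the hugely foreshortened surface behind a
patch seen at grazing incidence. Without this clipping the generator
painted phantom heat patches tens of millimeters from the contact, which
the pipeline then faithfully — and wrongly, by the ground truth —
reported.

What the generator does *not* emulate, and tests therefore cannot show:
surface-domain heat conduction and cooling curves, emissivity variation
and specular thermal reflections, calibration drift, scanner artifacts
on reflective surfaces, and non-rigid objects. Passing the synthetic
suite demonstrates the geometry and logic of the pipeline, not
robustness to those physical effects.

Every generator output is a pure function of its inputs and a seed;
identical seeds give byte-identical exported scenes.

## Numerical choices and degenerate inputs

Distortion inversion is a fixed-point iteration (≤50 sweeps, 10⁻¹²
tolerance) that errors rather than returning an unconverged ray.
Rotation averaging projects summed rotations back to SO(3) via SVD.
Meshes drop degenerate faces at load; clouds drop non-finite points; a
cloud of rank < 3 is rejected before ICP. A mesh entirely behind a
camera renders an all-infinite depth map with a warning, not an error.
The blob detector's "all pixels above threshold" degenerate case is
guarded although the median ambient makes it unreachable in practice.
Sorting rules (blobs by descending peak excess, contacts by coordinates,
cluster ties by camera then radius) make every output order
deterministic.

## Problem sizes

The validation suite uses 320 × 256 px frames, meshes of 28–136 faces,
clouds of 1 500–3 000 points, and a 20-scene end-to-end benchmark —
desk-scale sizes chosen so the full suite and the acceptance script each
run comfortably on a single CPU while still exercising every stage at
realistic geometry. On these conditions the pipeline recovers all
contacts (precision = recall = 1) with ≈0.3–0.4 mm RMSE against ground
truth — comfortably inside the few-millimeter accuracy regime the
physical rig is expected to reach, where calibration residues and
thermal conduction, not geometry, dominate.

## Known limitations

- ICP is local: no global pose retrieval, and symmetric objects are
  ambiguous by construction.
- The incident-angle fusion rule assumes projection error stays within
  the 9 mm merge radius; observations at extreme grazing angles can
  violate this on real data and would then appear as spurious extra
  contacts.
- Circle centers use blob centroids, so calibration inherits a ~0.1 px
  centroid bias from hard circle edges; ellipse fitting would reduce it
  if tighter rig accuracy were needed.
- The linear counts-to-temperature mapping ignores emissivity; contacts
  on low-emissivity (shiny) surfaces will be under- or mis-detected.
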