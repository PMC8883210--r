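# thermaltouch

Measure **where human fingers touched an object** from the transient heat
the skin leaves behind. When a hand at skin temperature (≈29.1 °C) grasps
an object in a ≈25.4 °C room, each fingertip leaves a short-lived warm
patch of roughly +3–4 °C on the surface. A rig of long-wave infrared
cameras records the scene right after the interaction; `thermaltouch`
turns those radiometric frames into a deduplicated set of contact points
`(X, Y, Z, r′)` in millimeters on the object's own 3D model — the raw
material for studying human prehension: which parts of an object people
actually grip, with which fingers spread how far apart.

The pipeline, per scene:

1. **Blob detection** — threshold each radiometric frame at
   `ambient + 1 °C` (ambient = per-frame median), extract 8-connected
   components, filter by area and circularity, and report each surviving
   heat signature as `(u, v, r)`: intensity-weighted centroid and
   equivalent-disk radius in pixels.
2. **Rig calibration** — a planar 4 × 11 asymmetric circle grid
   (20.0 mm spacing, 15.0 mm circles) that is visible in the thermal band:
   warm coated board, bare-metal circles reflecting the colder room. The
   grid is detected with the same blob detector at inverted polarity,
   ordered canonically, and per-camera intrinsics plus the camera chain
   are solved by planar calibration (closed-form homography decomposition
   + joint Levenberg–Marquardt refinement), so every camera carries a pose
   `(R, T)` relative to the reference frame.
3. **Localization** — the object pose in the scanner frame is estimated by
   point-to-plane ICP between the scene point cloud and the mesh surface,
   with residual and inlier diagnostics and an explicit failure mode.
4. **Contact mapping** — render the object's Z-buffer from each camera at
   sensor resolution, look up the depth under each blob center,
   back-project along the pixel ray, snap to the mesh surface (points off
   the object are discarded), transform to object coordinates, and convert
   the radius by similar triangles (`r′ = r · depth / fx`).
5. **Fusion** — candidates from all cameras within 9 mm of each other
   (single linkage) are merged, keeping the observation with the smallest
   angle between the camera's optical axis and the surface normal — the
   most reliable view wins.

A synthetic-scene generator (procedural asymmetric meshes, a 4-camera
ring, physically parameterized heat patches, scanner-cloud sampling, and
thermal renders of the calibration target) replaces the physical rig so
the entire pipeline runs and is validated at desk scale.

## Worked example

```r
library(thermaltouch)

scene <- make_benchmark_suite(n_scenes = 1, seed = 42)[[1]]
scene
#> <scene_truth> box_notch, 5 contact(s), 4 camera(s), ambient 25.4 degC, seed 42379

frames <- render_scene_frames(scene)
cloud  <- sample_cloud(scene, 3000)
pose   <- register_mesh(scene$mesh, cloud,
                        initial = scene$object_pose$transform)
pose
#> <object_pose> rms 0.0000 mm, inliers 100%, 1 iteration(s)

result <- map_scene(frames, scene$rig, scene$mesh, pose)
tidy(result)
#> # A tibble: 5 × 6
#>       X      Y      Z r_prime incident_angle camera
#>   <dbl>  <dbl>  <dbl>   <dbl>          <dbl> <chr>
#> 1 -9.80 -40    -16.8     3.56           46.3 ir2
#> 2 -5.68  -6.12  20       4.35           50.3 ir0
#> 3 11.6   17.3   20       4.03           50.3 ir0
#> 4 33.2   20      1.84    4.13           53.5 ir0
#> 5 43.8    5.98  17.3     4.20           49.7 ir3

evaluate_contacts(tidy(result), truth_contacts(scene))
#> # A tibble: 1 × 6
#>   precision recall rmse_mm n_matched n_result n_truth
#>       <dbl>  <dbl>   <dbl>     <int>    <int>   <int>
#> 1         1      1   0.217         5        5       5
```

Each row of `tidy(result)` is one recovered contact on the object surface:
its object-frame coordinates in mm, the physical contact radius `r_prime`,
the incident angle of the winning observation (smaller = the surface faced
that camera more squarely), and which camera won the fusion. Here all five
simulated fingertip contacts are recovered with 0.22 mm RMS error.
`autoplot(result)` draws the contact layout; `plot_frame(frames$ir0)`
shows a thermal frame with its detections.

A thin CLI wraps the same functions
(`inst/cli/thermaltouch simulate|calibrate|detect|localize|map|evaluate`).

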