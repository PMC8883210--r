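test_that("canonical target geometry matches the asymmetric lattice", {
  spec <- target_spec()
  tp <- target_points(spec)
  expect_equal(nrow(tp), 44)
  # row-major: first 11 points are row 0, columns 0..10
  expect_equal(tp[1:11, 1], (0:10) * 20)
  expect_equal(tp[1:11, 2], rep(c(0, 10), 6)[1:11])   # odd columns offset
  expect_equal(tp[12, ], c(0, 20, 0))                 # row 1 starts
  expect_true(all(tp[, 3] == 0))
  expect_error(target_spec(spacing = 5, circle_diameter = 15), "spacing")
})

test_that("rendered targets are detected and ordered against truth", {
  rig <- make_rig()
  spec <- target_spec()
  poses <- calibration_poses()
  views <- render_calibration_views(spec, rig, poses[c(1, 4)])
  for (v in views) {
    o <- detect_target(v$frame, spec, pose_id = v$pose_id)
    err <- sqrt(rowSums((o$image_points - v$true_centers)^2))
    expect_lt(max(err), 0.2)     # ordering correct and centers sub-pixel
  }
})

test_that("a 30-degree-rotated target still orders canonically", {
  rig <- make_rig()[1]
  spec <- target_spec()
  base <- rigid_transform(diag(3), c(-100, -45, 0))
  pose <- rt_compose(rigid_transform(rot_axis_angle(c(0, 0, 1), 30)), base)
  v <- render_calibration_views(spec, rig, list(pose))[[1]]
  o <- detect_target(v$frame, spec)
  # nearest-neighbor oracle: detected point i must be closest to truth i
  D <- as.matrix(stats::dist(rbind(o$image_points, v$true_centers)))
  D <- D[1:44, 45:88]
  expect_equal(unname(apply(D, 1, which.min)), 1:44)
})

test_that("partial grids are a detection failure", {
  rig <- make_rig()[1]
  spec <- target_spec()
  v <- render_calibration_views(spec, rig, calibration_poses()[1])[[1]]
  px <- v$frame$pixels
  # paint over one circle with board temperature: 43 candidates remain
  ctr <- v$true_centers[22, ]
  U <- matrix(rep(0:(ncol(px) - 1), each = nrow(px)), nrow(px))
  V <- matrix(rep(0:(nrow(px) - 1), ncol(px)), nrow(px))
  px[(U - ctr[1])^2 + (V - ctr[2])^2 < 15^2] <- max(px)
  expect_error(detect_target(radiometric_frame(px), spec),
               "43 candidate circles")
})

test_that("zero contrast is a negative control", {
  rig <- make_rig()[1]
  spec <- target_spec()
  v <- render_calibration_views(spec, rig, calibration_poses()[1],
                                contrast = 0)[[1]]
  expect_lt(diff(range(v$frame$pixels)), 1e-9)
  expect_error(detect_target(v$frame, spec), "detection failure")
})
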