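test_that("self-consistent observations reproject exactly", {
  rig <- make_rig()
  obs <- exact_observations(rig, calibration_poses())
  cal <- calibrate_rig(obs, width = 320, height = 256)
  expect_lt(cal$mean_reprojection_error, 1e-2)
})

test_that("single-camera intrinsics are recovered from 5 zero-noise poses", {
  rig <- make_rig()[1]
  obs <- exact_observations(rig, calibration_poses())
  cal <- calibrate_rig(obs, width = 320, height = 256)
  expect_lt(abs(cal$cameras[[1]]$fx - 800) / 800, 0.005)
  expect_lt(abs(cal$cameras[[1]]$fy - 800) / 800, 0.005)
})

test_that("inter-camera extrinsics are recovered through shared poses", {
  rig <- make_rig()[1:2]
  obs <- exact_observations(rig, calibration_poses()[1:3])
  cal <- calibrate_rig(obs, width = 320, height = 256)
  Ttrue <- rt_compose(rig[[2]]$pose, rt_inverse(rig[[1]]$pose))
  Test <- cal$cameras[[2]]$pose
  expect_lt(sqrt(sum((Test$translation - Ttrue$translation)^2)), 1)
  expect_lt(rotation_angle(Test$rotation %*% t(Ttrue$rotation)), 0.1)
})

test_that("the recovered chain is independent of the reference choice", {
  rig <- make_rig()
  obs <- exact_observations(rig, calibration_poses())
  cal0 <- calibrate_rig(obs, reference = "ir0", width = 320, height = 256)
  cal1 <- calibrate_rig(obs, reference = "ir1", width = 320, height = 256)
  # relative transform ir1 <- ir0 must agree between the two anchorings
  rel0 <- cal0$cameras[["ir1"]]$pose
  rel1 <- rt_compose(cal1$cameras[["ir1"]]$pose,
                     rt_inverse(cal1$cameras[["ir0"]]$pose))
  expect_lt(max(abs(rel0$rotation - rel1$rotation)), 1e-6)
  expect_lt(max(abs(rel0$translation - rel1$translation)), 1e-6)
})

test_that("insufficient or disconnected observations are errors", {
  rig <- make_rig()[1:2]
  poses <- calibration_poses()
  obs2 <- exact_observations(rig, poses[1:2])
  expect_error(calibrate_rig(obs2), "at least 3")
  # disjoint pose sets: ir0 sees poses 1-3, ir1 sees poses 4-6 (renamed)
  oa <- exact_observations(rig[1], poses[1:3])
  ob <- exact_observations(rig[2], poses[c(1, 3, 5)])
  for (i in seq_along(ob)) ob[[i]]$pose_id <- paste0("other", i)
  expect_error(calibrate_rig(c(oa, ob), width = 320, height = 256),
               "disconnected.*ir1")
})

test_that("the full image-based chain meets its reprojection contract", {
  rig <- make_rig()
  spec <- target_spec()
  views <- render_calibration_views(spec, rig, calibration_poses())
  obs <- lapply(views, function(v)
    detect_target(v$frame, spec, pose_id = v$pose_id))
  cal <- calibrate_rig(obs, width = 320, height = 256)
  expect_lt(cal$mean_reprojection_error, 0.5)
  for (cn in names(rig))
    expect_lt(abs(cal$cameras[[cn]]$fx - 800) / 800, 0.005)
  expect_equal(nrow(tidy(cal)), 4)
  expect_equal(glance(cal)$n_cameras, 4)
})
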