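test_that("contact-free noise-free frames are constant at ambient", {
  rig <- make_rig()
  mesh <- builtin_mesh("box_notch")
  mesh <- mesh_transform(mesh, rigid_transform(diag(3),
                                               -colMeans(mesh$vertices)))
  truth <- scene_truth(mesh, rt_identity(), list(), rig, noise_sigma = 0)
  fr <- render_ir_frame(truth, "ir0")
  expect_lt(diff(range(fr$pixels)), 1e-12)
  expect_equal(fr$pixels[1, 1], 25.4)
})

test_that("rendering is deterministic under the scene seed", {
  suite <- make_benchmark_suite(n_scenes = 1, seed = 12)
  a <- render_ir_frame(suite[[1]], "ir1")
  b <- render_ir_frame(suite[[1]], "ir1")
  expect_identical(a$pixels, b$pixels)
  ca <- sample_cloud(suite[[1]], 500)
  cb <- sample_cloud(suite[[1]], 500)
  expect_identical(ca$points, cb$points)
})

test_that("occluded contacts leave no bump in the blocked view", {
  mesh <- builtin_mesh("box_notch")
  mesh <- mesh_transform(mesh, rigid_transform(diag(3),
                                               -colMeans(mesh$vertices)))
  rig <- make_rig()
  p <- mesh_closest_point(mesh, c(max(mesh$vertices[, 1]), 0, 0))
  truth <- scene_truth(mesh, rt_identity(),
                       list(contact_spec(p$points[1, ])), rig,
                       noise_sigma = 0, seed = 2)
  fr_facing <- render_ir_frame(truth, "ir0")
  fr_hidden <- render_ir_frame(truth, "ir2")
  expect_gt(max(fr_facing$pixels) - 25.4, 3)
  expect_lt(max(fr_hidden$pixels) - 25.4, 1e-9)
})

test_that("off-surface contact centers are rejected at construction", {
  mesh <- builtin_mesh("box_notch")
  rig <- make_rig()
  expect_error(scene_truth(mesh, rt_identity(),
                           list(contact_spec(c(500, 500, 500))), rig),
               "off the mesh surface")
})

test_that("sampled clouds follow the pose rigidly", {
  mesh <- builtin_mesh("l_bracket")
  rig <- make_rig()
  t0 <- scene_truth(mesh, rt_identity(), list(), rig, seed = 6)
  t1 <- scene_truth(mesh, rigid_transform(diag(3), c(10, 0, 0)), list(),
                    rig, seed = 6)
  c0 <- sample_cloud(t0, 2000)
  c1 <- sample_cloud(t1, 2000)
  expect_equal(colMeans(c1$points) - colMeans(c0$points), c(10, 0, 0),
               tolerance = 1e-9)
  cp <- mesh_closest_point(mesh, c0$points)
  expect_lt(max(cp$dist), 1e-9)
})

test_that("the benchmark suite is reproducible and satisfies its contract", {
  s1 <- make_benchmark_suite(n_scenes = 3, seed = 4)
  s2 <- make_benchmark_suite(n_scenes = 3, seed = 4)
  for (i in 1:3) {
    expect_identical(truth_contacts(s1[[i]]), truth_contacts(s2[[i]]))
    tc <- truth_contacts(s1[[i]])
    expect_gte(nrow(tc), 3)
    expect_lte(nrow(tc), 6)
    if (nrow(tc) > 1) {
      D <- as.matrix(stats::dist(tc[, c("X", "Y", "Z")]))
      diag(D) <- Inf
      expect_gt(min(D), 20)     # enforced separation
    }
    cp <- mesh_closest_point(s1[[i]]$mesh,
                             as.matrix(tc[, c("X", "Y", "Z")]))
    expect_lt(max(cp$dist), 0.5)
  }
})

test_that("calibration views return the true projected centers", {
  rig <- make_rig()[1]
  spec <- target_spec()
  pose <- calibration_poses()[[2]]
  v <- render_calibration_views(spec, rig, list(pose))[[1]]
  tp <- target_points(spec)
  pc <- rt_apply(rt_compose(rig[[1]]$pose, pose), tp)
  expect_equal(v$true_centers, project_points(pc, rig[[1]]),
               tolerance = 1e-12)
  expect_error(render_calibration_views(spec, rig, list(rt_identity())),
               "not fully visible")
})
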