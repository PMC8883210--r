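make_test_cloud <- function(mesh, pose, n = 1500, seed = 21) {
  set.seed(seed)
  s <- mesh_sample_surface(mesh, n)
  scene_cloud(rt_apply(pose, s$points))
}

test_that("ICP is a fixed point at the true pose", {
  mesh <- builtin_mesh("box_notch")
  pose <- rigid_transform(rot_axis_angle(c(0, 0, 1), 25), c(15, -10, 5))
  cloud <- make_test_cloud(mesh, pose)
  fit <- register_mesh(mesh, cloud, initial = pose)
  expect_lt(fit$rms_residual, 1e-6)
  expect_equal(fit$inlier_fraction, 1)
  expect_lt(max(abs(fit$transform$rotation - pose$rotation)), 1e-6)
  expect_lt(max(abs(fit$transform$translation - pose$translation)), 1e-6)
})

test_that("poses are recovered from perturbed initials on all meshes", {
  for (nm in c("box_notch", "l_bracket", "jug")) {
    mesh <- builtin_mesh(nm)
    mesh <- mesh_transform(mesh, rigid_transform(diag(3),
                                                 -colMeans(mesh$vertices)))
    pose <- rigid_transform(rot_axis_angle(c(1, 2, -1), 20), c(10, 20, -5))
    cloud <- make_test_cloud(mesh, pose, seed = 4)
    for (off in list(c(5, 5), c(10, 10))) {
      set.seed(13)
      init <- rt_compose(pose, rigid_transform(
        rot_axis_angle(rnorm(3), off[2]),
        rnorm(3) / sqrt(3) * off[1]))
      fit <- register_mesh(mesh, cloud, initial = init,
                           max_iterations = 100)
      dR <- rotation_angle(fit$transform$rotation %*% t(pose$rotation))
      dt <- sqrt(sum((fit$transform$translation - pose$translation)^2))
      expect_lt(dR, 0.1)
      expect_lt(dt, 0.1)
    }
  }
})

test_that("the point-to-plane residual is non-increasing", {
  mesh <- builtin_mesh("l_bracket")
  pose <- rigid_transform(rot_axis_angle(c(0, 1, 0), 10), c(5, 5, 5))
  cloud <- make_test_cloud(mesh, pose, seed = 8)
  set.seed(2)
  init <- rt_compose(pose, rigid_transform(rot_axis_angle(rnorm(3), 8),
                                           c(4, -4, 4)))
  fit <- register_mesh(mesh, cloud, initial = init, max_iterations = 100)
  expect_true(all(diff(fit$history) <= 1e-6))
})

test_that("an unrelated cloud is a localization failure", {
  jug <- builtin_mesh("jug")
  box <- builtin_mesh("box_notch")
  cloud <- make_test_cloud(box, rigid_transform(diag(3), c(400, 0, 0)))
  expect_error(register_mesh(jug, cloud, initial = rt_identity(),
                             max_iterations = 100),
               class = "thermaltouch_localization_failure")
})

test_that("degenerate clouds are rejected", {
  pts <- cbind(runif(100, 0, 50), runif(100, 0, 50), 0)   # rank 2
  expect_error(register_mesh(builtin_mesh("box_notch"), scene_cloud(pts)),
               "rank")
})
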