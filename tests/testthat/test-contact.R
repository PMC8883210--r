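test_that("blobs at known surface projections map back to the surface", {
  rig <- make_rig()
  mesh <- builtin_mesh("box_notch")
  mesh <- mesh_transform(mesh, rigid_transform(diag(3),
                                               -colMeans(mesh$vertices)))
  pose <- object_pose(rigid_transform(rot_axis_angle(c(0, 0, 1), 15),
                                      c(5, -10, 10)))
  set.seed(17)
  s <- mesh_sample_surface(mesh, 200)
  cam <- rig[["ir0"]]
  depth <- render_depth(mesh, pose, cam)
  tested <- 0
  for (k in seq_len(200)) {
    p_obj <- s$points[k, ]
    p_cam <- rt_apply(rt_compose(cam$pose, pose$transform), p_obj)
    if (p_cam[3] <= 0) next
    uv <- project_points(p_cam, cam)
    ui <- round(uv[1]); vi <- round(uv[2])
    if (ui < 2 || ui > cam$width - 3 || vi < 2 || vi > cam$height - 3) next
    d <- depth$depths[vi + 1, ui + 1]
    if (!is.finite(d) || abs(d - p_cam[3]) > 0.5) next   # occluded point
    blob <- tibble::tibble(u = uv[1], v = uv[2], r = 5, camera = "ir0")
    res <- project_blob(blob, depth, mesh, pose, cam)
    expect_equal(res$status, "ok")
    err <- sqrt(sum((c(res$point$X, res$point$Y, res$point$Z) - p_obj)^2))
    expect_lt(err, 0.5)
    tested <- tested + 1
    if (tested >= 40) break
  }
  expect_gte(tested, 20)
})

test_that("blobs over background and out-of-bounds blobs are handled", {
  cam <- test_camera(width = 64, height = 64, cx = 32, cy = 32, fx = 100,
                     fy = 100)
  mesh <- triangle_mesh(rbind(c(-5, -5, 500), c(5, -5, 500), c(0, 5, 500)),
                        rbind(c(1, 2, 3)))
  pose <- object_pose(rt_identity())
  depth <- render_depth(mesh, pose, cam)
  blob_bg <- tibble::tibble(u = 2, v = 2, r = 3, camera = "cam")
  expect_equal(project_blob(blob_bg, depth, mesh, pose, cam)$status,
               "boundary")
  blob_out <- tibble::tibble(u = 90, v = 2, r = 3, camera = "cam")
  expect_error(project_blob(blob_out, depth, mesh, pose, cam),
               "outside sensor bounds")
})

test_that("pixel radii convert to millimeters by similar triangles", {
  cam <- test_camera(fx = 1000, fy = 1000)
  # large plane at z = 500 covering the view
  mesh <- triangle_mesh(rbind(c(-600, -600, 500), c(600, -600, 500),
                              c(0, 900, 500)),
                        rbind(c(1, 2, 3)))
  pose <- object_pose(rt_identity())
  depth <- render_depth(mesh, pose, cam)
  blob <- tibble::tibble(u = 320, v = 256, r = 10, camera = "cam")
  res <- project_blob(blob, depth, mesh, pose, cam)
  expect_equal(res$point$r_prime, 10 * 500 / 1000, tolerance = 1e-6)
})

test_that("fusion retains the smallest incident angle within the radius", {
  base <- tibble::tibble(X = 0, Y = 0, Z = 0, r_prime = 3,
                         incident_angle = 10, camera = "ir0")
  near <- tibble::tibble(X = 5, Y = 0, Z = 0, r_prime = 4,
                         incident_angle = 30, camera = "ir1")
  far <- tibble::tibble(X = 12, Y = 0, Z = 0, r_prime = 4,
                        incident_angle = 30, camera = "ir1")
  fused <- fuse_contacts(rbind(base, near))
  expect_equal(nrow(fused), 1)
  expect_equal(fused$incident_angle, 10)
  expect_equal(nrow(fuse_contacts(rbind(base, far))), 2)
  expect_equal(nrow(fuse_contacts(base[0, ])), 0)
})

test_that("single-linkage chains collapse to one point", {
  chain <- tibble::tibble(X = (0:4) * 6, Y = 0, Z = 0,
                          r_prime = 3, incident_angle = c(40, 25, 33, 8, 19),
                          camera = "ir0")
  fused <- fuse_contacts(chain)
  expect_equal(nrow(fused), 1)
  expect_equal(fused$incident_angle, 8)   # global minimum over the chain
})

test_that("fusion agrees with the exhaustive oracle on small sets", {
  set.seed(55)
  for (trial in 1:60) {
    n <- sample(1:6, 1)
    cand <- random_candidates(n)
    got <- fuse_contacts(cand)
    want <- oracle_fuse(cand, 9)
    expect_equal(as.data.frame(got), as.data.frame(want))
  }
})

test_that("fusion is idempotent and monotone in the merge radius", {
  set.seed(77)
  for (trial in 1:10) {
    cand <- random_candidates(12, spread = 25)
    fused <- fuse_contacts(cand)
    expect_equal(as.data.frame(fuse_contacts(fused)), as.data.frame(fused))
    sizes <- vapply(c(2, 5, 9, 15, 30),
                    function(r) nrow(fuse_contacts(cand, r)), 0L)
    expect_true(all(diff(sizes) <= 0))
  }
})

test_that("map_scene composes the stages and logs them", {
  suite <- make_benchmark_suite(n_scenes = 1, seed = 3, noise_sigma = 0)
  truth <- suite[[1]]
  frames <- render_scene_frames(truth)
  m <- map_scene(frames, truth$rig, truth$mesh, truth$object_pose)
  expect_s3_class(m, "contact_map")
  expect_equal(nrow(m$log), 4)
  expect_true(all(m$log$blobs >= 0))
  met <- evaluate_contacts(tidy(m), truth_contacts(truth))
  expect_equal(met$precision, 1)
  expect_equal(met$recall, 1)
  expect_equal(glance(m)$n_contacts, nrow(m$contacts))
  # every fused contact lies on the mesh surface
  cp <- mesh_closest_point(truth$mesh,
                           as.matrix(m$contacts[, c("X", "Y", "Z")]))
  expect_lt(max(cp$dist), 0.5)
})

test_that("a scene with no heated regions maps to no contacts", {
  suite <- make_benchmark_suite(n_scenes = 1, seed = 5, noise_sigma = 0)
  truth <- suite[[1]]
  truth$contacts <- list()
  frames <- render_scene_frames(truth)
  m <- map_scene(frames, truth$rig, truth$mesh, truth$object_pose)
  expect_equal(nrow(m$contacts), 0)
})

test_that("a contact seen by one camera is recovered from that camera", {
  mesh <- builtin_mesh("box_notch")
  mesh <- mesh_transform(mesh, rigid_transform(diag(3),
                                               -colMeans(mesh$vertices)))
  rig <- make_rig()
  # +x face center: faces ir0 (azimuth 0), hidden from ir2, grazing for
  # ir1/ir3 so the 1 mm depth-visibility test rejects them
  p <- c(max(mesh$vertices[, 1]), 0, 0)
  cp <- mesh_closest_point(mesh, p)
  truth <- scene_truth(mesh, rt_identity(),
                       list(contact_spec(cp$points[1, ])), rig,
                       noise_sigma = 0, seed = 9)
  frames <- render_scene_frames(truth)
  m <- map_scene(frames, rig, mesh, truth$object_pose)
  expect_equal(nrow(m$contacts), 1)
  expect_equal(m$contacts$camera, "ir0")
})
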