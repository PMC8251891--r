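test_that("scene generation is deterministic and satisfies its invariants", {
  s1 <- generate_scene(scene_config(), seed = 1)
  s2 <- generate_scene(scene_config(), seed = 1)
  expect_identical(s1$liver_mesh$vertices, s2$liver_mesh$vertices)
  expect_identical(s1$discs, s2$discs)
  expect_identical(s1$clips, s2$clips)
  s3 <- generate_scene(scene_config(), seed = 2)
  expect_false(identical(s1$tumor_centers, s3$tumor_centers))

  # tumor strictly inside the liver (point-in-mesh over tumor vertices)
  expect_true(all(points_in_mesh(s1$tumor_meshes[[1]]$vertices, s1$liver_mesh)))

  # clips on the liver surface within 0.5 mm
  dclip <- point_mesh_distance(s1$clips, s1$liver_mesh)$distance
  expect_lt(max(dclip), 0.5)

  # intra-tracker disc separation at the configured pairing distance
  for (k in 1:3) {
    d <- sqrt(sum((s1$discs[2 * k - 1, ] - s1$discs[2 * k, ])^2))
    expect_equal(d, 20, tolerance = 1e-6)
  }

  # liver sensor close to the target tumor surface
  dsen <- sqrt(sum((s1$sensor$position - s1$tumor_centers[1, ])^2)) -
    s1$tumor_radius
  expect_lte(dsen, 50)
})

test_that("degenerate and infeasible configurations are handled", {
  s0 <- generate_scene(scene_config(tumor_count = 0), seed = 4)
  expect_identical(nrow(s0$tumor_centers), 0L)
  expect_identical(length(s0$tumor_meshes), 0L)
  expect_identical(nrow(s0$clips), 4L)

  expect_error(scene_config(tumor_radius = 60), "config error")
  expect_error(scene_config(clip_count = 3), "config error")
  expect_error(scene_config(pairing_distance = 5), "config error")
})

test_that("deformation respects the rigid core and moves ribs rigidly", {
  scene <- generate_scene(scene_config(), seed = 3)
  null_model <- deformation_model(breathing_amplitude = c(0, 0, 0))
  s0 <- apply_deformation(scene, null_model, time = 1.23)
  lm <- scene_landmarks(scene)
  pts <- as.matrix(lm[, c("x", "y", "z")])
  ref <- scene_points_em(scene, pts, "liver")
  expect_lt(max(abs(scene_points_em(s0, pts, "liver") - ref)), 1e-9)

  # pure global rigid motion preserves all inter-landmark distances
  G <- make_global_trajectory(shift = c(10, -6, 4), rot_deg = 9,
                              rot_axis = c(1, 2, 0.5), duration = 1)
  rig <- deformation_model(global_trajectory = G,
                           breathing_amplitude = c(0, 0, 0))
  s1 <- apply_deformation(scene, rig, time = 1)
  moved <- scene_points_em(s1, pts, "liver")
  expect_equal(as.numeric(stats::dist(moved)), as.numeric(stats::dist(pts)),
               tolerance = 1e-6)

  # ribs/discs follow only the global rigid part under breathing
  br <- deformation_model(breathing_amplitude = c(0, 0, 10),
                          breathing_period = 4)
  s2 <- apply_deformation(scene, br, time = 1)  # sin(pi/2) = full amplitude
  disc_ref <- scene_points_em(scene, scene$discs, "body")
  expect_lt(max(abs(scene_points_em(s2, scene$discs, "body") - disc_ref)), 1e-9)
  sensor_moved <- drop(scene_points_em(s2, matrix(scene$sensor$position, 1),
                                       "liver"))
  sensor_ref <- drop(scene_points_em(scene, matrix(scene$sensor$position, 1),
                                     "liver"))
  expect_equal(sensor_moved - sensor_ref, c(0, 0, 10), tolerance = 1e-9)
})

test_that("the local field is attenuated at the sensor and smooth", {
  scene <- generate_scene(scene_config(), seed = 3)
  model <- deformation_model(field_magnitude = 10, field_length_scale = 100,
                             breathing_amplitude = c(0, 0, 0), seed = 3)
  u_sensor <- displacement_field(model, scene,
                                 matrix(scene$sensor$position, 1))
  expect_lt(sqrt(sum(u_sensor^2)), 0.1 * 10)   # locally rigid core

  # grid sample: attenuation exactly zero inside the core radius
  set.seed(8)
  dirs <- matrix(stats::rnorm(150), 50, 3)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  near <- sweep(dirs * 25, 2, scene$sensor$position, "+")  # inside 30 mm core
  expect_lt(max(abs(displacement_field(model, scene, near))), 1e-12)

  # far from the core the field reaches deformation-scale magnitudes
  far <- sweep(dirs * 120, 2, scene$sensor$position, "+")
  expect_gt(max(sqrt(rowSums(displacement_field(model, scene, far)^2))), 2)

  # C1 smoothness: central-difference gradient bounded by magnitude / scale
  h <- 0.5
  g <- sapply(1:3, function(ax) {
    e <- diag(3)[ax, ] * h
    (displacement_field(model, scene, sweep(far, 2, e, "+")) -
       displacement_field(model, scene, sweep(far, 2, e, "-"))) / (2 * h)
  })
  expect_lt(max(abs(g)), 10 / 100 * 10)   # |du/dx| << magnitude/length-scale * C
})

test_that("EM streams reproduce ground truth noiselessly and have the stated noise", {
  scene <- generate_scene(scene_config(), seed = 5)
  model <- deformation_model(breathing_amplitude = c(0, 0, 8))
  traj <- scene_trajectory(scene, model)

  clean <- simulate_em_stream(traj, em_noise_model(0, 0, seed = 1),
                              rate = 10, duration = 2)
  ids <- vapply(clean, function(s) s$tool_id, character(1))
  expect_identical(sum(ids == "liver_sensor"), 20L)   # 10 Hz x 2 s
  expect_identical(sum(ids == "tracker_2b"), 20L)
  expect_identical(sum(ids == "pointer"), 20L)

  s0 <- clean[[which(ids == "liver_sensor")[3]]]
  truth <- traj(s0$timestamp)$liver_sensor
  expect_equal(s0$position, truth$position, tolerance = 1e-12)
  expect_equal(s0$orientation, truth$orientation, tolerance = 1e-12)

  # repeatability per seed
  again <- simulate_em_stream(traj, em_noise_model(0.5, 0.3, seed = 9),
                              rate = 10, duration = 1)
  again2 <- simulate_em_stream(traj, em_noise_model(0.5, 0.3, seed = 9),
                               rate = 10, duration = 1)
  expect_identical(again, again2)

  # static tool: per-axis position SD matches sigma_pos within 10%
  static_traj <- function(time) {
    list(probe = pose_sample(time, "probe", c(10, 20, 30),
                             c(1, 0, 0, 0), 6L))
  }
  noisy <- simulate_em_stream(static_traj, em_noise_model(0.5, 0, seed = 2),
                              rate = 100, duration = 10)
  pos <- t(vapply(noisy, function(s) s$position, numeric(3)))
  expect_equal(unname(apply(pos, 2, stats::sd)), rep(0.5, 3),
               tolerance = 0.1)
})

test_that("rendered volumes carry the tissue classes and FOV geometry", {
  scene <- generate_scene(scene_config(), seed = 1)

  # air-only region; a FOV that misses the metal landmarks warns about it
  expect_warning(
    vair <- render_volume(scene, 4, fov = fov_box(c(400, 400, 300), c(40, 40, 40)),
                          modality = "ct", noise_sigma = 5, seed = 1),
    "excludes")
  expect_equal(mean(vair$voxels), -1000, tolerance = 1)

  # tumor center voxel within the tumor class band
  tum_ct <- drop(landmark_in_image(scene, scene$tumor_centers[1, , drop = FALSE],
                                   "liver", "CT"))
  vt <- suppressWarnings(
    render_volume(scene, 2, fov = fov_box(tum_ct, c(30, 30, 30)),
                  modality = "ct", noise_sigma = 5, seed = 2))
  val <- interp_volume(vt, matrix(tum_ct, 1))
  expect_gt(val, 160 - 20)
  expect_lt(val, 160 + 20)

  # standard-FOV CBCT: discs at radius > 12.5 cm fall outside the
  # fully sampled cylinder and are absent (air)
  disc_cbct <- landmark_in_image(scene, scene$discs, "body", "CBCT")
  ctr <- livernav:::default_fov_center(scene, "CBCT")
  rad <- sqrt((disc_cbct[, 1] - ctr[1])^2 + (disc_cbct[, 2] - ctr[2])^2)
  expect_true(all(rad > 125))
  vstd <- suppressWarnings(
    render_volume(scene, 3, fov = "cbct_standard", modality = "cbct",
                  noise_sigma = 5, seed = 3))
  inb <- interp_volume(vstd, disc_cbct)
  expect_true(all(is.na(inb) | inb < -900))

  # truncated FOV: same discs present (metal-blend intensities)
  vtr <- render_volume(scene, 1.5, fov = "cbct_truncated", modality = "cbct",
                       noise_sigma = 5, seed = 3)
  expect_true(all(interp_volume(vtr, disc_cbct, outside = -1000) > 1500))
})
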