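make_pose <- function(t, pos, q = c(1, 0, 0, 0), id = "liver_sensor") {
  pose_sample(t, id, pos, q, 6L)
}

test_that("the semi-rigid tracking transform follows the sensor pose", {
  q0 <- quat_from_axis_angle(c(0.3, 1, 0.2), 0.7)
  S_ref <- make_pose(0, c(10, 20, 30), q0)

  T0 <- liver_tracking_transform(S_ref, S_ref)
  expect_lt(quat_angle(T0$q), 1e-12)
  expect_lt(max(abs(T0$t)), 1e-12)

  # pure sensor translation propagates as pure translation
  S_tr <- make_pose(1, c(10, 20, 45), q0)
  Tt <- liver_tracking_transform(S_tr, S_ref)
  expect_lt(quat_angle(Tt$q), 1e-12)
  expect_equal(Tt$t, c(0, 0, 15), tolerance = 1e-12)

  # sensor rotated 30 degrees about its own position: a model point 40 mm
  # away moves on the 40-mm arc around the sensor
  dq <- quat_from_axis_angle(c(0, 0, 1), pi / 6)
  S_rot <- make_pose(2, c(10, 20, 30), quat_multiply(dq, q0))
  Tr <- liver_tracking_transform(S_rot, S_ref)
  p <- c(50, 20, 30)   # 40 mm from the sensor along +x
  got <- drop(apply_transform(Tr, p))
  expected <- c(10, 20, 30) + drop(quat_rotate(dq, p - c(10, 20, 30)))
  expect_equal(got, expected, tolerance = 1e-9)
  expect_equal(sqrt(sum((got - c(10, 20, 30))^2)), 40, tolerance = 1e-9)

  # translation-only ablation ignores the rotation
  Tab <- liver_tracking_transform(S_rot, S_ref, translation_only = TRUE)
  expect_lt(quat_angle(Tab$q), 1e-12)

  S5 <- pose_sample(0, "liver_sensor", c(0, 0, 0), c(0, 0, 1), 5L)
  expect_error(liver_tracking_transform(S5, S_ref), "dof error")
  expect_error(liver_tracking_transform(make_pose(0, c(0, 0, 0), q0, "other"),
                                        S_ref), "tool mismatch")
})

test_that("registration chains validate their frame labels", {
  S_ref <- make_pose(0, c(0, 0, 0))
  T1 <- identity_transform("MRI", "CBCT")
  T23 <- identity_transform("CBCT", "EM")
  chain <- build_chain(T1, T23, S_ref)
  expect_s3_class(chain, "registration_chain")

  bad_T1 <- identity_transform("MRI", "CT")
  expect_error(build_chain(bad_T1, T23, S_ref), "frame error.*T1")
  expect_error(build_chain(T1, identity_transform("EM", "CBCT"), S_ref),
               "frame error.*T23")
  expect_error(build_chain(T1, T23, S_ref,
                           T4 = identity_transform("MRI", "CBCT")),
               "frame error.*T4")
  S5 <- pose_sample(0, "s", c(0, 0, 0), c(0, 0, 1), 5L)
  expect_error(build_chain(T1, T23, S5), "dof error")
  expect_error(build_chain(T1, T23, S_ref, tracker_ref = diag(3)),
               "6 tracker")
})

test_that("locate_model reduces to the static registration at the snapshot", {
  set.seed(19)
  T1 <- rand_rigid("MRI", "CBCT")
  T23 <- rand_rigid("CBCT", "EM")
  S_ref <- make_pose(0, c(5, -2, 8), quat_from_axis_angle(c(1, 1, 0), 0.4))
  chain <- build_chain(T1, T23, S_ref)
  state <- navigation_state(chain, S_ref)
  pts <- matrix(stats::rnorm(30, sd = 40), 10, 3)
  expect_equal(locate_model(state, pts),
               apply_transform(compose_transform(T23, T1), pts),
               tolerance = 1e-9)
})

test_that("rigid phantom motion is tracked exactly through the chain", {
  scene <- generate_scene(scene_config(), seed = 6)
  model <- deformation_model(
    global_trajectory = make_global_trajectory(c(12, -8, 5), 10,
                                               c(0.2, 1, 0.4), duration = 1),
    breathing_amplitude = c(0, 0, 0))
  snap <- apply_deformation(scene, model, 0)
  chain <- exact_chain(snap)
  st <- apply_deformation(scene, model, 0.8)
  state <- navigation_state(chain, sensor_pose_em(st, 0.8))
  tum_true <- scene_points_em(st, scene$tumor_centers, "liver")
  tum_nav <- locate_model(state, scene$tumor_centers)
  expect_lt(max(abs(tum_true - tum_nav)), 1e-9)

  # under EM noise the located tumor stays within a few sigma of truth
  traj <- scene_trajectory(scene, model)
  stream <- simulate_em_stream(traj, em_noise_model(0.5, 0, seed = 12),
                               rate = 10, duration = 1,
                               tools = "liver_sensor")
  s_noisy <- stream[[9]]
  state_n <- navigation_state(chain, s_noisy)
  st2 <- apply_deformation(scene, model, s_noisy$timestamp)
  err <- sqrt(sum((scene_points_em(st2, scene$tumor_centers[1, , drop = FALSE],
                                   "liver") -
                     locate_model(state_n, scene$tumor_centers[1, , drop = FALSE]))^2))
  expect_lt(err, 3 * 0.5 + 1)   # position noise plus a small rotation lever
})

test_that("the rib frame separates body motion from liver motion", {
  scene <- generate_scene(scene_config(), seed = 6)
  null_model <- deformation_model(breathing_amplitude = c(0, 0, 0))
  snap <- apply_deformation(scene, null_model, 0)
  chain <- exact_chain(snap)

  live_same <- scene_points_em(snap, snap$discs, "body")
  R0 <- rib_frame(live_same, chain)
  expect_lt(quat_angle(R0$q), 1e-9)
  expect_lt(max(abs(R0$t)), 1e-9)

  # whole-body rigid shift: liver-relative-to-ribs motion is identity
  G <- make_global_trajectory(c(15, 5, -10), 7, c(1, 0.3, 0), duration = 1)
  gmodel <- deformation_model(global_trajectory = G,
                              breathing_amplitude = c(0, 0, 0))
  moved <- apply_deformation(scene, gmodel, 1)
  state <- navigation_state(chain, sensor_pose_em(moved, 1))
  rel <- liver_relative_to_ribs(state, scene_points_em(moved, moved$discs, "body"))
  expect_lt(quat_angle(rel$q), 1e-9)
  expect_lt(max(abs(rel$t)), 1e-9)

  # liver-only breathing: ribs static, relative motion = tracking transform
  bmodel <- deformation_model(breathing_amplitude = c(0, 0, 10),
                              breathing_period = 4)
  breathed <- apply_deformation(scene, bmodel, 1)
  state_b <- navigation_state(chain, sensor_pose_em(breathed, 1))
  rel_b <- liver_relative_to_ribs(state_b,
                                  scene_points_em(breathed, breathed$discs, "body"))
  track <- liver_tracking_transform(state_b$S_live, chain$S_ref)
  expect_equal(rel_b$t, track$t, tolerance = 1e-9)
  expect_lt(rotation_error_deg(rel_b$q, track$q), 1e-9)

  collinear <- matrix(rep(seq(0, 100, by = 20), each = 3)[1:18], 6, 3,
                      byrow = TRUE)
  chain2 <- chain
  chain2$tracker_ref <- collinear
  expect_error(rib_frame(collinear + 0.5, chain2), "collinear")
})

test_that("pointer-to-tumor distance matches oracles and flags the zone", {
  scene <- generate_scene(scene_config(), seed = 6)
  snap <- apply_deformation(scene,
                            deformation_model(breathing_amplitude = c(0, 0, 0)),
                            0)
  chain <- exact_chain(snap)
  state <- navigation_state(chain, sensor_pose_em(snap, 0))
  mesh <- scene$tumor_meshes[[1]]
  mesh_em <- transform_mesh(mesh, state$model_to_em_live)

  # a tip on a transformed vertex is at distance zero
  tip0 <- mesh_em$vertices[40, ]
  expect_lt(pointer_to_tumor_distance(tip0, state, mesh)$distance, 1e-9)

  # sphere closed form along a vertex direction: 25 mm from center -> 10 mm
  ctr_em <- drop(apply_transform(state$model_to_em_live,
                                 scene$tumor_centers[1, ]))
  vdir <- (mesh_em$vertices[7, ] - ctr_em) / 15
  tip <- ctr_em + 25 * vdir
  expect_equal(pointer_to_tumor_distance(tip, state, mesh)$distance, 10,
               tolerance = 1e-9)

  # a tip inside the tumor reports zero
  inside_tip <- ctr_em + 5 * vdir
  res_in <- pointer_to_tumor_distance(inside_tip, state, mesh)
  expect_identical(res_in$distance, 0)
  expect_true(res_in$inside)

  # indexed distance equals the brute-force all-triangles oracle
  set.seed(33)
  tips <- sweep(matrix(stats::rnorm(60, sd = 50), 20, 3), 2, ctr_em, "+")
  for (i in 1:20) {
    a <- pointer_to_tumor_distance(tips[i, ], state, mesh, index = TRUE)
    b <- pointer_to_tumor_distance(tips[i, ], state, mesh, index = FALSE)
    expect_equal(a$distance, b$distance, tolerance = 1e-9)
  }

  sensor <- state$S_live$position
  z0 <- in_target_zone(sensor, state)
  expect_true(z0$inside)
  expect_equal(z0$distance_to_sensor, 0)
  offset <- c(1, 0, 0)
  expect_true(in_target_zone(sensor + 50 * offset, state)$inside)   # closed
  expect_false(in_target_zone(sensor + 50.1 * offset, state)$inside)
})
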