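test_that("image distance agrees between mesh and mask representations", {
  ctr <- c(10, -5, 20)
  mesh <- mesh_ellipsoid(ctr, c(10, 10, 10), subdivisions = 3)

  # sphere closed form along a vertex direction: clip at 18 mm -> 8 mm
  vdir <- (mesh$vertices[33, ] - ctr) / 10
  expect_equal(image_distance(ctr + 18 * vdir, mesh), 8, tolerance = 1e-9)

  # mask mode: sphere segmentation at 1 mm voxels
  g <- expand.grid(x = seq(-15, 15), y = seq(-15, 15), z = seq(-15, 15))
  inside <- rowSums(as.matrix(g)^2) <= 10^2
  seg <- volume_image(array(as.numeric(inside), c(31, 31, 31)),
                      c(1, 1, 1), origin = ctr - 15)
  clip_on <- ctr + c(10, 0, 0)
  expect_lt(image_distance(clip_on, seg), 0.5)        # on the surface
  d_mask <- image_distance(ctr + c(18, 0, 0), seg)
  d_mesh <- image_distance(ctr + c(18, 0, 0), mesh)
  expect_lt(abs(d_mask - d_mesh), sqrt(3))            # one voxel diagonal

  expect_error(image_distance(c(0, 0, 0),
                              volume_image(array(0, c(4, 4, 4)), c(1, 1, 1))),
               "empty tumor")
})

test_that("accuracy statistics implement the absolute-difference measure", {
  rec <- function(id, dn, di) accuracy_record(id, dn, di)
  equal <- lapply(1:5, function(i) rec(i, i * 3, i * 3))
  s0 <- accuracy_stats(equal)
  expect_equal(s0$mean_abs_diff, 0)
  expect_equal(s0$pearson_r, 1, tolerance = 1e-12)

  shifted <- lapply(1:5, function(i) rec(i, i * 3 + 2, i * 3))
  s2 <- accuracy_stats(shifted)
  expect_equal(s2$mean_abs_diff, 2)
  expect_equal(s2$sd, 0)
  expect_equal(s2$pearson_r, 1, tolerance = 1e-12)
  expect_identical(s2$n, 5L)

  expect_error(accuracy_stats(equal[1:2]), "sample-size")
  flat <- lapply(1:4, function(i) rec(i, 5, i * 2))
  expect_warning(sf <- accuracy_stats(flat), "zero variance")
  expect_true(sf$degenerate)
  expect_true(is.na(sf$pearson_r))

  # observer averaging defines d_img
  r <- accuracy_record("m1", 4, observer_values = c(3, 5, 7))
  expect_equal(r$d_img, 5)
  expect_error(accuracy_record("m1", 4, d_img = 9,
                               observer_values = c(3, 5, 7)),
               "mean of observer_values")
})

test_that("accuracy statistics recover simulated measurement noise", {
  # d_img ~ U(2, 40), d_nav = d_img + N(0, 3): closed-form targets
  n_rec <- 40
  n_seeds <- 12
  mad <- numeric(n_seeds)
  r <- numeric(n_seeds)
  for (s in seq_len(n_seeds)) {
    set.seed(400 + s)
    d_img <- stats::runif(n_rec, 2, 40)
    d_nav <- pmax(0, d_img + stats::rnorm(n_rec, 0, 3))
    recs <- lapply(seq_len(n_rec), function(i)
      accuracy_record(i, d_nav[i], d_img[i]))
    st <- accuracy_stats(recs)
    mad[s] <- st$mean_abs_diff
    r[s] <- st$pearson_r
  }
  expect_equal(mean(mad), 3 * sqrt(2 / pi), tolerance = 0.15)
  sd_img2 <- 38^2 / 12
  expect_equal(mean(r), sqrt(sd_img2 / (sd_img2 + 9)), tolerance = 0.05)
})

test_that("repeat variability reports per-point ranges", {
  expect_equal(repeat_variability(list(a = c(7, 7, 7)))$mean_spread, 0)
  rv <- repeat_variability(list(a = c(10, 12, 15), b = c(1, 2)))
  expect_equal(unname(rv$per_point["a"]), 5)
  expect_equal(rv$mean_spread, 3)
  expect_error(repeat_variability(list(a = 5)), "single repeat")

  # three observers with 1-mm normal jitter: mean range 3 / sqrt(pi)
  set.seed(77)
  spreads <- replicate(300, {
    m <- lapply(1:12, function(i) stats::rnorm(3, 20, 1))
    repeat_variability(m)$mean_spread
  })
  expect_equal(mean(spreads), 3 / sqrt(pi), tolerance = 0.05)
})

test_that("the TRE profile is zero for rigid noise-free tracking and grows off-zone", {
  scene <- generate_scene(scene_config(), seed = 8)
  rigid <- deformation_model(
    global_trajectory = make_global_trajectory(c(10, 4, -6), 8, c(0, 1, 1),
                                               duration = 1),
    breathing_amplitude = c(0, 0, 0))
  snap <- apply_deformation(scene, rigid, 0)
  chain <- exact_chain(snap)
  times <- seq(0, 1, by = 0.25)
  scenes <- lapply(times, function(t) apply_deformation(scene, rigid, t))
  states <- lapply(seq_along(times), function(i)
    navigation_state(chain, sensor_pose_em(scenes[[i]], times[i])))
  pts <- scene$liver_mesh$vertices[seq(1, 642, by = 6), ]
  prof <- tre_profile(scenes, states, pts, reference_scene = scene)
  expect_lt(max(prof$mean_tre, na.rm = TRUE), 1e-9)

  # noise-only static tracking: mean TRE matches an independent Monte-Carlo
  # of the same noise model at the same lever arms
  null_model <- deformation_model(breathing_amplitude = c(0, 0, 0))
  snap0 <- apply_deformation(scene, null_model, 0)
  chain0 <- exact_chain(snap0)
  sigma_pos <- 0.5
  traj <- scene_trajectory(scene, null_model)
  stream <- simulate_em_stream(traj, em_noise_model(sigma_pos, 0, seed = 5),
                               rate = 10, duration = 30,
                               tools = "liver_sensor")
  states_n <- lapply(stream, function(s) navigation_state(chain0, s))
  scenes_n <- rep(list(snap0), length(states_n))
  p_near <- matrix(scene$sensor$position + c(5, 0, 0), 1)
  prof_n <- tre_profile(scenes_n, states_n, p_near, reference_scene = scene)
  # oracle: the reference pose is noise-free here, so TRE = || dp_live ||
  # with dp_live ~ N(0, sigma^2 I3)
  set.seed(91)
  mc <- replicate(20000, sqrt(sum(stats::rnorm(3, 0, sigma_pos)^2)))
  got <- mean(attr(prof_n, "tre"))
  expect_equal(got, mean(mc), tolerance = 0.15)
})
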