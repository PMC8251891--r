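test_that("bone masking follows the intensity window and cleans speckle", {
  scene <- generate_scene(scene_config(), seed = 2)
  rib_ct <- landmark_in_image(scene, matrix(scene$ribs[[3]]$center +
                                              c(0, scene$ribs[[3]]$radius, 0), 1),
                              "body", "CT")
  vol <- suppressWarnings(
    render_volume(scene, 1, fov = fov_box(drop(rib_ct), c(60, 60, 40)),
                  modality = "ct", noise_sigma = 5, seed = 4))
  clean <- suppressWarnings(
    render_volume(scene, 1, fov = fov_box(drop(rib_ct), c(60, 60, 40)),
                  modality = "ct", noise_sigma = 0, seed = 4))
  n_bone <- sum(clean$voxels >= 700 & clean$voxels <= 1500)
  m <- bone_mask(vol, 600, 1600)
  expect_equal(sum(m$voxels), n_bone, tolerance = 0.05)

  air <- volume_image(array(-1000, c(8, 8, 8)), c(1, 1, 1))
  expect_error(bone_mask(air, 600, 1600), "empty-mask")
  expect_error(bone_mask(air, 1600, 600), "lo < hi")

  everything <- bone_mask(vol, -2000, 4000)
  expect_true(all(everything$voxels))
})

test_that("center-of-mass alignment recovers pure translations", {
  m <- array(FALSE, c(20, 20, 20))
  m[8:12, 9:13, 5:9] <- TRUE
  fixed <- volume_image(m, c(2, 2, 2), origin = c(0, 0, 0), frame = "CBCT")
  moving_same <- volume_image(m, c(2, 2, 2), origin = c(0, 0, 0), frame = "CT")
  T0 <- com_align(fixed, moving_same)
  expect_equal(T0$t, c(0, 0, 0), tolerance = 1e-12)
  expect_identical(T0$frame_from, "CT")
  expect_identical(T0$frame_to, "CBCT")

  # same voxels, origin shifted: exact world-space translation
  moving <- volume_image(m, c(2, 2, 2), origin = c(-12, 0, 7), frame = "CT")
  T1 <- com_align(fixed, moving)
  expect_equal(T1$t, c(12, 0, -7), tolerance = 1e-12)

  # single-voxel masks: exact difference vector
  a <- array(FALSE, c(5, 5, 5)); a[2, 3, 4] <- TRUE
  b <- array(FALSE, c(5, 5, 5)); b[4, 2, 1] <- TRUE
  va <- volume_image(a, c(1, 1, 1), frame = "CBCT")
  vb <- volume_image(b, c(1, 1, 1), frame = "CT")
  expect_equal(com_align(va, vb)$t, c(2 - 4, 3 - 2, 4 - 1) * 1.0)
})

test_that("masked MI registration recovers known offsets", {
  scene <- generate_scene(scene_config(), seed = 2)
  params <- registration_params()
  cbct <- suppressWarnings(render_volume(scene, 3, fov = "cbct_truncated",
                                         modality = "cbct", seed = 12))
  ct <- render_volume(scene, 3, modality = "ct", seed = 11)
  fm <- bone_mask(cbct, params$bone_lo, params$bone_hi)

  # self-registration: fixed == moving, identity init
  self_mask <- bone_mask(cbct, params$bone_lo, params$bone_hi)
  moving_self <- cbct
  moving_self$frame <- "CBCT2"
  r0 <- register_mi(cbct, moving_self,
                    identity_transform("CBCT2", "CBCT"),
                    fixed_mask = self_mask, params = params)
  expect_lt(sqrt(sum(r0$transform$t^2)), 0.1)
  expect_lt(quat_angle(r0$transform$q) * 180 / pi, 0.1)

  # cross-modality offset recovery with COM init
  set.seed(61)
  off <- rand_rigid("CT", "CT", max_t = 10, max_angle = 4 * pi / 180)
  ct_off <- offset_volume_geometry(ct, off)
  mm <- bone_mask(ct_off, params$bone_lo, params$bone_hi)
  init <- com_align(fm, mm)
  r <- register_mi(cbct, ct_off, init, fixed_mask = fm, params = params)
  gt <- compose_transform(gt_ct_to_cbct(scene), invert_transform(off))
  expect_lt(sqrt(sum((r$transform$t - gt$t)^2)), 3)        # 1 voxel
  expect_lt(rotation_error_deg(r$transform$q, gt$q), 0.5)
  expect_true(r$converged)

  # determinism: identical inputs give bit-identical transforms
  r2 <- register_mi(cbct, ct_off, init, fixed_mask = fm, params = params)
  expect_identical(r$transform, r2$transform)
  expect_identical(r$metric, r2$metric)

  # MI is invariant to monotone intensity remapping
  remapped <- cbct
  remapped$voxels <- 800 * tanh(cbct$voxels / 700) + cbct$voxels / 8
  remapped$frame <- "CBCT2"
  rr <- register_mi(cbct, remapped, identity_transform("CBCT2", "CBCT"),
                    fixed_mask = self_mask, params = params)
  expect_lt(sqrt(sum(rr$transform$t^2)), 3)
  expect_lt(quat_angle(rr$transform$q) * 180 / pi, 1)

  # frame mismatch in the init is refused
  expect_error(register_mi(cbct, ct_off, identity_transform("EM", "CBCT"),
                           fixed_mask = fm, params = params),
               "frame mismatch")
})

test_that("ROI registration isolates local alignment and supports manual mode", {
  # two-structure volume: blob A (in ROI) and blob B move differently
  grid <- expand.grid(x = seq(0, 99, by = 2), y = seq(0, 99, by = 2),
                      z = seq(0, 59, by = 2))
  # blob B is dominant, so an unrestricted registration locks onto it
  blobs <- function(cA, cB) {
    g <- 300 * exp(-rowSums(sweep(as.matrix(grid), 2, cA, "-")^2) / (2 * 8^2)) +
         500 * exp(-rowSums(sweep(as.matrix(grid), 2, cB, "-")^2) / (2 * 14^2))
    volume_image(array(g, c(50, 50, 30)), c(2, 2, 2), frame = "F")
  }
  fixed <- blobs(c(30, 30, 30), c(76, 70, 30))
  moving <- blobs(c(35, 30, 30), c(61, 70, 30))   # A: +5 in x; B: -15 in x
  moving$frame <- "M"
  roi <- list(lo = c(10, 10, 10), hi = c(50, 50, 50))
  p <- registration_params(levels = 2, step_trans = 2)
  r_roi <- register_roi(fixed, moving, roi, identity_transform("M", "F"),
                        params = p)
  expect_lt(abs(r_roi$transform$t[1] - (-5)), 2)     # local offset, 1 voxel
  r_all <- register_mi(fixed, moving, identity_transform("M", "F"), params = p)
  expect_gt(abs(r_all$transform$t[1] - (-5)), 4)     # whole-volume is pulled off

  # manual pass-through relabels the frames and returns verbatim
  set.seed(3)
  manual <- rand_rigid("X", "Y")
  rm <- register_roi(fixed, moving, roi, identity_transform("M", "F"),
                     manual = manual)
  expect_identical(rm$transform$q, manual$q)
  expect_identical(rm$transform$t, manual$t)
  expect_identical(rm$transform$frame_from, "M")
  expect_identical(rm$transform$frame_to, "F")

  out_roi <- list(lo = c(500, 500, 500), hi = c(600, 600, 600))
  expect_error(register_roi(fixed, moving, out_roi,
                            identity_transform("M", "F")),
               "roi error")
})
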