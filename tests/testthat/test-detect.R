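test_that("metal blobs are localized with sub-voxel accuracy", {
  scene <- generate_scene(scene_config(), seed = 1)
  spacing <- 0.66
  set.seed(14)
  errs <- numeric(8)
  for (i in seq_along(errs)) {
    k <- ((i - 1) %% 6) + 1
    truth <- drop(landmark_in_image(scene, scene$discs[k, , drop = FALSE],
                                    "body", "CBCT"))
    # random sub-voxel alignment between the disc and the grid
    ctr <- truth + stats::runif(3, -spacing / 2, spacing / 2)
    vol <- render_patch(scene, ctr, size = 24, spacing = spacing,
                        seed = 100 + i)
    b <- detect_metal_blobs(vol, threshold = 2000, min_vol = 25, max_vol = 400)
    expect_identical(nrow(b), 1L)
    errs[i] <- sqrt(sum((as.numeric(b[1, c("x", "y", "z")]) - truth)^2))
    expect_gt(b$volume_mm3[1], 50)
    expect_lt(b$volume_mm3[1], 300)
  }
  expect_lt(max(errs), 0.5 * spacing)
  expect_lt(mean(errs), 0.25 * spacing)
})

test_that("empty volumes and merged components are handled", {
  empty <- volume_image(array(50, c(10, 10, 10)), c(1, 1, 1))
  expect_identical(nrow(detect_metal_blobs(empty, 2000)), 0L)

  # two discs fused into one supra-threshold component exceed max_vol
  v <- array(0, c(40, 40, 20))
  v[8:24, 15:25, 8:12] <- 3000
  fused <- volume_image(v, c(1, 1, 1))
  expect_message(
    b <- detect_metal_blobs(fused, 2000, min_vol = 25, max_vol = 400),
    "merged")
  expect_identical(nrow(b), 0L)
})

test_that("detection is invariant to intensity scaling above threshold", {
  scene <- generate_scene(scene_config(), seed = 1)
  truth <- drop(landmark_in_image(scene, scene$discs[2, , drop = FALSE],
                                  "body", "CBCT"))
  vol <- render_patch(scene, truth, seed = 7)
  vol2 <- vol
  vol2$voxels <- vol$voxels * 1.8
  b1 <- detect_metal_blobs(vol, 2000, 25, 400)
  b2 <- detect_metal_blobs(vol2, 2000 * 1.8, 25, 400 * 4)
  expect_lt(sqrt(sum((as.numeric(b1[1, 1:3]) - as.numeric(b2[1, 1:3]))^2)),
            0.05)
})

test_that("blobs are grouped into trackers with distractors excluded", {
  set.seed(3)
  fix <- synthetic_tracker_blobs(sep = 20, n_clips = 0)
  lay <- group_into_trackers(fix$blobs, 20, tol = 2)
  expect_identical(dim(lay$centers), c(6L, 3L))
  expect_equal(sort(lay$pair_distances), sort(rep(20, 3)), tolerance = 0.1)

  # a 7th blob (clip misdetection) far from the pairing distance is excluded
  set.seed(4)
  fix7 <- synthetic_tracker_blobs(sep = 20, n_clips = 1)
  lay7 <- group_into_trackers(fix7$blobs, 20, tol = 2)
  got <- lay7$centers[order(lay7$centers[, 1], lay7$centers[, 2]), ]
  want <- fix7$true_centers[order(fix7$true_centers[, 1],
                                  fix7$true_centers[, 2]), ]
  expect_equal(got, want, tolerance = 1e-9)

  expect_error(group_into_trackers(fix$blobs[1:5, ], 20), "grouping error")
  # six blobs but no geometry near the pairing distance
  set.seed(5)
  scatter <- fix$blobs
  scatter[1:6, 1:3] <- matrix(stats::runif(18, -200, 200), 6, 3)
  expect_error(group_into_trackers(scatter, 20, tol = 2), "grouping error")
})

test_that("clips are detected in a liver ROI and outside-FOV clips are absent", {
  scene <- generate_scene(scene_config(), seed = 1)
  clips_cbct <- landmark_in_image(scene, scene$clips, "liver", "CBCT")
  ctr <- colMeans(clips_cbct)
  vol <- render_patch(scene, ctr, size = 2 * max(abs(sweep(clips_cbct, 2, ctr))) + 20,
                      spacing = 0.66, seed = 21)
  roi <- list(lo = apply(clips_cbct, 2, min) - 8,
              hi = apply(clips_cbct, 2, max) + 8)
  found <- detect_clips(vol, roi)
  expect_identical(nrow(found), 4L)
  for (i in 1:4) {
    d <- min(sqrt(rowSums(sweep(found, 2, clips_cbct[i, ], "-")^2)))
    expect_lt(d, 0.5)
  }

  # a clip beyond the rendered FOV is simply not detected
  roi_all <- list(lo = roi$lo - 100, hi = roi$hi + 100)
  small <- render_patch(scene, clips_cbct[1, ], size = 12, spacing = 0.66,
                        seed = 22)
  found1 <- detect_clips(small, roi_all)
  expect_lte(nrow(found1), 2L)

  expect_error(detect_clips(vol, list(lo = c(900, 900, 900),
                                      hi = c(910, 910, 910))), "roi error")
})

test_that("full-vs-truncated localization displacement is sub-voxel", {
  expect_error(truncation_consistency(diag(3), diag(3)[1:2, ]), "cardinality")

  pts <- matrix(c(0, 0, 0, 100, 0, 0, 0, 100, 0, 50, 50, 80), 4, 3,
                byrow = TRUE)
  same <- truncation_consistency(pts, pts)
  expect_equal(same$displacement, rep(0, 4))

  shifted <- pts
  shifted[2, 1] <- shifted[2, 1] + 0.66
  one <- truncation_consistency(pts, shifted)
  expect_equal(one$mean, 0.66 / 4, tolerance = 1e-9)

  # the same disc localized in a clean and a degraded (truncated-FOV
  # periphery) reconstruction moves by less than one 0.66 mm voxel
  scene <- generate_scene(scene_config(), seed = 2)
  disc_cbct <- landmark_in_image(scene, scene$discs, "body", "CBCT")
  ctr_scan <- livernav:::default_fov_center(scene, "CBCT")
  centers_full <- matrix(NA_real_, 3, 3)
  centers_trunc <- matrix(NA_real_, 3, 3)
  for (k in 1:3) {
    fov_clean <- fov_box(disc_cbct[k, ], rep(24, 3))
    clean <- suppressWarnings(render_volume(scene, 0.66, fov_clean, "cbct",
                                            noise_sigma = 10, seed = 30 + k))
    fov_deg <- fov_clean
    fov_deg$cylinder_diameter <- 250
    fov_deg$cylinder_length <- 200
    fov_deg$cylinder_center <- ctr_scan
    fov_deg$truncated <- TRUE
    degraded <- suppressWarnings(render_volume(scene, 0.66, fov_deg, "cbct",
                                               noise_sigma = 10, seed = 60 + k))
    centers_full[k, ] <- as.numeric(
      detect_metal_blobs(clean, 2000, 25, 400)[1, c("x", "y", "z")])
    centers_trunc[k, ] <- as.numeric(
      detect_metal_blobs(degraded, 2000, 25, 400)[1, c("x", "y", "z")])
  }
  res <- truncation_consistency(centers_full, centers_trunc)
  expect_lt(res$mean, 0.66)
})
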