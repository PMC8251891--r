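# Shared fixtures: everything is generated in code at test time.

# Random rigid transform (caller controls the RNG state).
rand_rigid <- function(frame_from = "A", frame_to = "B",
                       max_t = 50, max_angle = pi) {
  axis <- stats::rnorm(3)
  ang <- stats::runif(1, -max_angle, max_angle)
  rigid_transform(quat_from_axis_angle(axis, ang),
                  stats::runif(3, -max_t, max_t), frame_from, frame_to)
}

rotation_error_deg <- function(qa, qb) {
  quat_angle(quat_multiply(qa, quat_conjugate(qb))) * 180 / pi
}

# Reposition a volume's grid rigidly in its world frame (used to create a
# known offset between two volumes without re-rendering).
offset_volume_geometry <- function(vol, T) {
  vol$origin <- drop(apply_transform(T, vol$origin))
  vol$direction <- quat_to_matrix(T$q) %*% vol$direction
  vol
}

# Ground-truth CT -> CBCT transform of a scene in a given motion state.
gt_ct_to_cbct <- function(snap) {
  g <- compose_transform(
    snap$gt$em_to_cbct,
    compose_transform(snap$motion$body$rigid,
                      invert_transform(snap$gt$mri_to_ct)))
  rigid_transform(g$q, g$t, "CT", "CBCT")
}

# Ground-truth MRI -> CBCT (model alignment) at a motion state.
gt_mri_to_cbct <- function(snap) {
  lr <- snap$motion$liver$rigid_part
  if (is.null(lr)) lr <- snap$motion$liver$rigid
  g <- compose_transform(snap$gt$em_to_cbct, lr)
  rigid_transform(g$q, g$t, "MRI", "CBCT")
}

# Exact registration chain for a scene at its snapshot state.
exact_chain <- function(snap, S_ref = sensor_pose_em(snap)) {
  build_chain(gt_mri_to_cbct(snap),
              invert_transform(snap$gt$em_to_cbct),
              S_ref,
              scene_points_em(snap, snap$discs, "body"))
}

# Render a small patch around a world point (image frame given by modality).
render_patch <- function(scene, center_img, size = 24, spacing = 0.66,
                         modality = "cbct", seed = 1, noise_sigma = 10) {
  suppressWarnings(render_volume(
    scene, spacing, fov = fov_box(center_img, rep(size, 3)),
    modality = modality, noise_sigma = noise_sigma, seed = seed))
}

# Synthetic tracker layout (3 pairs at `sep` mm) plus clip distractors,
# for grouping tests without rendering.
synthetic_tracker_blobs <- function(sep = 20, n_clips = 2, jitter = 0.1) {
  base <- rbind(c(0, 0, 0), c(60, 20, 10), c(-50, 40, 30))
  dirs <- rbind(c(1, 0, 0), c(0, 1, 0), c(0.6, 0, 0.8))
  centers <- do.call(rbind, lapply(1:3, function(k) {
    rbind(base[k, ] - dirs[k, ] * sep / 2, base[k, ] + dirs[k, ] * sep / 2)
  }))
  centers <- centers + matrix(stats::rnorm(18, 0, jitter), 6, 3)
  clips <- matrix(stats::runif(n_clips * 3, -120, 120), n_clips, 3)
  # keep distractors away from disc pairing range of any true disc
  for (i in seq_len(n_clips)) {
    repeat {
      d <- sqrt(rowSums(sweep(centers, 2, clips[i, ], "-")^2))
      if (all(abs(d - sep) > 6)) break
      clips[i, ] <- stats::runif(3, -120, 120)
    }
  }
  pts <- rbind(centers, clips)
  df <- data.frame(x = pts[, 1], y = pts[, 2], z = pts[, 3],
                   volume_mm3 = c(rep(100, 6), rep(10, n_clips)),
                   peak = c(rep(3000, 6), rep(2900, n_clips)),
                   axis1 = 8, axis2 = 8, axis3 = 2)
  class(df) <- c("blob_detections", "data.frame")
  list(blobs = df, true_centers = centers)
}
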