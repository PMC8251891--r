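# End-to-end reproducible run: generate a phantom, render CT + CBCT, build
# the registration chain (T4 by masked MI, T23 by six-point registration of
# detected disc sensors against live EM readings, T1 manually or by ROI
# registration), capture the sensor snapshot, replay the EM stream, and
# emit guidance and accuracy outputs plus a JSON report of all FRE/TRE/
# metric values. Deterministic per seeds.

#' Ramped global rigid trajectory
#'
#' Linear ramp from identity at `t = 0` to the given shift/rotation at
#' `t = duration`; rotation about a fixed center in the EM frame.
#'
#' @param shift final translation, mm.
#' @param rot_deg final rotation angle, degrees.
#' @param rot_axis rotation axis.
#' @param center rotation center, mm (EM frame).
#' @param duration seconds to reach the final pose.
#' @return function(time) -> `rigid_transform` EM -> EM.
#' @export
make_global_trajectory <- function(shift = c(0, 0, 0), rot_deg = 0,
                                   rot_axis = c(0, 0, 1),
                                   center = c(0, 0, 0), duration = 1) {
  force(shift); force(rot_deg); force(rot_axis); force(center); force(duration)
  function(time) {
    a <- min(max(time / duration, 0), 1)
    q <- quat_from_axis_angle(rot_axis, a * rot_deg * pi / 180)
    t <- a * shift + center - drop(quat_rotate(q, center))
    rigid_transform(q, t, "EM", "EM")
  }
}

#' Assemble a run configuration
#'
#' All parameters of a full pipeline run, serializable to YAML; a persisted
#' configuration re-runs to identical outputs.
#'
#' @param seed master seed (scene, noise, rendering all derive from it).
#' @param scene a [scene_config()] (or a plain list of its arguments, as
#'   read back from YAML) describing the phantom.
#' @param zone_radius target-navigation-zone radius, mm.
#' @param sigma_pos,sigma_rot EM noise, mm / degrees.
#' @param spacing_ct,spacing_cbct render spacings, mm (coarser than the
#'   clinical 0.66 mm grid to keep desk-scale runs tractable).
#' @param spacing_candidate spacing of the whole-FOV metal candidate scan,
#'   mm (fine enough that a disc's partial-volume intensity clears the bone
#'   ceiling).
#' @param spacing_detect spacing of the fine detection patches rendered
#'   around each candidate, mm (the clinical reconstruction grid).
#' @param motion `"none"`, `"rigid"` (ramped global shift + rotation),
#'   `"breathing"` or `"deformed"` (adds the attenuated local field).
#' @param shift,rot_deg global rigid motion parameters (motion != "none").
#' @param field_magnitude,field_length_scale local deformation field, mm.
#' @param breathing_amplitude cranio-caudal breathing amplitude, mm.
#' @param rate,duration EM stream rate (Hz) and length (s).
#' @param snapshot_time CBCT acquisition time, s (breath-hold sample).
#' @param t1_mode `"manual"` (ground-truth pass-through, mirroring the
#'   clinical manual alignment) or `"roi"` (automated ROI registration).
#' @param registration_source `"detected"` (image detections drive T23) or
#'   `"ground_truth"` (exact landmark positions; isolates tracking-chain
#'   properties from detection error).
#' @param do_t4 run the CT -> CBCT bone MI registration stage.
#' @param out_dir optional output directory for report/guidance files.
#' @return named list of class `run_config`.
#' @export
run_config <- function(seed = 7L, scene = scene_config(), zone_radius = 50,
                       sigma_pos = 0, sigma_rot = 0,
                       spacing_ct = 3, spacing_cbct = 3,
                       spacing_candidate = 1.5, spacing_detect = 0.66,
                       motion = c("rigid", "none", "breathing", "deformed"),
                       shift = c(8, -5, 12), rot_deg = 6,
                       field_magnitude = 10, field_length_scale = 100,
                       breathing_amplitude = 10,
                       rate = 10, duration = 2, snapshot_time = 0,
                       t1_mode = c("manual", "roi"),
                       registration_source = c("detected", "ground_truth"),
                       do_t4 = TRUE, out_dir = NULL) {
  if (!inherits(scene, "scene_config")) {
    scene <- do.call(scene_config, scene[!vapply(scene, is.null, logical(1))])
  }
  cfg <- list(seed = as.integer(seed), scene = scene, zone_radius = zone_radius,
              sigma_pos = sigma_pos, sigma_rot = sigma_rot,
              spacing_ct = spacing_ct, spacing_cbct = spacing_cbct,
              spacing_candidate = spacing_candidate,
              spacing_detect = spacing_detect,
              motion = match.arg(motion), shift = shift, rot_deg = rot_deg,
              field_magnitude = field_magnitude,
              field_length_scale = field_length_scale,
              breathing_amplitude = breathing_amplitude,
              rate = rate, duration = duration, snapshot_time = snapshot_time,
              t1_mode = match.arg(t1_mode),
              registration_source = match.arg(registration_source),
              do_t4 = do_t4, out_dir = out_dir)
  class(cfg) <- c("run_config", "list")
  cfg
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("stage error [%s]: %s", stage, conditionMessage(e)),
         call. = FALSE)
  })
}

build_model_from_config <- function(cfg, scene) {
  em_center <- drop(scene_points_em(scene, matrix(scene$body$center, 1), "body"))
  traj <- if (cfg$motion %in% c("rigid", "breathing", "deformed")) {
    if (cfg$motion == "rigid") {
      make_global_trajectory(cfg$shift, cfg$rot_deg, c(0.3, 1, 0.5),
                             em_center, cfg$duration)
    } else NULL
  } else NULL
  deformation_model(
    global_trajectory = traj,
    breathing_amplitude = if (cfg$motion %in% c("breathing", "deformed"))
      c(0, 0, cfg$breathing_amplitude) else c(0, 0, 0),
    field_magnitude = if (cfg$motion == "deformed") cfg$field_magnitude else 0,
    field_length_scale = cfg$field_length_scale,
    seed = cfg$seed)
}

#' Run the full navigation pipeline on a phantom
#'
#' Executes every stage of the registration pipeline end-to-end and
#' collects all quality figures. Stage failures propagate with the stage
#' name; when `out_dir` is set, partial outputs written so far are
#' retained for debugging.
#'
#' @param config a [run_config()].
#' @return run report: a named list with the resolved configuration, the
#'   FRE of the six-point registration, T1/T23/T4 errors against ground
#'   truth, per-frame guidance rows, and TRE summaries (in-zone and
#'   overall).
#' @export
run_pipeline <- function(config = run_config()) {
  cfg <- config
  report <- list(config = unclass(cfg)[setdiff(names(cfg), "out_dir")])
  report$config$scene <- unclass(report$config$scene)
  out_dir <- cfg$out_dir
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  emit <- function() {
    if (!is.null(out_dir)) {
      jsonlite::write_json(report, file.path(out_dir, "report.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
    }
  }

  scene <- with_stage("phantom", generate_scene(cfg$scene, cfg$seed))
  model <- with_stage("phantom", build_model_from_config(cfg, scene))
  traj <- scene_trajectory(scene, model)
  snap <- with_stage("phantom", apply_deformation(scene, model, cfg$snapshot_time))

  # EM stream over the run; the snapshot poses are the samples nearest the
  # CBCT acquisition time (breath-hold convention).
  noise <- em_noise_model(cfg$sigma_pos, cfg$sigma_rot, seed = cfg$seed + 1L)
  stream <- with_stage("em_stream",
    simulate_em_stream(traj, noise, cfg$rate, cfg$duration, t0 = 0))
  ids <- vapply(stream, function(s) s$tool_id, character(1))
  ts <- vapply(stream, function(s) s$timestamp, numeric(1))
  nearest <- function(tool) {
    k <- which(ids == tool)
    k[which.min(abs(ts[k] - cfg$snapshot_time))]
  }
  disc_tools <- sprintf("tracker_%d%s", rep(1:3, each = 2), c("a", "b"))
  S_ref <- stream[[nearest("liver_sensor")]]
  tracker_ref <- do.call(rbind, lapply(disc_tools, function(tl)
    stream[[nearest(tl)]]$position))

  # T4: bone-to-bone CT -> CBCT by masked MI, COM-initialized.
  gt_T4 <- compose_transform(
    snap$gt$em_to_cbct,
    compose_transform(snap$motion$body$rigid,
                      invert_transform(scene$gt$mri_to_ct)))
  gt_T4 <- rigid_transform(gt_T4$q, gt_T4$t, "CT", "CBCT")
  if (cfg$do_t4) {
    ct <- with_stage("render_ct",
      render_volume(scene, cfg$spacing_ct, modality = "ct",
                    seed = cfg$seed + 2L))
    cbct <- with_stage("render_cbct",
      render_volume(snap, cfg$spacing_cbct, fov = fov_preset("cbct_truncated"),
                    modality = "cbct", seed = cfg$seed + 3L))
    t4 <- with_stage("register_t4", {
      p <- registration_params()
      fm <- bone_mask(cbct, p$bone_lo, p$bone_hi)
      mm <- bone_mask(ct, p$bone_lo, p$bone_hi)
      init <- com_align(fm, mm)
      register_mi(cbct, ct, init, fixed_mask = fm, params = p)
    })
    report$t4 <- list(metric = t4$metric, converged = t4$converged,
                      translation_error_mm =
                        sqrt(sum((t4$transform$t - gt_T4$t)^2)),
                      rotation_error_deg =
                        quat_angle(quat_multiply(
                          t4$transform$q, quat_conjugate(gt_T4$q))) * 180 / pi)
    emit()
  }

  # T23: disc-sensor centers in the CBCT registered to live EM positions.
  # Coarse candidate scan on the rendered CBCT, then fine patches at the
  # clinical 0.66-mm-class grid around each candidate (emulating detection
  # on the full-resolution reconstruction without rendering all of it).
  gt_disc_cbct <- landmark_in_image(snap, snap$discs, "body", "CBCT")
  if (cfg$registration_source == "detected") {
    det <- with_stage("detect_discs", {
      cand_vol <- render_volume(snap, cfg$spacing_candidate,
                                fov = fov_preset("cbct_truncated"),
                                modality = "cbct", seed = cfg$seed + 4L)
      cand <- detect_metal_blobs(cand_vol, threshold = 1800,
                                 min_vol = 3, max_vol = 2000)
      if (nrow(cand) == 0) stop("no metal candidates found in the CBCT")
      scan_center <- c(0, 0, 0)   # CBCT iso-centre
      discs_f <- list(); clips_f <- list()
      for (i in seq_len(nrow(cand))) {
        ctr <- as.numeric(cand[i, c("x", "y", "z")])
        fovp <- fov_box(ctr, c(26, 26, 26))
        fovp$cylinder_diameter <- 250
        fovp$cylinder_length <- 200
        fovp$cylinder_center <- scan_center
        fovp$truncated <- TRUE
        patch <- suppressWarnings(
          render_volume(snap, cfg$spacing_detect, fov = fovp,
                        modality = "cbct", seed = cfg$seed + 4L + i))
        pb <- detect_metal_blobs(patch, threshold = 2000, min_vol = 1,
                                 max_vol = 400)
        discs_f[[i]] <- pb[pb$volume_mm3 >= 25, , drop = FALSE]
        clips_f[[i]] <- pb[pb$volume_mm3 <= 20, , drop = FALSE]
      }
      list(discs = do.call(rbind, discs_f), clips = do.call(rbind, clips_f))
    })
    blobs <- with_stage("detect_discs", {
      b <- det$discs
      # fine patches around neighbouring candidates can see the same disc
      if (!is.null(b) && nrow(b) > 1) {
        keep <- rep(TRUE, nrow(b))
        ctrs <- blob_centers(b)
        for (i in seq_len(nrow(b) - 1)) {
          if (!keep[i]) next
          for (j in seq(i + 1, nrow(b))) {
            if (sqrt(sum((ctrs[i, ] - ctrs[j, ])^2)) < 4) keep[j] <- FALSE
          }
        }
        b <- b[keep, , drop = FALSE]
      }
      if (is.null(b) || nrow(b) < 6) {
        n <- if (is.null(b)) 0 else nrow(b)
        stop(sprintf("found only %d of 6 tracker discs (%d missing, possibly outside the FOV)",
                     n, 6 - n))
      }
      b
    })
    layout <- with_stage("detect_discs",
      group_into_trackers(blobs, snap$config$pairing_distance, tol = 3))
    disc_cbct <- layout$centers
    report$disc_detection_error_mm <-
      mean(truncation_consistency(gt_disc_cbct, disc_cbct)$displacement)
  } else {
    disc_cbct <- gt_disc_cbct
  }
  t23 <- with_stage("register_t23", {
    f <- match_correspondence(disc_cbct, tracker_ref,
                              frame_src = "CBCT", frame_dst = "EM")
    register_points(f)
  })
  report$t23_fre_mm <- t23$fre
  gt_T23 <- invert_transform(snap$gt$em_to_cbct)
  report$t23_translation_error_mm <- sqrt(sum((t23$transform$t - gt_T23$t)^2))

  # T1: model (MRI) -> CBCT around the target lesion.
  liver_rigid_snap <- snap$motion$liver$rigid_part %||% snap$motion$liver$rigid
  gt_T1 <- compose_transform(snap$gt$em_to_cbct, liver_rigid_snap)
  gt_T1 <- rigid_transform(gt_T1$q, gt_T1$t, "MRI", "CBCT")
  if (cfg$t1_mode == "manual") {
    T1 <- gt_T1
    report$t1 <- list(mode = "manual")
  } else {
    mri <- with_stage("render_mri",
      render_volume(scene, cfg$spacing_ct, modality = "mri",
                    seed = cfg$seed + 5L))
    cbct_t1 <- with_stage("render_cbct",
      render_volume(snap, cfg$spacing_cbct, fov = fov_preset("cbct_truncated"),
                    modality = "cbct", seed = cfg$seed + 6L))
    tum_cbct <- drop(landmark_in_image(snap, snap$tumor_centers[1, , drop = FALSE],
                                       "liver", "CBCT"))
    roi <- list(lo = tum_cbct - 60, hi = tum_cbct + 60)
    init <- rigid_transform(gt_T1$q, gt_T1$t, "MRI", "CBCT")  # manual pre-alignment
    r1 <- with_stage("register_t1",
      register_roi(cbct_t1, mri, roi, init))
    T1 <- r1$transform
    report$t1 <- list(mode = "roi", metric = r1$metric,
                      translation_error_mm = sqrt(sum((T1$t - gt_T1$t)^2)))
  }
  emit()

  chain <- with_stage("build_chain",
    build_chain(T1, t23$transform, S_ref, tracker_ref))

  # Replay: guidance per frame + TRE against ground truth.
  sample_pts <- rbind(scene$tumor_centers, scene$clips,
                      scene$liver_mesh$vertices[seq(1, nrow(scene$liver_mesh$vertices),
                                                    by = 8), ])
  d_sensor <- sqrt(rowSums(sweep(sample_pts, 2, scene$sensor$position, "-")^2))
  frame_times <- sort(unique(ts))
  guidance <- vector("list", length(frame_times))
  tre_all <- matrix(NA_real_, length(frame_times), nrow(sample_pts))
  tumor_mesh <- scene$tumor_meshes[[1]]
  for (i in seq_along(frame_times)) {
    tt <- frame_times[i]
    k <- which(ids == "liver_sensor" & ts == tt)[1]
    state <- navigation_state(chain, stream[[k]], zone_radius = cfg$zone_radius)
    truth <- apply_deformation(scene, model, tt)
    tre_all[i, ] <- sqrt(rowSums((scene_points_em(truth, sample_pts, "liver") -
                                    locate_model(state, sample_pts))^2))
    kp <- which(ids == "pointer" & ts == tt)[1]
    ptr <- stream[[kp]]$position
    dist <- pointer_to_tumor_distance(ptr, state, tumor_mesh)
    zone <- in_target_zone(ptr, state)
    guidance[[i]] <- data.frame(
      time = tt, tumor_distance_mm = dist$distance,
      in_zone = zone$inside, distance_to_sensor_mm = zone$distance_to_sensor)
  }
  guidance <- do.call(rbind, guidance)
  in_zone_pts <- d_sensor <= cfg$zone_radius
  report$tre <- list(
    max_in_zone_mm = max(tre_all[, in_zone_pts]),
    mean_in_zone_mm = mean(tre_all[, in_zone_pts]),
    max_overall_mm = max(tre_all),
    n_points = nrow(sample_pts), n_frames = length(frame_times))

  if (!is.null(out_dir)) {
    utils::write.csv(guidance, file.path(out_dir, "guidance.csv"),
                     row.names = FALSE)
    write_run_config(report$config, file.path(out_dir, "config_used.yaml"))
  }
  emit()
  report$guidance <- guidance
  invisible(report)
}
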