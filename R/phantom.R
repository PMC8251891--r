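# Synthetic phantom: ground-truth scenes that emulate a contrast-CBCT liver
# surgery setting — liver with tumor(s) and vessels, ribs, four surgical
# clips, three patient trackers carrying six disc-shaped 5-DoF sensors, one
# liver-surface 6-DoF sensor — plus deformation/breathing trajectories and
# noisy EM pose streams. Everything is a pure function of (config, seed) and
# every landmark's true position is queryable at any time.
#
# Frames: "MRI" is the reference frame the geometry is authored in (the
# preoperative model frame); "EM" is the world frame where tracking lives;
# "CBCT" and "CT" are scanner frames. Ground-truth placement and scanner
# poses are stored in scene$gt so every pipeline transform has a known truth.

#' Phantom scene configuration
#'
#' Default geometry approximates an adult abdomen: body ellipsoid
#' 340 x 260 x 220 mm, liver ellipsoid 240 x 160 x 120 mm, one 15-mm-radius
#' superficial tumor, four surgical clips and one 6-DoF sensor on the liver
#' surface near the tumor, three posterior patient trackers each carrying two
#' disc sensors 20 mm apart, and six rib arcs.
#'
#' @param liver_semiaxes,liver_center liver ellipsoid, mm (MRI frame).
#' @param body_semiaxes,body_center body (soft-tissue) ellipsoid, mm.
#' @param tumor_count,tumor_radius number of tumors and radius, mm.
#' @param clip_count number of surgical clips (the clinical setup uses 4).
#' @param clip_spread tangential spread of clips around the tumor site, mm.
#' @param tracker_count patient trackers (3), each with 2 disc sensors.
#' @param pairing_distance intra-tracker disc center distance, mm.
#' @param disc_radius,disc_thickness disc sensor dimensions, mm.
#' @param clip_radius clip radius, mm (clip volume stays below 20 mm^3).
#' @param sensor_tumor_max_distance maximum allowed distance from the liver
#'   sensor to the nearest tumor surface, mm (clinically the sensor sits
#'   within ~3 cm of the target, always inside the 5-cm navigation zone).
#' @param rib_count,rib_tube_radius rib arcs and their tube radius, mm.
#' @param vessel_count,vessel_radius contrast vessel tubes and radius, mm.
#' @param placement rigid transform MRI -> EM at the reference state (patient
#'   placement on the OR table); NULL for the default non-trivial pose.
#' @param em_to_cbct rigid transform EM -> CBCT (scanner pose); NULL for the
#'   default non-trivial pose.
#' @param mri_to_ct rigid transform MRI -> CT (preoperative CT pose); NULL
#'   for the default.
#' @return a list of class `scene_config`.
#' @export
scene_config <- function(liver_semiaxes = c(120, 80, 60),
                         liver_center = c(20, -25, 10),
                         body_semiaxes = c(170, 130, 110),
                         body_center = c(0, 0, 0),
                         tumor_count = 1,
                         tumor_radius = 15,
                         clip_count = 4,
                         clip_spread = 22,
                         tracker_count = 3,
                         pairing_distance = 20,
                         disc_radius = 4,
                         disc_thickness = 2,
                         clip_radius = 1.5,
                         sensor_tumor_max_distance = 50,
                         rib_count = 6,
                         rib_tube_radius = 5,
                         vessel_count = 3,
                         vessel_radius = 4,
                         placement = NULL,
                         em_to_cbct = NULL,
                         mri_to_ct = NULL) {
  cfg <- list(liver_semiaxes = liver_semiaxes, liver_center = liver_center,
              body_semiaxes = body_semiaxes, body_center = body_center,
              tumor_count = tumor_count, tumor_radius = tumor_radius,
              clip_count = clip_count, clip_spread = clip_spread,
              tracker_count = tracker_count, pairing_distance = pairing_distance,
              disc_radius = disc_radius, disc_thickness = disc_thickness,
              clip_radius = clip_radius,
              sensor_tumor_max_distance = sensor_tumor_max_distance,
              rib_count = rib_count, rib_tube_radius = rib_tube_radius,
              vessel_count = vessel_count, vessel_radius = vessel_radius,
              placement = placement, em_to_cbct = em_to_cbct,
              mri_to_ct = mri_to_ct)
  class(cfg) <- "scene_config"
  validate_scene_config(cfg)
  cfg
}

validate_scene_config <- function(cfg) {
  if (any(cfg$liver_semiaxes <= 0) || any(cfg$body_semiaxes <= 0)) {
    stop("config error: semi-axes must be positive")
  }
  if (cfg$tumor_count > 0 &&
      cfg$tumor_radius >= min(cfg$liver_semiaxes) * 0.8) {
    stop("config error: tumor radius too large for the liver semi-axes")
  }
  if (cfg$tumor_count < 0) stop("config error: negative tumor count")
  if (cfg$clip_count != 4) {
    stop("config error: the surgical setup uses exactly 4 clips")
  }
  if (cfg$tracker_count != 3) {
    stop("config error: the setup uses exactly 3 patient trackers")
  }
  if (cfg$pairing_distance <= 2 * cfg$disc_radius) {
    stop("config error: pairing distance must exceed the disc diameter")
  }
  invisible(TRUE)
}

# Surface point of an ellipsoid along direction d from its center.
ellipsoid_surface_point <- function(center, semiaxes, d) {
  s <- 1 / sqrt(sum((d / semiaxes)^2))
  center + s * d
}

# Outward unit normal of an ellipsoid at surface point p.
ellipsoid_normal <- function(center, semiaxes, p) {
  n <- 2 * (p - center) / semiaxes^2
  n / sqrt(sum(n^2))
}

# Orthonormal frame (3x3, columns) whose 3rd column is z.
frame_from_z <- function(z) {
  z <- z / sqrt(sum(z^2))
  ref <- if (abs(z[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  x <- cross3(ref, z)
  x <- x / sqrt(sum(x^2))
  y <- cross3(z, x)
  cbind(x, y, z)
}

default_placement <- function() {
  rigid_transform(quat_from_axis_angle(c(0.2, 1, 0.3), 5 * pi / 180),
                  c(20, -15, 10), "MRI", "EM")
}

default_em_to_cbct <- function() {
  rigid_transform(quat_from_axis_angle(c(0, 0.3, 1), 8 * pi / 180),
                  c(-12, 8, -5), "EM", "CBCT")
}

default_mri_to_ct <- function() {
  rigid_transform(quat_from_axis_angle(c(1, 0.1, 0), -4 * pi / 180),
                  c(6, 10, -8), "MRI", "CT")
}

#' Generate a ground-truth phantom scene
#'
#' Deterministic per `(config, seed)`. Tumors are placed strictly inside the
#' liver near its surface, clips and the 6-DoF sensor on the liver surface
#' close to the (first) tumor, disc sensors on the posterior body surface,
#' ribs as posterior-lateral arc tubes.
#'
#' @param config a `scene_config`.
#' @param seed integer RNG seed.
#' @return object of class `phantom_scene` with geometry in the MRI frame,
#'   motion state (initially the reference placement), ground-truth
#'   transforms in `$gt`, and `tri_mesh` surfaces for liver and tumors.
#' @export
generate_scene <- function(config = scene_config(), seed = 1L) {
  validate_scene_config(config)
  set.seed(as.integer(seed))
  L <- config$liver_center
  A <- config$liver_semiaxes

  # Tumors: superficial (60-75% of the radial extent from the liver center),
  # mutually separated, strictly inside the liver.
  tumors <- list()
  if (config$tumor_count > 0) {
    margin <- 3
    avail <- A - config$tumor_radius - margin
    if (any(avail <= 0)) stop("config error: tumor does not fit inside the liver")
    tries <- 0
    while (length(tumors) < config$tumor_count && tries < 500) {
      tries <- tries + 1
      d <- stats::rnorm(3)
      d <- d / sqrt(sum(d^2))
      frac <- stats::runif(1, 0.60, 0.75)
      cand <- L + frac * avail * d
      ok <- all(vapply(tumors, function(tc)
        sqrt(sum((tc - cand)^2)) > 2.5 * config$tumor_radius, logical(1)))
      if (ok) tumors <- c(tumors, list(cand))
    }
    if (length(tumors) < config$tumor_count) {
      stop("config error: could not place the requested number of tumors")
    }
  }
  tumor_centers <- if (length(tumors)) do.call(rbind, tumors) else
    matrix(numeric(0), 0, 3)

  # Anchor direction on the liver surface: through the first tumor, or a
  # fixed anterior direction when the scene has no tumor.
  anchor_dir <- if (length(tumors)) tumors[[1]] - L else c(0.3, -1, 0.4)
  anchor_dir <- anchor_dir / sqrt(sum(anchor_dir^2))
  anchor <- ellipsoid_surface_point(L, A, anchor_dir)
  tang <- frame_from_z(ellipsoid_normal(L, A, anchor))  # columns x,y = tangents

  surface_near_anchor <- function(offset2d) {
    p <- anchor + tang[, 1] * offset2d[1] + tang[, 2] * offset2d[2]
    ellipsoid_surface_point(L, A, p - L)
  }

  # Liver 6-DoF sensor: on the surface at a small tangential offset from the
  # anchor so it never sits on top of a clip.
  sensor_pos <- surface_near_anchor(c(8, -6))
  sensor_R <- frame_from_z(ellipsoid_normal(L, A, sensor_pos))
  sensor_q <- matrix_to_quat(sensor_R)
  if (length(tumors)) {
    d_t <- sqrt(sum((sensor_pos - tumors[[1]])^2)) - config$tumor_radius
    if (d_t > config$sensor_tumor_max_distance) {
      stop("config error: liver sensor farther from the tumor surface than allowed")
    }
  }

  # Four clips around the anchor at the configured tangential spread.
  ang <- seq(0, 2 * pi, length.out = config$clip_count + 1)[-(config$clip_count + 1)]
  ang <- ang + pi / 7   # avoid axis-aligned symmetry
  clips <- t(vapply(ang, function(a)
    surface_near_anchor(config$clip_spread * c(cos(a), sin(a))), numeric(3)))

  # Patient trackers on the posterior body surface (LPS: posterior = +y),
  # each a pair of discs `pairing_distance` apart along a surface tangent.
  # low axial angles keep all discs outside the fully sampled 250-mm
  # cylinder of the standard CBCT FOV, as in the clinical Phase-II setup
  azim <- c(50, 90, 130) * pi / 180
  zlev <- c(5, 8, 5)
  discs <- matrix(0, 6, 3)
  disc_normals <- matrix(0, 6, 3)
  tracker_id <- rep(seq_len(3), each = 2)
  for (k in 1:3) {
    dirk <- c(cos(azim[k]), sin(azim[k]), zlev[k] / config$body_semiaxes[3])
    ck <- ellipsoid_surface_point(config$body_center, config$body_semiaxes, dirk)
    nk <- ellipsoid_normal(config$body_center, config$body_semiaxes, ck)
    tk <- cross3(c(0, 0, 1), nk)   # horizontal surface tangent
    tk <- tk / sqrt(sum(tk^2))
    for (s in 1:2) {
      off <- (s - 1.5) * config$pairing_distance
      p <- ck + off * tk
      p <- ellipsoid_surface_point(config$body_center, config$body_semiaxes,
                                   p - config$body_center)
      discs[2 * (k - 1) + s, ] <- p
      disc_normals[2 * (k - 1) + s, ] <-
        ellipsoid_normal(config$body_center, config$body_semiaxes, p)
    }
    # enforce the exact pairing distance along the chord
    i1 <- 2 * k - 1; i2 <- 2 * k
    mid <- (discs[i1, ] + discs[i2, ]) / 2
    u <- discs[i2, ] - discs[i1, ]
    u <- u / sqrt(sum(u^2))
    discs[i1, ] <- mid - u * config$pairing_distance / 2
    discs[i2, ] <- mid + u * config$pairing_distance / 2
  }

  # Ribs: posterior-lateral arcs in axial planes, just inside the body wall.
  ribs <- lapply(seq_len(config$rib_count), function(i) {
    z0 <- seq(-45, 80, length.out = config$rib_count)[i]
    rr <- 0.92 * sqrt(prod(config$body_semiaxes[1:2]))  # mean lateral radius
    list(center = c(config$body_center[1], config$body_center[2], z0),
         radius = rr * (1 - 0.15 * abs(z0) / 90),
         theta = c(25, 155) * pi / 180,   # atan2 angles, posterior span
         tube_radius = config$rib_tube_radius)
  })

  # Contrast vessels: capsule chains from the liver hilum toward the tumor
  # region ("vascular tree anatomy around the target lesion").
  vessels <- lapply(seq_len(config$vessel_count), function(i) {
    jitter <- stats::rnorm(3, 0, 8)
    mid <- L + 0.5 * (anchor - L) + jitter
    endd <- anchor - 0.25 * A * anchor_dir + stats::rnorm(3, 0, 6)
    list(points = rbind(L, mid, endd), radius = config$vessel_radius)
  })

  gt <- list(
    placement = if (is.null(config$placement)) default_placement() else config$placement,
    em_to_cbct = if (is.null(config$em_to_cbct)) default_em_to_cbct() else config$em_to_cbct,
    mri_to_ct = if (is.null(config$mri_to_ct)) default_mri_to_ct() else config$mri_to_ct)

  scene <- structure(list(
    config = config,
    liver = list(center = L, semiaxes = A),
    body = list(center = config$body_center, semiaxes = config$body_semiaxes),
    tumor_centers = tumor_centers,
    tumor_radius = config$tumor_radius,
    clips = clips,
    discs = discs,
    disc_normals = disc_normals,
    tracker_id = tracker_id,
    sensor = list(position = sensor_pos, q = sensor_q),
    ribs = ribs,
    vessels = vessels,
    liver_mesh = mesh_ellipsoid(L, A, subdivisions = 3),
    tumor_meshes = lapply(seq_len(nrow(tumor_centers)), function(i)
      mesh_ellipsoid(tumor_centers[i, ], rep(config$tumor_radius, 3),
                     subdivisions = 2)),
    gt = gt,
    motion = reference_motion(gt$placement),
    time = 0
  ), class = "phantom_scene")
  scene
}

#' @export
print.phantom_scene <- function(x, ...) {
  cat(sprintf("phantom_scene: %d tumor(s), %d clips, %d disc sensors, %d ribs (t = %.2f s)\n",
              nrow(x$tumor_centers), nrow(x$clips), nrow(x$discs),
              length(x$ribs), x$time))
  invisible(x)
}

# Motion state: per component (liver-attached vs body-attached) a forward map
# MRI reference -> EM, its inverse, and the rigid part (NULL when the motion
# is not rigid). The reference state is pure patient placement.
reference_motion <- function(placement) {
  fwd <- function(x) apply_transform(placement, x)
  inv <- function(x) apply_transform(invert_transform(placement), x)
  list(liver = list(fwd = fwd, inv = inv, rigid = placement, field = NULL),
       body = list(fwd = fwd, inv = inv, rigid = placement, field = NULL))
}

#' Deformation / breathing / manipulation model
#'
#' The liver-attached component moves by a global rigid trajectory, a
#' sinusoidal cranio-caudal breathing translation, and a smooth local
#' displacement field (sum of 3-D Gaussian kernels) that is analytically
#' attenuated to zero inside a rigid-core radius around the liver sensor —
#' the "locally rigid body" the tracking model assumes. Ribs and body move
#' with the global rigid trajectory only.
#'
#' @param global_trajectory function(time) returning a `rigid_transform`
#'   EM -> EM, or NULL for no global motion.
#' @param breathing_amplitude 3-vector, mm (default 10 mm cranio-caudal).
#' @param breathing_period seconds.
#' @param field_magnitude peak kernel displacement, mm (0 disables the field).
#' @param field_length_scale Gaussian kernel length-scale, mm.
#' @param rigid_core_radius radius around the sensor inside which the local
#'   field is attenuated to zero, mm.
#' @param kernel_centers K x 3 matrix of kernel centers (MRI frame); NULL
#'   draws `n_kernels` centers around the liver at generation time.
#' @param n_kernels number of kernels when `kernel_centers` is NULL.
#' @param seed RNG seed for kernel placement and amplitude directions.
#' @return object of class `deformation_model`.
#' @export
deformation_model <- function(global_trajectory = NULL,
                              breathing_amplitude = c(0, 0, 10),
                              breathing_period = 4,
                              field_magnitude = 0,
                              field_length_scale = 100,
                              rigid_core_radius = 30,
                              kernel_centers = NULL,
                              n_kernels = 4,
                              seed = 1L) {
  stopifnot(breathing_period > 0, field_length_scale > 0, rigid_core_radius >= 0)
  if (field_magnitude < 0) stop("field magnitude must be non-negative")
  structure(list(global_trajectory = global_trajectory,
                 breathing_amplitude = as.numeric(breathing_amplitude),
                 breathing_period = breathing_period,
                 field_magnitude = field_magnitude,
                 field_length_scale = field_length_scale,
                 rigid_core_radius = rigid_core_radius,
                 kernel_centers = kernel_centers,
                 n_kernels = n_kernels,
                 seed = as.integer(seed)),
            class = "deformation_model")
}

# Kernel centers / directions are fixed per (model, scene): drawn once,
# deterministically, around the liver but away from the sensor.
deformation_kernels <- function(model, scene) {
  if (!is.null(model$kernel_centers)) {
    centers <- as_points(model$kernel_centers)
  } else {
    set.seed(model$seed + 77L)
    L <- scene$liver$center; A <- scene$liver$semiaxes
    centers <- t(vapply(seq_len(model$n_kernels), function(i) {
      d <- stats::rnorm(3); d <- d / sqrt(sum(d^2))
      L + stats::runif(1, 0.5, 1.1) * A * d
    }, numeric(3)))
  }
  set.seed(model$seed + 78L)
  dirs <- matrix(stats::rnorm(nrow(centers) * 3), ncol = 3)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  list(centers = centers, dirs = dirs)
}

#' Evaluate the local displacement field of a deformation model
#'
#' Returns the displacement (mm) of liver-attached material points given in
#' the MRI reference frame, including the rigid-core attenuation around the
#' liver sensor. This is the ground truth every tracking error is measured
#' against.
#'
#' @param model a `deformation_model`.
#' @param scene the `phantom_scene` the field is attached to.
#' @param points N x 3 matrix, MRI frame.
#' @return N x 3 displacement matrix, mm.
#' @export
displacement_field <- function(model, scene, points) {
  pts <- as_points(points)
  if (model$field_magnitude == 0) return(matrix(0, nrow(pts), 3))
  k <- deformation_kernels(model, scene)
  u <- matrix(0, nrow(pts), 3)
  for (i in seq_len(nrow(k$centers))) {
    r2 <- rowSums(sweep(pts, 2, k$centers[i, ], "-")^2)
    w <- exp(-r2 / (2 * model$field_length_scale^2))
    u <- u + outer(w, model$field_magnitude * k$dirs[i, ])
  }
  # smoothstep attenuation: exactly 0 inside the rigid core, 1 beyond 2x core
  d <- sqrt(rowSums(sweep(pts, 2, scene$sensor$position, "-")^2))
  rc <- model$rigid_core_radius
  s <- if (rc > 0) pmin(pmax((d - rc) / rc, 0), 1) else rep(1, length(d))
  att <- s * s * (3 - 2 * s)
  u * att
}

breathing_translation <- function(model, time) {
  model$breathing_amplitude * sin(2 * pi * time / model$breathing_period)
}

global_at <- function(model, time) {
  if (is.null(model$global_trajectory)) return(identity_transform("EM"))
  G <- model$global_trajectory(time)
  stopifnot(is_rigid_transform(G))
  G
}

#' Move a phantom scene to a time point of a deformation model
#'
#' Liver-attached structures (liver, tumors, vessels, clips, sensor) move by
#' the local field, then placement, then breathing, then the global rigid
#' trajectory; body-attached structures (body, ribs, tracker discs) move by
#' placement and the global trajectory only. The scene keeps an invertible
#' map back to the reference state, so rendering and ground-truth queries
#' remain exact.
#'
#' @param scene a `phantom_scene` (reference state).
#' @param model a `deformation_model`.
#' @param time seconds.
#' @return the deformed `phantom_scene` (geometry fields still stored in the
#'   MRI frame; `$motion` carries the state, `$time` the time point).
#' @export
apply_deformation <- function(scene, model, time) {
  stopifnot(inherits(scene, "phantom_scene"), inherits(model, "deformation_model"))
  G <- global_at(model, time)
  b <- breathing_translation(model, time)
  P <- scene$gt$placement
  Pi <- invert_transform(P)
  Gi <- invert_transform(G)

  body_rigid <- compose_transform(G, P)
  liver_rigid <- compose_transform(
    G, compose_transform(rigid_transform(c(1, 0, 0, 0), b, "EM", "EM"), P))
  liver_rigid_i <- invert_transform(liver_rigid)

  has_field <- model$field_magnitude > 0
  liver_fwd <- function(x) {
    x <- as_points(x)
    if (has_field) x <- x + displacement_field(model, scene, x)
    apply_transform(liver_rigid, x)
  }
  liver_inv <- function(x) {
    y <- apply_transform(liver_rigid_i, as_points(x))
    if (!has_field) return(y)
    xr <- y
    for (it in 1:25) {   # contraction: |du/dx| << 1 for sane magnitudes
      xr_new <- y - displacement_field(model, scene, xr)
      if (max(abs(xr_new - xr)) < 1e-10) { xr <- xr_new; break }
      xr <- xr_new
    }
    xr
  }
  body_fwd <- function(x) apply_transform(body_rigid, as_points(x))
  body_inv <- function(x) apply_transform(invert_transform(body_rigid), as_points(x))

  out <- scene
  out$motion <- list(
    liver = list(fwd = liver_fwd, inv = liver_inv,
                 rigid = if (has_field) NULL else liver_rigid,
                 rigid_part = liver_rigid, field = if (has_field) model else NULL),
    body = list(fwd = body_fwd, inv = body_inv, rigid = body_rigid, field = NULL))
  out$time <- time
  out
}

#' Current (EM-frame) positions of scene landmarks
#'
#' @param scene a `phantom_scene`.
#' @param points N x 3 matrix in the MRI reference frame.
#' @param component `"liver"` for liver-attached points, `"body"` for
#'   rib/tracker-attached points.
#' @return N x 3 matrix in the EM frame at the scene's current time.
#' @export
scene_points_em <- function(scene, points, component = c("liver", "body")) {
  component <- match.arg(component)
  scene$motion[[component]]$fwd(as_points(points))
}

#' Current liver-sensor pose in the EM frame
#'
#' The sensor position follows the full liver motion (the local field is
#' attenuated to ~0 at the sensor by construction); its orientation follows
#' the rigid part of the motion, consistent with the locally rigid core.
#'
#' @param scene a `phantom_scene`.
#' @param timestamp seconds stamped onto the sample.
#' @return a 6-DoF `pose_sample` for tool `"liver_sensor"`.
#' @export
sensor_pose_em <- function(scene, timestamp = scene$time) {
  pos <- drop(scene$motion$liver$fwd(scene$sensor$position))
  rigid <- scene$motion$liver$rigid_part %||% scene$motion$liver$rigid
  q <- quat_multiply(rigid$q, scene$sensor$q)
  pose_sample(timestamp, "liver_sensor", pos, q / sqrt(sum(q^2)), 6L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Ground-truth tool poses of a scene trajectory
#'
#' Returns a function of time producing the noise-free poses of every EM
#' tool: the liver 6-DoF sensor, the six 5-DoF tracker discs
#' (`tracker_1a` ... `tracker_3b`) and the pointer (held on the first clip,
#' i.e. moving with the liver).
#'
#' @param scene reference `phantom_scene`.
#' @param model a `deformation_model`.
#' @return function(time) -> named list of `pose_sample`.
#' @export
scene_trajectory <- function(scene, model) {
  force(scene); force(model)
  function(time) {
    st <- apply_deformation(scene, model, time)
    out <- list()
    out$liver_sensor <- sensor_pose_em(st, time)
    disc_em <- scene_points_em(st, st$discs, "body")
    rigid_b <- st$motion$body$rigid
    for (i in seq_len(nrow(disc_em))) {
      id <- sprintf("tracker_%d%s", st$tracker_id[i], c("a", "b")[1 + (i - 1) %% 2])
      dir <- drop(quat_rotate(rigid_b$q, st$disc_normals[i, ]))
      out[[id]] <- pose_sample(time, id, disc_em[i, ], dir / sqrt(sum(dir^2)), 5L)
    }
    tip <- drop(scene_points_em(st, st$clips[1, , drop = FALSE], "liver"))
    rigid_l <- st$motion$liver$rigid_part %||% st$motion$liver$rigid
    out$pointer <- pose_sample(time, "pointer", tip, rigid_l$q, 6L)
    out
  }
}

#' EM measurement-noise model
#'
#' @param sigma_pos per-axis position noise SD, mm (default 0.5, a
#'   tabletop-generator-class figure).
#' @param sigma_rot orientation noise SD, degrees (default 0.3).
#' @param seed RNG seed; identical seeds give identical streams.
#' @return object of class `em_noise_model`.
#' @export
em_noise_model <- function(sigma_pos = 0.5, sigma_rot = 0.3, seed = 1L) {
  if (sigma_pos < 0 || sigma_rot < 0) stop("noise sigmas must be non-negative")
  structure(list(sigma_pos = sigma_pos, sigma_rot = sigma_rot,
                 seed = as.integer(seed)),
            class = "em_noise_model")
}

perturb_pose <- function(s, noise) {
  pos <- s$position + stats::rnorm(3, 0, noise$sigma_pos)
  if (noise$sigma_rot > 0) {
    axis <- stats::rnorm(3)
    ang <- stats::rnorm(1, 0, noise$sigma_rot * pi / 180)
    dq <- quat_from_axis_angle(axis, ang)
    if (s$dof == 6L) {
      q <- quat_multiply(dq, s$orientation)
      ori <- q / sqrt(sum(q^2))
    } else {
      ori <- drop(quat_rotate(dq, s$orientation))
      ori <- ori / sqrt(sum(ori^2))
    }
  } else {
    ori <- s$orientation
  }
  pose_sample(s$timestamp, s$tool_id, pos, ori, s$dof)
}

#' Simulate a noisy EM pose stream
#'
#' Samples the ground-truth trajectory at the tracker frame rate (clinically
#' 10 Hz) and adds EM measurement noise. With zero sigmas the stream
#' reproduces the ground-truth poses exactly.
#'
#' @param trajectory function(time) -> named list of `pose_sample`
#'   (see [scene_trajectory()]).
#' @param noise an `em_noise_model`.
#' @param rate frames per second (> 0).
#' @param duration seconds; `rate * duration` samples per tool.
#' @param t0 time of the first sample, seconds.
#' @param tools tool ids to include; NULL keeps all.
#' @return list of `pose_sample`, frame-major (all tools at t1, then t2, ...).
#' @export
simulate_em_stream <- function(trajectory, noise = em_noise_model(),
                               rate = 10, duration = 1, t0 = 0, tools = NULL) {
  stopifnot(rate > 0, duration >= 0)
  n <- floor(rate * duration + 1e-9)
  times <- t0 + (seq_len(n) - 1) / rate
  set.seed(noise$seed)
  out <- vector("list", 0)
  for (tt in times) {
    poses <- trajectory(tt)
    if (!is.null(tools)) poses <- poses[intersect(names(poses), tools)]
    out <- c(out, lapply(poses, perturb_pose, noise = noise))
  }
  names(out) <- NULL
  out
}

#' Scene landmark table (reference frame)
#'
#' @param scene a `phantom_scene`.
#' @return data.frame with label, component and x/y/z (mm, MRI frame) of
#'   tumor centers, clips, disc centers and the liver sensor.
#' @export
scene_landmarks <- function(scene) {
  lab <- c(if (nrow(scene$tumor_centers)) paste0("tumor_", seq_len(nrow(scene$tumor_centers))),
           paste0("clip_", seq_len(nrow(scene$clips))),
           paste0("disc_", seq_len(nrow(scene$discs))),
           "liver_sensor")
  pts <- rbind(scene$tumor_centers, scene$clips, scene$discs,
               matrix(scene$sensor$position, 1))
  comp <- c(rep("liver", nrow(scene$tumor_centers) + nrow(scene$clips)),
            rep("body", nrow(scene$discs)), "liver")
  data.frame(label = lab, component = comp,
             x = pts[, 1], y = pts[, 2], z = pts[, 3])
}
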