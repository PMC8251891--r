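# Voxel rendering of phantom scenes. Intensities approximate Hounsfield
# units by tissue class only (no CT-physics claim): air -1000, soft tissue
# 50, liver 100, tumor 160, contrast vessels 300, bone 700-1500 (ramped from
# core to cortex), metal 3000. Metal (clips, disc sensors) is rendered with a
# signed-distance coverage fraction, which emulates partial volume and keeps
# intensity-weighted centroids sub-voxel accurate. Large grids are processed
# in voxel chunks to bound memory.

intensity_map <- function(modality) {
  switch(modality,
         ct = ,
         cbct = list(air = -1000, soft = 50, liver = 100, tumor = 160,
                     vessel = 300, bone_lo = 700, bone_hi = 1500, metal = 3000),
         mri = list(air = 5, soft = 60, liver = 110, tumor = 170,
                    vessel = 250, bone_lo = 25, bone_hi = 35, metal = 40),
         stop("unknown modality: ", modality))
}

#' CBCT field-of-view presets
#'
#' `"cbct_standard"` is the clinical reconstruction (cylinder diameter
#' 250 mm, length 200 mm); `"cbct_truncated"` is the extended
#' truncated-projection reconstruction (350 x 350 x 200 mm box whose region
#' outside the fully sampled 250-mm cylinder is under-sampled but still
#' usable for high-contrast tracker localization).
#'
#' @param name preset name.
#' @param center box center in the image frame, mm.
#' @return fov list with `center`, `size`, `cylinder_diameter`,
#'   `cylinder_length`, `truncated`.
#' @export
fov_preset <- function(name = c("cbct_standard", "cbct_truncated"),
                       center = c(0, 0, 0)) {
  name <- match.arg(name)
  if (name == "cbct_standard") {
    list(center = center, size = c(250, 250, 200),
         cylinder_diameter = 250, cylinder_length = 200, truncated = FALSE)
  } else {
    list(center = center, size = c(350, 350, 200),
         cylinder_diameter = 250, cylinder_length = 200, truncated = TRUE)
  }
}

#' Axis-aligned field of view
#'
#' @param center box center, mm (image frame).
#' @param size box edge lengths, mm.
#' @return fov list (no cylinder masking).
#' @export
fov_box <- function(center, size) {
  list(center = as.numeric(center), size = as.numeric(size),
       cylinder_diameter = NULL, cylinder_length = NULL, truncated = FALSE)
}

# Distance from points to a rib arc centerline (circular arc in an axial
# plane).
rib_arc_distance <- function(pts, rib) {
  dx <- pts[, 1] - rib$center[1]
  dy <- pts[, 2] - rib$center[2]
  th <- atan2(dy, dx)
  th <- pmin(pmax(th, rib$theta[1]), rib$theta[2])
  ax <- rib$center[1] + rib$radius * cos(th)
  ay <- rib$center[2] + rib$radius * sin(th)
  sqrt((pts[, 1] - ax)^2 + (pts[, 2] - ay)^2 + (pts[, 3] - rib$center[3])^2)
}

point_segment_distance <- function(pts, a, b) {
  ab <- b - a
  len2 <- sum(ab^2)
  ap <- sweep(pts, 2, a, "-")
  t <- if (len2 > 0) pmin(pmax((ap %*% ab) / len2, 0), 1) else rep(0, nrow(pts))
  foot <- outer(drop(t), ab) + matrix(a, nrow(pts), 3, byrow = TRUE)
  sqrt(rowSums((pts - foot)^2))
}

in_ellipsoid <- function(pts, center, semiaxes) {
  rowSums(sweep(sweep(pts, 2, center, "-"), 2, semiaxes, "/")^2) <= 1
}

# Signed distance to a finite disc (cylinder): negative inside.
disc_sdf <- function(pts, center, normal, radius, half_thickness) {
  rel <- sweep(pts, 2, center, "-")
  ax <- drop(rel %*% normal)
  rad <- sqrt(pmax(rowSums(rel^2) - ax^2, 0))
  pmax(abs(ax) - half_thickness, rad - radius)
}

# Tissue classification of one chunk of image-frame voxel centers.
classify_chunk <- function(scene, pts_img, ref_of_img, imap, vox) {
  pts_body <- ref_of_img(pts_img, "body")
  pts_liver <- ref_of_img(pts_img, "liver")
  v <- rep(imap$air, nrow(pts_img))
  v[in_ellipsoid(pts_body, scene$body$center, scene$body$semiaxes)] <- imap$soft
  v[in_ellipsoid(pts_liver, scene$liver$center, scene$liver$semiaxes)] <- imap$liver
  for (i in seq_len(nrow(scene$tumor_centers))) {
    inside <- rowSums(sweep(pts_liver, 2, scene$tumor_centers[i, ], "-")^2) <=
      scene$tumor_radius^2
    v[inside] <- imap$tumor
  }
  for (ves in scene$vessels) {
    for (s in seq_len(nrow(ves$points) - 1)) {
      dd <- point_segment_distance(pts_liver, ves$points[s, ], ves$points[s + 1, ])
      v[dd <= ves$radius] <- imap$vessel
    }
  }
  for (rib in scene$ribs) {
    dd <- rib_arc_distance(pts_body, rib)
    inside <- dd <= rib$tube_radius
    if (any(inside)) {
      v[inside] <- imap$bone_lo +
        (imap$bone_hi - imap$bone_lo) * dd[inside] / rib$tube_radius
    }
  }
  add_metal <- function(v, sdf) {
    cov <- pmin(pmax(0.5 - sdf / vox, 0), 1)
    hit <- cov > 0
    v[hit] <- v[hit] * (1 - cov[hit]) + imap$metal * cov[hit]
    v
  }
  cfg <- scene$config
  for (i in seq_len(nrow(scene$clips))) {
    v <- add_metal(v, sqrt(rowSums(sweep(pts_liver, 2, scene$clips[i, ], "-")^2)) -
                     cfg$clip_radius)
  }
  for (i in seq_len(nrow(scene$discs))) {
    v <- add_metal(v, disc_sdf(pts_body, scene$discs[i, ], scene$disc_normals[i, ],
                               cfg$disc_radius, cfg$disc_thickness / 2))
  }
  v
}

#' Render a phantom scene as a CT/CBCT/MRI-like volume
#'
#' Voxel intensities are assigned by tissue class with additive Gaussian
#' noise. For `modality = "cbct"` with a cylindrical FOV (see
#' [fov_preset()]), voxels outside the fully sampled cylinder are set to air
#' in the standard reconstruction, or degraded (extra noise and a constant
#' intensity bias) in the truncated-projection reconstruction. A warning is
#' raised when the FOV excludes tracker discs or clips, which obstructs the
#' downstream registrations.
#'
#' @param scene a `phantom_scene` (any motion state; the render evaluates
#'   the scene's current geometry through the inverse motion maps).
#' @param spacing voxel spacing, mm (scalar or 3-vector).
#' @param fov an [fov_box()] / [fov_preset()] list, or a preset name; the
#'   default box covers the whole body in the image frame.
#' @param modality `"ct"`, `"cbct"` or `"mri"`.
#' @param noise_sigma additive Gaussian noise SD (intensity units).
#' @param trunc_noise_factor,trunc_bias degradation applied outside the
#'   fully sampled cylinder of a truncated reconstruction.
#' @param seed RNG seed for the noise.
#' @param chunk_voxels voxels classified per chunk (memory bound).
#' @return a `volume_image` in the modality's image frame
#'   (`"CT"`, `"CBCT"` or `"MRI"`).
#' @export
render_volume <- function(scene, spacing, fov = NULL,
                          modality = c("ct", "cbct", "mri"),
                          noise_sigma = 10, trunc_noise_factor = 5,
                          trunc_bias = 30, seed = 1L,
                          chunk_voxels = 1500000) {
  modality <- match.arg(modality)
  stopifnot(inherits(scene, "phantom_scene"))
  spacing <- rep(as.numeric(spacing), length.out = 3)
  if (any(spacing <= 0)) stop("spacing must be positive")
  imap <- intensity_map(modality)
  frame <- switch(modality, ct = "CT", cbct = "CBCT", mri = "MRI")

  ref_of_img <- switch(frame,
    MRI = function(x, comp) x,
    CT = {
      Di <- invert_transform(scene$gt$mri_to_ct)
      function(x, comp) apply_transform(Di, x)
    },
    CBCT = {
      to_em <- invert_transform(scene$gt$em_to_cbct)
      function(x, comp) scene$motion[[comp]]$inv(apply_transform(to_em, x))
    })

  if (is.character(fov)) fov <- fov_preset(fov, center = default_fov_center(scene, frame))
  if (is.null(fov)) {
    fov <- fov_box(default_fov_center(scene, frame), 2 * scene$body$semiaxes + 30)
  }

  dims <- pmax(2L, as.integer(round(fov$size / spacing)))
  origin <- fov$center - (dims - 1) / 2 * spacing
  vol <- volume_image(array(0, dim = dims), spacing, origin, diag(3), frame)
  ntot <- prod(dims)
  vox <- mean(spacing)
  v <- numeric(ntot)

  set.seed(as.integer(seed))
  starts <- seq(1, ntot, by = chunk_voxels)
  for (s0 in starts) {
    s1 <- min(s0 + chunk_voxels - 1, ntot)
    lin <- (s0:s1) - 1
    idx <- cbind(lin %% dims[1],
                 (lin %/% dims[1]) %% dims[2],
                 lin %/% (dims[1] * dims[2]))
    pts_img <- index_to_world(vol, idx)
    vi <- classify_chunk(scene, pts_img, ref_of_img, imap, vox)
    if (noise_sigma > 0) vi <- vi + stats::rnorm(length(vi), 0, noise_sigma)
    if (modality == "cbct" && !is.null(fov$cylinder_diameter)) {
      ccen <- fov$cylinder_center %||% fov$center
      rel <- sweep(pts_img, 2, ccen, "-")
      in_cyl <- sqrt(rel[, 1]^2 + rel[, 2]^2) <= fov$cylinder_diameter / 2 &
        abs(rel[, 3]) <= fov$cylinder_length / 2
      if (fov$truncated) {
        nout <- sum(!in_cyl)
        if (nout > 0) {
          vi[!in_cyl] <- vi[!in_cyl] + trunc_bias +
            stats::rnorm(nout, 0, noise_sigma * (trunc_noise_factor - 1))
        }
      } else {
        vi[!in_cyl] <- imap$air
      }
    }
    v[s0:s1] <- vi
  }

  # FOV completeness check against the scene's metal landmarks
  disc_img <- landmark_in_image(scene, scene$discs, "body", frame)
  clip_img <- landmark_in_image(scene, scene$clips, "liver", frame)
  lo <- origin - spacing / 2
  hi <- origin + (dims - 0.5) * spacing
  out_of_fov <- function(p) any(p < lo | p > hi)
  n_disc_out <- sum(apply(disc_img, 1, out_of_fov))
  n_clip_out <- sum(apply(clip_img, 1, out_of_fov))
  if (n_disc_out > 0 || n_clip_out > 0) {
    warning(sprintf("imaging FOV excludes %d tracker disc(s) and %d clip(s)",
                    n_disc_out, n_clip_out))
  }

  vol$voxels <- array(v, dim = dims)
  vol
}

default_fov_center <- function(scene, frame) {
  p <- matrix(scene$body$center, 1)
  drop(landmark_in_image(scene, p, "body", frame))
}

#' Map reference-frame landmarks into an image frame
#'
#' Applies the scene's current motion state and the scanner pose, giving
#' the ground-truth position of a landmark in a rendered volume.
#'
#' @param scene a `phantom_scene`.
#' @param pts_ref N x 3 matrix, MRI reference frame.
#' @param component `"liver"` or `"body"` (which motion the landmark rides).
#' @param frame `"MRI"`, `"CT"`, `"CBCT"` or `"EM"`.
#' @return N x 3 matrix in the requested frame.
#' @export
landmark_in_image <- function(scene, pts_ref, component, frame) {
  pts_ref <- as_points(pts_ref)
  switch(frame,
    MRI = pts_ref,
    CT = apply_transform(scene$gt$mri_to_ct, pts_ref),
    CBCT = apply_transform(scene$gt$em_to_cbct,
                           scene$motion[[component]]$fwd(pts_ref)),
    EM = scene$motion[[component]]$fwd(pts_ref),
    stop("unknown frame: ", frame))
}
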