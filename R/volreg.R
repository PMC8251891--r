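# Rigid volume-to-volume registration. The CT -> CBCT bone-to-bone step is:
# rough bone masking by intensity window, center-of-mass initialization, and
# mutual-information maximization restricted to the masked voxels. The
# MRI -> CBCT step is the same engine restricted to a box ROI around the
# target lesion, with a manual pass-through mode mirroring the clinical
# manual alignment.

#' Registration parameters
#'
#' @param bone_lo,bone_hi default bone intensity window for CT-like volumes.
#' @param bins joint-histogram bins per axis (>= 8).
#' @param levels multi-resolution levels (sample strides `2^(levels-1) ... 1`).
#' @param max_iter maximum optimizer iterations per level.
#' @param tol convergence tolerance on the metric.
#' @param sample_cap maximum number of fixed sample points per level.
#' @param mask_dilate dilations (voxels) applied to the fixed mask before
#'   sampling, so the samples include the bone/soft-tissue boundary that
#'   makes the histogram informative.
#' @param step_trans,step_rot initial optimizer steps (mm, degrees) at the
#'   finest level; coarser levels scale them up by the stride.
#' @param min_step_trans,min_step_rot optimizer stopping steps (mm, degrees).
#' @param init_rot_span,init_rot_step rotation-grid initialization sweep at
#'   the coarsest level (degrees; span 0 disables it).
#' @return list of class `registration_params`.
#' @export
registration_params <- function(bone_lo = 600, bone_hi = 1600, bins = 32,
                                levels = 3, max_iter = 200, tol = 1e-4,
                                sample_cap = 60000, mask_dilate = 2,
                                step_trans = 1, step_rot = 1,
                                min_step_trans = 0.02, min_step_rot = 0.02,
                                init_rot_span = 10, init_rot_step = 5) {
  if (bone_lo >= bone_hi) stop("bone window requires lo < hi")
  if (bins < 8) stop("at least 8 histogram bins are required")
  if (levels < 1) stop("at least 1 resolution level is required")
  structure(list(bone_lo = bone_lo, bone_hi = bone_hi, bins = bins,
                 levels = levels, max_iter = max_iter, tol = tol,
                 sample_cap = sample_cap, mask_dilate = mask_dilate,
                 step_trans = step_trans, step_rot = step_rot,
                 min_step_trans = min_step_trans, min_step_rot = min_step_rot,
                 init_rot_span = init_rot_span, init_rot_step = init_rot_step),
            class = "registration_params")
}

#' Bone mask by intensity window
#'
#' Thresholds to `[lo, hi]` and applies a one-voxel morphological opening to
#' drop speckle.
#'
#' @param vol a `volume_image`.
#' @param lo,hi intensity window (lo < hi).
#' @return a `volume_image` with logical voxels on the same grid.
#' @export
bone_mask <- function(vol, lo = 600, hi = 1600) {
  if (lo >= hi) stop("bone window requires lo < hi")
  m <- vol$voxels >= lo & vol$voxels <= hi
  m <- binary_open(m)
  if (!any(m)) stop("empty-mask error: no voxels in the bone intensity window")
  volume_image(m, vol$spacing, vol$origin, vol$direction, vol$frame)
}

mask_world_com <- function(mask_vol) {
  idx <- which(mask_vol$voxels, arr.ind = TRUE) - 1
  if (nrow(idx) == 0) stop("empty-mask error: mask has no voxels")
  colMeans(index_to_world(mask_vol, idx))
}

#' Center-of-mass initialization
#'
#' Pure translation mapping the moving mask's center of mass onto the fixed
#' mask's (world coordinates), zero rotation.
#'
#' @param fixed_mask,moving_mask binary `volume_image`s.
#' @return a `rigid_transform` moving frame -> fixed frame.
#' @export
com_align <- function(fixed_mask, moving_mask) {
  cf <- mask_world_com(fixed_mask)
  cm <- mask_world_com(moving_mask)
  rigid_transform(c(1, 0, 0, 0), cf - cm, moving_mask$frame, fixed_mask$frame)
}

euler_to_matrix <- function(deg) {
  r <- deg * pi / 180
  cx <- cos(r[1]); sx <- sin(r[1])
  cy <- cos(r[2]); sy <- sin(r[2])
  cz <- cos(r[3]); sz <- sin(r[3])
  Rx <- matrix(c(1, 0, 0, 0, cx, -sx, 0, sx, cx), 3, byrow = TRUE)
  Ry <- matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3, byrow = TRUE)
  Rz <- matrix(c(cz, -sz, 0, sz, cz, 0, 0, 0, 1), 3, byrow = TRUE)
  Rz %*% Ry %*% Rx
}

# Mutual information of paired bin indices (natural log).
mi_from_bins <- function(fb, mb, bins) {
  n <- length(fb)
  if (n == 0) return(-Inf)
  joint <- tabulate(fb + bins * (mb - 1L), nbins = bins * bins)
  p <- joint[joint > 0] / n
  pf <- tabulate(fb, nbins = bins) / n
  pm <- tabulate(mb, nbins = bins) / n
  hj <- -sum(p * log(p))
  hf <- -sum(pf[pf > 0] * log(pf[pf > 0]))
  hm <- -sum(pm[pm > 0] * log(pm[pm > 0]))
  hf + hm - hj
}

bin_index <- function(v, lo, hi, bins) {
  b <- floor((v - lo) / (hi - lo) * bins) + 1L
  pmin.int(pmax.int(b, 1L), bins)
}

#' Rigid registration by mutual-information maximization
#'
#' Maximizes the joint-histogram mutual information between the fixed and
#' moving volumes over rigid transforms, sampling the fixed volume at masked
#' voxels only (trilinear interpolation into the moving volume), with a
#' deterministic multi-resolution pattern search. No random sampling is
#' used: identical inputs give bit-identical results.
#'
#' @param fixed,moving `volume_image`s.
#' @param init `rigid_transform` moving frame -> fixed frame (e.g. from
#'   [com_align()]).
#' @param fixed_mask optional binary `volume_image` on the fixed grid
#'   restricting the metric; NULL uses all voxels.
#' @param moving_mask optional binary `volume_image`; samples mapping
#'   outside it are dropped from the histogram.
#' @param params a [registration_params()].
#' @return list with `transform` (moving -> fixed), `metric` (final MI,
#'   nats), `converged`, and `iterations` per level.
#' @export
register_mi <- function(fixed, moving, init, fixed_mask = NULL,
                        moving_mask = NULL, params = registration_params()) {
  stopifnot(inherits(fixed, "volume_image"), inherits(moving, "volume_image"),
            is_rigid_transform(init))
  if (!identical(init$frame_from, moving$frame) ||
      !identical(init$frame_to, fixed$frame)) {
    stop(sprintf("frame mismatch: init maps '%s'->'%s' but volumes are '%s'->'%s'",
                 init$frame_from, init$frame_to, moving$frame, fixed$frame))
  }
  bins <- params$bins

  if (is.null(fixed_mask)) {
    msk <- array(TRUE, dim(fixed$voxels))
  } else {
    msk <- fixed_mask$voxels
    for (i in seq_len(params$mask_dilate)) msk <- binary_dilate1(msk)
  }
  idx <- which(msk, arr.ind = TRUE) - 1
  if (nrow(idx) == 0) stop("empty-mask error: fixed mask has no voxels")
  pts_all <- index_to_world(fixed, idx)
  fvals_all <- fixed$voxels[msk]
  frange <- range(fvals_all)
  if (diff(frange) <= 0) frange <- frange + c(-1, 1)
  mrange <- range(moving$voxels)
  if (diff(mrange) <= 0) mrange <- mrange + c(-1, 1)

  ctr <- colMeans(pts_all)
  Mi <- transform_matrix(invert_transform(init))  # fixed -> moving, 4x4
  dmov <- dim(moving$voxels)
  mbin_vol <- array(bin_index(moving$voxels, mrange[1], mrange[2], bins),
                    dim = dmov)

  # p = (rot deg x3, trans mm x3); delta acts in fixed space about ctr
  moving_coords <- function(pts, p) {
    R <- euler_to_matrix(p[1:3])
    y <- sweep(sweep(pts, 2, ctr, "-") %*% t(R), 2, ctr + p[4:6], "+")
    sweep(y %*% t(Mi[1:3, 1:3]), 2, Mi[1:3, 4], "+")
  }

  # Partial-volume joint histogram (weights spread over the 8 moving-grid
  # neighbours): smooth in the transform parameters, which avoids the
  # spurious local optima a plain interpolate-then-bin estimate produces.
  metric_for <- function(pts, fb, p) {
    mc <- moving_coords(pts, p)
    idxm <- world_to_index(moving, mc)
    ok <- idxm[, 1] >= 0 & idxm[, 1] <= dmov[1] - 1 &
          idxm[, 2] >= 0 & idxm[, 2] <= dmov[2] - 1 &
          idxm[, 3] >= 0 & idxm[, 3] <= dmov[3] - 1
    if (!is.null(moving_mask)) {
      mm <- interp_volume(moving_mask, mc, outside = 0)
      ok <- ok & mm >= 0.5
    }
    if (!any(ok)) return(-Inf)
    idxm <- idxm[ok, , drop = FALSE]
    fbo <- fb[ok]
    i0 <- floor(idxm)
    fx <- idxm - i0
    joint <- numeric(bins * bins)
    for (cx in 0:1) for (cy in 0:1) for (cz in 0:1) {
      ii <- pmin(i0[, 1] + cx, dmov[1] - 1)
      jj <- pmin(i0[, 2] + cy, dmov[2] - 1)
      kk <- pmin(i0[, 3] + cz, dmov[3] - 1)
      w <- (if (cx == 1) fx[, 1] else 1 - fx[, 1]) *
           (if (cy == 1) fx[, 2] else 1 - fx[, 2]) *
           (if (cz == 1) fx[, 3] else 1 - fx[, 3])
      mb <- mbin_vol[cbind(ii + 1, jj + 1, kk + 1)]
      acc <- rowsum(w, fbo + bins * (mb - 1L))
      ks <- as.integer(rownames(acc))
      joint[ks] <- joint[ks] + acc[, 1]
    }
    pj <- joint / sum(joint)
    hj <- -sum(pj[pj > 0] * log(pj[pj > 0]))
    pm2 <- matrix(pj, bins, bins)
    pf <- rowSums(pm2)
    pm <- colSums(pm2)
    (-sum(pf[pf > 0] * log(pf[pf > 0]))) +
      (-sum(pm[pm > 0] * log(pm[pm > 0]))) - hj
  }

  p <- rep(0, 6)
  iterations <- integer(0)
  converged <- TRUE
  for (lev in seq(params$levels, 1)) {
    stride <- 2^(lev - 1)
    sel <- seq(1, nrow(pts_all), by = stride)
    if (length(sel) > params$sample_cap) {
      sel <- sel[seq(1, length(sel), length.out = params$sample_cap)]
    }
    pts <- pts_all[sel, , drop = FALSE]
    fb <- bin_index(fvals_all[sel], frange[1], frange[2], bins)

    if (lev == params$levels) {
      # overlap check at the initialization
      mv0 <- interp_volume(moving, moving_coords(pts, p))
      if (!any(!is.na(mv0))) {
        stop("initialization error: no mask overlap between fixed and moving volumes under init")
      }
      # deterministic rotation-grid sweep: a COM init leaves the full
      # rotation to recover, and repetitive structures (rib arcs) create
      # rotational local optima the local search alone can fall into
      if (params$init_rot_span > 0) {
        grid1 <- seq(-params$init_rot_span, params$init_rot_span,
                     by = params$init_rot_step)
        best_p <- p
        best_v <- metric_for(pts, fb, p)
        for (rx in grid1) for (ry in grid1) for (rz in grid1) {
          cand <- c(rx, ry, rz, p[4:6])
          val <- metric_for(pts, fb, cand)
          if (val > best_v) {
            best_v <- val
            best_p <- cand
          }
        }
        p <- best_p
      }
    }

    # Hooke-Jeeves pattern search: exploratory coordinate sweep plus a
    # pattern (extrapolation) move, which follows rotation/translation
    # ridges a pure coordinate search stalls on.
    step <- c(rep(params$step_rot * stride, 3), rep(params$step_trans * stride, 3))
    min_step <- c(rep(params$min_step_rot, 3), rep(params$min_step_trans, 3))
    eps <- params$tol * 1e-3
    cur <- metric_for(pts, fb, p)
    base <- p
    it <- 0
    while (it < params$max_iter) {
      it <- it + 1
      pe <- p
      ve <- cur
      for (j in 1:6) {
        for (s in c(1, -1)) {
          cand <- pe
          cand[j] <- cand[j] + s * step[j]
          val <- metric_for(pts, fb, cand)
          if (val > ve + eps) {
            ve <- val
            pe <- cand
            break
          }
        }
      }
      if (ve > cur + eps) {
        pp <- pe + (pe - base)
        vp <- metric_for(pts, fb, pp)
        base <- p
        if (vp > ve + eps) {
          p <- pp
          cur <- vp
        } else {
          p <- pe
          cur <- ve
        }
      } else {
        if (all(step <= min_step)) break
        step <- pmax(step / 2, min_step * 0.999)
        base <- p
      }
    }
    iterations <- c(iterations, it)
    if (it >= params$max_iter) converged <- FALSE
  }

  # final transform: x_m = Mi (Delta x_f) => T_fixed->moving, invert it
  R <- euler_to_matrix(p[1:3])
  delta <- diag(4)
  delta[1:3, 1:3] <- R
  delta[1:3, 4] <- ctr + p[4:6] - drop(R %*% ctr)
  m_fm <- Mi %*% delta
  T <- invert_transform(transform_from_matrix(m_fm, fixed$frame, moving$frame))
  list(transform = T, metric = cur, converged = converged,
       iterations = iterations)
}

#' ROI-restricted rigid registration (with manual pass-through)
#'
#' Restricts [register_mi()] to an axis-aligned box in the fixed volume's
#' world coordinates — the automated surrogate for the clinical manual
#' MRI-to-CBCT alignment around the target lesion. In manual mode a
#' user-supplied transform is validated and returned verbatim with frames
#' relabeled.
#'
#' @param fixed,moving `volume_image`s.
#' @param roi list with `lo` and `hi` 3-vectors (mm, fixed world frame).
#' @param init `rigid_transform` moving -> fixed.
#' @param manual optional `rigid_transform`: returned unchanged (manual
#'   mode).
#' @param params a [registration_params()].
#' @return as [register_mi()]; in manual mode a list with `transform` only.
#' @export
register_roi <- function(fixed, moving, roi, init, manual = NULL,
                         params = registration_params()) {
  if (!is.null(manual)) {
    stopifnot(is_rigid_transform(manual))
    T <- rigid_transform(manual$q, manual$t, moving$frame, fixed$frame)
    return(list(transform = T, metric = NA_real_, converged = TRUE,
                iterations = integer(0), manual = TRUE))
  }
  stopifnot(is.list(roi), !is.null(roi$lo), !is.null(roi$hi))
  pts <- voxel_world_coords(fixed)
  inside <- pts[, 1] >= roi$lo[1] & pts[, 1] <= roi$hi[1] &
            pts[, 2] >= roi$lo[2] & pts[, 2] <= roi$hi[2] &
            pts[, 3] >= roi$lo[3] & pts[, 3] <= roi$hi[3]
  if (!any(inside)) stop("roi error: ROI does not intersect the fixed volume")
  mask <- volume_image(array(inside, dim(fixed$voxels)), fixed$spacing,
                       fixed$origin, fixed$direction, fixed$frame)
  p2 <- params
  p2$mask_dilate <- 0   # the ROI box is already the sampling region
  register_mi(fixed, moving, init, fixed_mask = mask, params = p2)
}
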