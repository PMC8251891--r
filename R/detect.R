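# Metal fiducial detection in CT/CBCT-like volumes: surgical clips and the
# six disc-shaped patient-tracker sensor centers, plus the
# full-vs-truncated-FOV localization consistency statistic used as the
# geometric-distortion QC of the extended reconstruction.

# 26-connected component labelling of a set of voxels (0-based index rows).
# Union-find over neighbor pairs found by hashing linear indices; intended
# for the sparse supra-threshold sets metal detection produces.
label_components_26 <- function(idx, dims) {
  n <- nrow(idx)
  if (n == 0) return(integer(0))
  lin <- idx[, 1] + dims[1] * (idx[, 2] + dims[2] * idx[, 3])
  ord <- order(lin)
  lin_sorted <- lin[ord]
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  offsets <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  offsets <- offsets[!(offsets$dx == 0 & offsets$dy == 0 & offsets$dz == 0), ]
  for (k in seq_len(nrow(offsets))) {
    dx <- offsets$dx[k]; dy <- offsets$dy[k]; dz <- offsets$dz[k]
    ni <- idx[, 1] + dx; nj <- idx[, 2] + dy; nk <- idx[, 3] + dz
    valid <- ni >= 0 & ni < dims[1] & nj >= 0 & nj < dims[2] &
             nk >= 0 & nk < dims[3]
    nlin <- ni + dims[1] * (nj + dims[2] * nk)
    pos <- findInterval(nlin, lin_sorted)
    hit <- valid & pos > 0 & lin_sorted[pmax(pos, 1)] == nlin
    a <- which(hit)
    b <- ord[pos[hit]]
    for (m in seq_along(a)) {
      ra <- find(a[m]); rb <- find(b[m])
      if (ra != rb) parent[ra] <- rb
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

#' Detect metal blobs in a volume
#'
#' 26-connected components of supra-threshold voxels, size-filtered to
#' `[min_vol, max_vol]` mm^3. Centers are intensity-weighted centroids in
#' world coordinates (sub-voxel); components merged beyond `max_vol` are
#' dropped and reported via a message.
#'
#' @param vol a `volume_image`.
#' @param threshold intensity threshold (default 2000, between the bone
#'   ceiling of 1500 and the metal class at 3000).
#' @param min_vol,max_vol component volume filter, mm^3.
#' @return data.frame of class `blob_detections`: `x, y, z` (mm, world),
#'   `volume_mm3`, `peak`, `axis1, axis2, axis3` (principal axis lengths,
#'   mm, descending), sorted by descending peak intensity.
#' @export
detect_metal_blobs <- function(vol, threshold = 2000, min_vol = 1,
                               max_vol = 1000) {
  stopifnot(inherits(vol, "volume_image"))
  dims <- dim(vol$voxels)
  sel <- which(vol$voxels > threshold)
  empty <- data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
                      volume_mm3 = numeric(0), peak = numeric(0),
                      axis1 = numeric(0), axis2 = numeric(0), axis3 = numeric(0))
  class(empty) <- c("blob_detections", "data.frame")
  if (length(sel) == 0) return(empty)
  idx <- cbind((sel - 1) %% dims[1],
               ((sel - 1) %/% dims[1]) %% dims[2],
               (sel - 1) %/% (dims[1] * dims[2]))
  labels <- label_components_26(idx, dims)
  vals <- vol$voxels[sel]
  voxel_vol <- prod(vol$spacing)
  world <- index_to_world(vol, idx)
  out <- list()
  dropped <- 0
  for (lab in seq_len(max(labels))) {
    m <- labels == lab
    vol_mm3 <- sum(m) * voxel_vol
    if (vol_mm3 > max_vol) { dropped <- dropped + 1; next }
    if (vol_mm3 < min_vol) next
    w <- vals[m] - min(0, min(vals[m]))   # intensity weights (positive)
    pts <- world[m, , drop = FALSE]
    ctr <- colSums(pts * w) / sum(w)
    centered <- sweep(pts, 2, ctr, "-")
    if (nrow(pts) >= 3) {
      ev <- eigen(crossprod(centered) / nrow(pts), symmetric = TRUE)$values
      axes <- 2 * sqrt(pmax(ev, 0))
    } else {
      axes <- c(0, 0, 0)
    }
    out[[length(out) + 1]] <- data.frame(
      x = ctr[1], y = ctr[2], z = ctr[3], volume_mm3 = vol_mm3,
      peak = max(vals[m]), axis1 = axes[1], axis2 = axes[2], axis3 = axes[3])
  }
  if (dropped > 0) {
    message(sprintf("detect_metal_blobs: dropped %d component(s) above max_vol (possible merged fiducials)",
                    dropped))
  }
  if (length(out) == 0) return(empty)
  df <- do.call(rbind, out)
  df <- df[order(-df$peak), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("blob_detections", "data.frame")
  df
}

blob_centers <- function(blobs) {
  m <- as.matrix(blobs[, c("x", "y", "z")])
  dimnames(m) <- NULL
  m
}

#' Group detected blobs into patient trackers
#'
#' Selects 6 blobs forming 3 disjoint pairs whose intra-pair distances best
#' match the configured pairing distance (exhaustive over candidate
#' 6-subsets and perfect matchings, minimizing the summed absolute distance
#' mismatch). Ties break deterministically by blob sort order. Clips and
#' other distractors are excluded by the pairing geometry.
#'
#' @param blobs a `blob_detections` data.frame (>= 6 rows).
#' @param pairing_distance nominal intra-tracker disc distance, mm.
#' @param tol per-pair tolerance on |distance - pairing_distance|, mm.
#' @return list of class `tracker_layout`: `centers` (6 x 3, rows ordered
#'   tracker 1a, 1b, 2a, 2b, 3a, 3b), `pairs` (3 x 2 row indices into
#'   `blobs`), `pair_distances`, `pairing_distance`.
#' @export
group_into_trackers <- function(blobs, pairing_distance = 20, tol = 2) {
  n <- nrow(blobs)
  if (n < 6) {
    stop(sprintf("grouping error: need at least 6 blobs, got %d", n))
  }
  ctrs <- blob_centers(blobs)
  dmat <- as.matrix(stats::dist(ctrs))
  cand <- which(abs(dmat - pairing_distance) <= tol & upper.tri(dmat),
                arr.ind = TRUE)
  if (nrow(cand) < 3) {
    near <- sort(abs(dmat[upper.tri(dmat)] - pairing_distance))[1:min(6, n)]
    stop(sprintf("grouping error: only %d candidate pair(s) within %.1f mm of %.1f mm; nearest mismatches: %s",
                 nrow(cand), tol, pairing_distance,
                 paste(sprintf("%.1f", near), collapse = ", ")))
  }
  cost <- abs(dmat[cand] - pairing_distance)
  ord <- order(cost, cand[, 1], cand[, 2])
  cand <- cand[ord, , drop = FALSE]
  cost <- cost[ord]
  best <- NULL
  best_cost <- Inf
  k <- nrow(cand)
  for (i in seq_len(k - 2)) {
    if (cost[i] >= best_cost) break
    for (j in seq(i + 1, k - 1)) {
      if (any(cand[j, ] %in% cand[i, ])) next
      cij <- cost[i] + cost[j]
      if (cij >= best_cost) break
      for (l in seq(j + 1, k)) {
        if (any(cand[l, ] %in% c(cand[i, ], cand[j, ]))) next
        tot <- cij + cost[l]
        if (tot < best_cost - 1e-12) {
          best_cost <- tot
          best <- rbind(cand[i, ], cand[j, ], cand[l, ])
        }
      }
    }
  }
  if (is.null(best)) {
    stop("grouping error: no three disjoint pairs match the pairing distance")
  }
  rows <- as.vector(t(best))
  layout <- list(centers = ctrs[rows, , drop = FALSE],
                 pairs = best,
                 pair_distances = dmat[best],
                 pairing_distance = pairing_distance)
  class(layout) <- "tracker_layout"
  layout
}

#' Detect surgical clips in a liver ROI
#'
#' Runs [detect_metal_blobs()] restricted to a bounding box with a
#' clip-scale size filter (clips are an order of magnitude smaller than the
#' disc sensors).
#'
#' @param vol a `volume_image`.
#' @param roi list with `lo`, `hi` world-coordinate corners, mm.
#' @param threshold intensity threshold.
#' @param min_vol,max_vol clip volume band, mm^3 (defaults 1-20).
#' @return N x 3 matrix of clip centers (world mm); clips outside the
#'   imaging FOV are necessarily absent.
#' @export
detect_clips <- function(vol, roi, threshold = 2000, min_vol = 1,
                         max_vol = 20) {
  stopifnot(inherits(vol, "volume_image"))
  d <- dim(vol$voxels)
  corners <- as.matrix(expand.grid(x = c(roi$lo[1], roi$hi[1]),
                                   y = c(roi$lo[2], roi$hi[2]),
                                   z = c(roi$lo[3], roi$hi[3])))
  ci <- world_to_index(vol, corners)
  lo <- pmax(floor(apply(ci, 2, min)), 0)
  hi <- pmin(ceiling(apply(ci, 2, max)), d - 1)
  if (any(lo > hi)) stop("roi error: empty clip ROI")
  sub <- vol$voxels[(lo[1]:hi[1]) + 1, (lo[2]:hi[2]) + 1, (lo[3]:hi[3]) + 1,
                    drop = FALSE]
  subvol <- volume_image(sub, vol$spacing,
                         drop(index_to_world(vol, matrix(lo, 1))),
                         vol$direction, vol$frame)
  blobs <- detect_metal_blobs(subvol, threshold, min_vol, max_vol)
  blob_centers(blobs)
}

#' Full-vs-truncated-FOV localization consistency
#'
#' Euclidean displacement of corresponding fiducial centers detected in a
#' fully sampled and a truncated-projection reconstruction of the same
#' scene; the mean displacement is the geometric-distortion QC statistic.
#' Correspondence is established with [match_correspondence()].
#'
#' @param centers_full,centers_trunc N x 3 matrices, mm (same frame).
#' @return list with `displacement` (per-center, mm) and `mean` (mm).
#' @export
truncation_consistency <- function(centers_full, centers_trunc) {
  a <- as_points(centers_full)
  b <- as_points(centers_trunc)
  if (nrow(a) != nrow(b)) {
    stop("cardinality error: center counts differ between reconstructions")
  }
  f <- match_correspondence(a, b, frame_src = "full", frame_dst = "trunc")
  disp <- sqrt(rowSums((f$src - f$dst)^2))
  list(displacement = disp, mean = mean(disp))
}
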