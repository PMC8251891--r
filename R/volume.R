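# 3-D scalar volumes with spacing/origin/direction metadata.
#
# Geometry convention: world coordinate of 0-based voxel index i is
# origin + direction %*% (spacing * i), voxel-center convention, LPS axes.

#' 3-D scalar volume with grid geometry
#'
#' @param voxels 3-D numeric array.
#' @param spacing voxel spacing, mm 3-vector (> 0).
#' @param origin world coordinate of voxel (0,0,0) center, mm.
#' @param direction 3x3 orthonormal direction matrix (columns are the world
#'   directions of the i/j/k axes).
#' @param frame frame label the world coordinates live in.
#' @return object of class `volume_image`.
#' @export
volume_image <- function(voxels, spacing, origin = c(0, 0, 0),
                         direction = diag(3), frame = "world") {
  stopifnot(length(dim(voxels)) == 3)
  spacing <- as.numeric(spacing)
  if (any(spacing <= 0)) stop("spacing must be positive on all axes")
  if (max(abs(crossprod(direction) - diag(3))) > 1e-6) {
    stop("direction matrix must be orthonormal")
  }
  structure(list(voxels = voxels, spacing = spacing,
                 origin = as.numeric(origin), direction = direction,
                 frame = as.character(frame)),
            class = "volume_image")
}

#' @export
print.volume_image <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("volume_image [%s]: %d x %d x %d voxels, spacing (%.3g, %.3g, %.3g) mm\n",
              x$frame, d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  invisible(x)
}

#' Voxel index / world coordinate conversion
#'
#' Indices are 0-based, voxel-center convention.
#'
#' @param vol a `volume_image`.
#' @param idx N x 3 matrix of 0-based (possibly fractional) voxel indices.
#' @return N x 3 matrix of world coordinates, mm.
#' @export
index_to_world <- function(vol, idx) {
  idx <- as_points(idx)
  sweep(sweep(idx, 2, vol$spacing, "*") %*% t(vol$direction), 2, vol$origin, "+")
}

#' @rdname index_to_world
#' @param pts N x 3 matrix of world coordinates, mm.
#' @export
world_to_index <- function(vol, pts) {
  pts <- as_points(pts)
  sweep(sweep(pts, 2, vol$origin, "-") %*% vol$direction, 2, vol$spacing, "/")
}

#' World coordinates of every voxel center
#'
#' @param vol a `volume_image`.
#' @return N x 3 matrix in array order (first index fastest).
#' @export
voxel_world_coords <- function(vol) {
  d <- dim(vol$voxels)
  idx <- cbind(rep.int(seq_len(d[1]) - 1, d[2] * d[3]),
               rep.int(rep(seq_len(d[2]) - 1, each = d[1]), d[3]),
               rep(seq_len(d[3]) - 1, each = d[1] * d[2]))
  index_to_world(vol, idx)
}

#' Trilinear interpolation of a volume at world points
#'
#' Points outside the grid return `outside` (default NA).
#'
#' @param vol a `volume_image`.
#' @param pts N x 3 world coordinates, mm.
#' @param outside value for out-of-grid samples.
#' @return numeric vector of interpolated intensities.
#' @export
interp_volume <- function(vol, pts, outside = NA_real_) {
  idx <- world_to_index(vol, pts)
  d <- dim(vol$voxels)
  i0 <- floor(idx)
  f <- idx - i0
  ok <- idx[, 1] >= 0 & idx[, 1] <= d[1] - 1 &
        idx[, 2] >= 0 & idx[, 2] <= d[2] - 1 &
        idx[, 3] >= 0 & idx[, 3] <= d[3] - 1
  out <- rep(outside, nrow(idx))
  if (!any(ok)) return(out)
  i0 <- i0[ok, , drop = FALSE]
  f <- f[ok, , drop = FALSE]
  # clamp the upper corner so points exactly on the far face interpolate
  i1 <- pmin(i0 + 1, matrix(rep(d - 1, each = nrow(i0)), ncol = 3))
  i0 <- pmin(pmax(i0, 0), matrix(rep(d - 1, each = nrow(i0)), ncol = 3))
  v <- vol$voxels
  at <- function(a, b, cc) v[cbind(a + 1, b + 1, cc + 1)]
  fx <- f[, 1]; fy <- f[, 2]; fz <- f[, 3]
  c000 <- at(i0[, 1], i0[, 2], i0[, 3]); c100 <- at(i1[, 1], i0[, 2], i0[, 3])
  c010 <- at(i0[, 1], i1[, 2], i0[, 3]); c110 <- at(i1[, 1], i1[, 2], i0[, 3])
  c001 <- at(i0[, 1], i0[, 2], i1[, 3]); c101 <- at(i1[, 1], i0[, 2], i1[, 3])
  c011 <- at(i0[, 1], i1[, 2], i1[, 3]); c111 <- at(i1[, 1], i1[, 2], i1[, 3])
  out[ok] <-
    c000 * (1 - fx) * (1 - fy) * (1 - fz) + c100 * fx * (1 - fy) * (1 - fz) +
    c010 * (1 - fx) * fy * (1 - fz) + c110 * fx * fy * (1 - fz) +
    c001 * (1 - fx) * (1 - fy) * fz + c101 * fx * (1 - fy) * fz +
    c011 * (1 - fx) * fy * fz + c111 * fx * fy * fz
  out
}

# 6-connected binary erosion/dilation by one voxel, via array shifts.
shift_array <- function(a, axis, by, fill) {
  d <- dim(a)
  out <- array(fill, d)
  src <- lapply(d, seq_len)
  dst <- src
  n <- d[axis]
  if (abs(by) >= n) return(out)
  if (by > 0) { dst[[axis]] <- (1 + by):n; src[[axis]] <- 1:(n - by) }
  if (by < 0) { dst[[axis]] <- 1:(n + by); src[[axis]] <- (1 - by):n }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

binary_erode1 <- function(mask) {
  # outside treated as foreground (border-replication convention), so a
  # degenerate all-true mask is a fixed point of opening
  out <- mask
  for (ax in 1:3) for (s in c(-1, 1)) {
    out <- out & shift_array(mask, ax, s, TRUE)
  }
  out
}

binary_dilate1 <- function(mask) {
  out <- mask
  for (ax in 1:3) for (s in c(-1, 1)) {
    out <- out | shift_array(mask, ax, s, FALSE)
  }
  out
}

#' Morphological opening of a binary mask (1-voxel radius, 6-connected)
#'
#' @param mask logical 3-D array.
#' @return opened logical array.
#' @export
binary_open <- function(mask) {
  binary_dilate1(binary_erode1(mask))
}
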