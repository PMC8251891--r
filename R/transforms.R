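# Rigid-body transform algebra over named coordinate frames.
#
# Conventions used throughout the package:
#   * column-vector convention, y = R x + t;
#   * compose(A, B) means "apply B first, then A";
#   * quaternions are scalar-first (w, x, y, z), unit norm;
#   * all coordinates in mm, LPS axes; the EM-tracker frame is the world root.

#' Create a unit quaternion
#'
#' Quaternions are stored scalar-first `(w, x, y, z)` and normalized on
#' construction.
#'
#' @param w,x,y,z quaternion components (scalar part first).
#' @return numeric vector of length 4 with unit norm.
#' @export
quaternion <- function(w, x, y, z) {
  q <- c(w, x, y, z)
  n <- sqrt(sum(q^2))
  if (n < 1e-12) stop("quaternion norm is zero")
  q / n
}

#' @rdname quaternion
#' @param axis rotation axis (3-vector, need not be unit).
#' @param angle rotation angle in radians.
#' @export
quat_from_axis_angle <- function(axis, angle) {
  n <- sqrt(sum(axis^2))
  if (n < 1e-12) {
    if (abs(angle) > 1e-12) stop("zero axis with non-zero angle")
    return(c(1, 0, 0, 0))
  }
  u <- axis / n
  c(cos(angle / 2), sin(angle / 2) * u)
}

quat_multiply <- function(a, b) {
  c(a[1] * b[1] - sum(a[2:4] * b[2:4]),
    a[1] * b[2:4] + b[1] * a[2:4] + cross3(a[2:4], b[2:4]))
}

quat_conjugate <- function(q) c(q[1], -q[2:4])

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Convert between unit quaternions and rotation matrices
#'
#' `quat_to_matrix` returns the 3x3 rotation matrix of a scalar-first unit
#' quaternion; `matrix_to_quat` inverts it (Shepperd's method, numerically
#' stable for all rotation angles). Round-trip error is below 1e-12.
#'
#' @param q unit quaternion `(w, x, y, z)`.
#' @return 3x3 orthonormal matrix with determinant +1.
#' @export
quat_to_matrix <- function(q) {
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), nrow = 3, byrow = TRUE)
}

#' @rdname quat_to_matrix
#' @param R 3x3 rotation matrix.
#' @export
matrix_to_quat <- function(R) {
  tr <- R[1, 1] + R[2, 2] + R[3, 3]
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(0.25 * s,
           (R[3, 2] - R[2, 3]) / s,
           (R[1, 3] - R[3, 1]) / s,
           (R[2, 1] - R[1, 2]) / s)
  } else if (R[1, 1] > R[2, 2] && R[1, 1] > R[3, 3]) {
    s <- sqrt(1 + R[1, 1] - R[2, 2] - R[3, 3]) * 2
    q <- c((R[3, 2] - R[2, 3]) / s, 0.25 * s,
           (R[1, 2] + R[2, 1]) / s, (R[1, 3] + R[3, 1]) / s)
  } else if (R[2, 2] > R[3, 3]) {
    s <- sqrt(1 + R[2, 2] - R[1, 1] - R[3, 3]) * 2
    q <- c((R[1, 3] - R[3, 1]) / s, (R[1, 2] + R[2, 1]) / s,
           0.25 * s, (R[2, 3] + R[3, 2]) / s)
  } else {
    s <- sqrt(1 + R[3, 3] - R[1, 1] - R[2, 2]) * 2
    q <- c((R[2, 1] - R[1, 2]) / s, (R[1, 3] + R[3, 1]) / s,
           (R[2, 3] + R[3, 2]) / s, 0.25 * s)
  }
  if (q[1] < 0) q <- -q
  q / sqrt(sum(q^2))
}

#' Rotation angle of a unit quaternion
#'
#' @param q unit quaternion.
#' @return angle in radians, in `[0, pi]`.
#' @export
quat_angle <- function(q) {
  2 * acos(pmin(1, abs(q[1])))
}

quat_rotate <- function(q, points) {
  points <- as_points(points)
  points %*% t(quat_to_matrix(q))
}

as_points <- function(points) {
  if (is.null(dim(points))) {
    stopifnot(length(points) == 3)
    points <- matrix(points, nrow = 1)
  }
  storage.mode(points) <- "double"
  stopifnot(ncol(points) == 3)
  points
}

#' Rigid transform between two named coordinate frames
#'
#' A rigid transform maps points from `frame_from` to `frame_to` using the
#' column-vector convention `y = R x + t`. The rotation is stored as a
#' scalar-first unit quaternion. Frame labels are mandatory and checked at
#' composition time, which turns silent chain-order mistakes into errors.
#'
#' @param rotation unit quaternion `(w, x, y, z)` or 3x3 rotation matrix.
#' @param translation 3-vector, mm.
#' @param frame_from,frame_to frame labels (non-empty strings).
#' @return object of class `rigid_transform` with elements `q`, `t`,
#'   `frame_from`, `frame_to`.
#' @examples
#' Tz <- rigid_transform(quat_from_axis_angle(c(0, 0, 1), pi / 2),
#'                       c(0, 0, 0), "A", "B")
#' apply_transform(Tz, c(1, 0, 0))  # -> (0, 1, 0)
#' @export
rigid_transform <- function(rotation = c(1, 0, 0, 0), translation = c(0, 0, 0),
                            frame_from, frame_to) {
  if (missing(frame_from) || missing(frame_to) ||
      !nzchar(frame_from) || !nzchar(frame_to)) {
    stop("rigid_transform requires non-empty frame_from and frame_to labels")
  }
  if (is.matrix(rotation)) {
    check_rotation_matrix(rotation)
    q <- matrix_to_quat(rotation)
  } else {
    stopifnot(length(rotation) == 4)
    n <- sqrt(sum(rotation^2))
    if (abs(n - 1) > 1e-9) stop("rotation quaternion is not unit norm")
    q <- rotation / n
    if (q[1] < 0) q <- -q
  }
  stopifnot(length(translation) == 3)
  structure(list(q = q, t = as.numeric(translation),
                 frame_from = as.character(frame_from),
                 frame_to = as.character(frame_to)),
            class = "rigid_transform")
}

check_rotation_matrix <- function(R, tol = 1e-9) {
  if (!all(dim(R) == c(3, 3))) stop("rotation matrix must be 3x3")
  if (max(abs(crossprod(R) - diag(3))) > sqrt(tol)) {
    stop("rotation matrix is not orthonormal")
  }
  if (det(R) < 0) stop("rotation matrix has negative determinant (reflection)")
  invisible(TRUE)
}

#' @rdname rigid_transform
#' @export
identity_transform <- function(frame_from, frame_to = frame_from) {
  rigid_transform(c(1, 0, 0, 0), c(0, 0, 0), frame_from, frame_to)
}

is_rigid_transform <- function(x) inherits(x, "rigid_transform")

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf("rigid_transform: %s -> %s\n", x$frame_from, x$frame_to))
  cat(sprintf("  rotation %.3f deg, translation (%.3f, %.3f, %.3f) mm\n",
              quat_angle(x$q) * 180 / pi, x$t[1], x$t[2], x$t[3]))
  invisible(x)
}

#' Compose two rigid transforms
#'
#' `compose_transform(outer, inner)` applies `inner` first, then `outer`
#' (column-vector convention). The frame labels must chain:
#' `inner$frame_to == outer$frame_from`.
#'
#' @param outer,inner `rigid_transform` objects.
#' @return the composed transform mapping `inner$frame_from` to
#'   `outer$frame_to`.
#' @export
compose_transform <- function(outer, inner) {
  stopifnot(is_rigid_transform(outer), is_rigid_transform(inner))
  if (!identical(inner$frame_to, outer$frame_from)) {
    stop(sprintf("frame mismatch in compose: inner maps to '%s' but outer maps from '%s'",
                 inner$frame_to, outer$frame_from))
  }
  q <- quat_multiply(outer$q, inner$q)
  t <- drop(quat_rotate(outer$q, inner$t)) + outer$t
  rigid_transform(q / sqrt(sum(q^2)), t, inner$frame_from, outer$frame_to)
}

#' Invert a rigid transform
#'
#' @param T a `rigid_transform`.
#' @return the inverse transform, with frame labels swapped.
#' @export
invert_transform <- function(T) {
  stopifnot(is_rigid_transform(T))
  qi <- quat_conjugate(T$q)
  rigid_transform(qi, -drop(quat_rotate(qi, T$t)), T$frame_to, T$frame_from)
}

#' Apply a rigid transform to points
#'
#' @param T a `rigid_transform`.
#' @param points 3-vector or N x 3 matrix of points in `T$frame_from` (mm).
#' @return points mapped into `T$frame_to`, same shape as the input.
#' @export
apply_transform <- function(T, points) {
  stopifnot(is_rigid_transform(T))
  single <- is.null(dim(points))
  pts <- as_points(points)
  out <- pts %*% t(quat_to_matrix(T$q))
  out <- sweep(out, 2, T$t, "+")
  if (single) drop(out) else out
}

#' Homogeneous 4x4 matrix of a rigid transform
#'
#' @param T a `rigid_transform`.
#' @return 4x4 homogeneous matrix (row-major when serialized).
#' @export
transform_matrix <- function(T) {
  m <- diag(4)
  m[1:3, 1:3] <- quat_to_matrix(T$q)
  m[1:3, 4] <- T$t
  m
}

#' @rdname transform_matrix
#' @param m 4x4 homogeneous rigid matrix.
#' @param frame_from,frame_to frame labels.
#' @export
transform_from_matrix <- function(m, frame_from, frame_to) {
  stopifnot(all(dim(m) == c(4, 4)))
  if (max(abs(m[4, ] - c(0, 0, 0, 1))) > 1e-9) {
    stop("last row of a rigid homogeneous matrix must be (0,0,0,1)")
  }
  rigid_transform(m[1:3, 1:3], m[1:3, 4], frame_from, frame_to)
}

# --- pose samples ------------------------------------------------------------

#' Timestamped EM sensor reading
#'
#' A 6-DoF sample carries a full pose (position + scalar-first unit
#' quaternion); a 5-DoF sample carries position + a unit direction (sensor
#' axis; roll is unobservable).
#'
#' @param timestamp seconds.
#' @param tool_id tool label, e.g. `"liver_sensor"`.
#' @param position 3-vector, mm (EM frame).
#' @param orientation unit quaternion (dof = 6) or unit 3-vector (dof = 5).
#' @param dof 5 or 6.
#' @return object of class `pose_sample`.
#' @export
pose_sample <- function(timestamp, tool_id, position, orientation, dof = 6L) {
  dof <- as.integer(dof)
  if (!dof %in% c(5L, 6L)) stop("dof must be 5 or 6")
  if (dof == 6L) {
    if (length(orientation) != 4) stop("6-DoF orientation must be a quaternion")
    n <- sqrt(sum(orientation^2))
    if (abs(n - 1) > 1e-9) stop("orientation quaternion is not unit norm")
    orientation <- orientation / n
  } else {
    if (length(orientation) != 3) stop("5-DoF orientation must be a direction 3-vector")
    n <- sqrt(sum(orientation^2))
    if (abs(n - 1) > 1e-9) stop("direction vector is not unit norm")
    orientation <- orientation / n
  }
  structure(list(timestamp = as.numeric(timestamp),
                 tool_id = as.character(tool_id),
                 position = as.numeric(position),
                 orientation = as.numeric(orientation),
                 dof = dof),
            class = "pose_sample")
}

#' Rigid pose of a 6-DoF sample
#'
#' Returns the transform from the sensor-local frame to the EM frame.
#'
#' @param s a 6-DoF `pose_sample`.
#' @param local_frame label for the sensor-local frame.
#' @return a `rigid_transform` local -> EM.
#' @export
pose_to_transform <- function(s, local_frame = paste0(s$tool_id, "_local")) {
  stopifnot(inherits(s, "pose_sample"))
  if (s$dof != 6L) stop("dof error: a 5-DoF sample has no full pose (roll unobservable)")
  rigid_transform(s$orientation, s$position, local_frame, "EM")
}

#' Validate per-tool timestamp monotonicity of a pose stream
#'
#' @param stream list of `pose_sample`.
#' @return invisibly TRUE; errors if any tool's timestamps decrease.
#' @export
validate_stream <- function(stream) {
  if (length(stream) == 0) return(invisible(TRUE))
  ids <- vapply(stream, function(s) s$tool_id, character(1))
  ts <- vapply(stream, function(s) s$timestamp, numeric(1))
  for (id in unique(ids)) {
    tt <- ts[ids == id]
    if (any(diff(tt) < 0)) {
      stop(sprintf("pose stream for tool '%s' has decreasing timestamps", id))
    }
  }
  invisible(TRUE)
}
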