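# Point-based rigid registration between coordinate frames: the Phase-I
# clip-to-pointer registration and the Phase-II six-disc-sensor registration
# share this solver; only the fiducial source differs.

#' Paired fiducial set
#'
#' A unique rigid solution needs at least 3 non-collinear pairs
#' ([register_points()] enforces this); smaller sets are still valid for
#' residual evaluation with [fre()].
#'
#' @param src N x 3 matrix of fiducial positions in the source frame, mm.
#' @param dst N x 3 matrix of the corresponding positions in the destination
#'   frame, mm.
#' @param labels optional fiducial labels.
#' @param frame_src,frame_dst frame labels.
#' @return object of class `fiducial_set`.
#' @export
fiducial_set <- function(src, dst, labels = NULL,
                         frame_src = "src", frame_dst = "dst") {
  src <- as_points(src)
  dst <- as_points(dst)
  if (nrow(src) != nrow(dst)) {
    stop("cardinality error: src and dst fiducial counts differ")
  }
  if (nrow(src) == 0) stop("empty fiducial set")
  if (nrow(src) > 1) {
    dd <- as.matrix(stats::dist(src))
    diag(dd) <- Inf
    if (min(dd) < 1e-6) stop("degenerate-geometry error: coincident source fiducials")
  }
  if (is.null(labels)) labels <- paste0("f", seq_len(nrow(src)))
  structure(list(labels = as.character(labels), src = src, dst = dst,
                 frame_src = frame_src, frame_dst = frame_dst),
            class = "fiducial_set")
}

# Smallest/largest singular value test for collinearity of the centered
# source cloud; names the unconstrained axis in the error.
check_not_collinear <- function(pts) {
  ctr <- sweep(pts, 2, colMeans(pts), "-")
  sv <- svd(ctr, nu = 0, nv = 3)
  if (sv$d[2] < 1e-6 * sv$d[1]) {
    axis <- sv$v[, 1]
    stop(sprintf(paste0("degenerate-geometry error: fiducials are collinear; ",
                        "rotation about axis (%.3f, %.3f, %.3f) is unconstrained"),
                 axis[1], axis[2], axis[3]))
  }
  invisible(TRUE)
}

#' Least-squares rigid point registration
#'
#' Closed-form solution of `argmin_T sum_i || R s_i + t - d_i ||^2` via the
#' cross-covariance SVD (Kabsch/Umeyama) with a determinant guard against
#' reflections. This is the global least-squares optimum; the fiducial
#' registration error (FRE) is the RMS residual after alignment.
#'
#' @param fids a `fiducial_set` (>= 3 non-collinear points).
#' @return list with `transform` (a `rigid_transform` src -> dst frame) and
#'   `fre` (mm).
#' @examples
#' src <- rbind(c(0,0,0), c(100,0,0), c(0,100,0), c(0,0,100))
#' f <- fiducial_set(src, sweep(src, 2, c(10,-5,2), "+"))
#' register_points(f)$fre  # 0
#' @export
register_points <- function(fids) {
  stopifnot(inherits(fids, "fiducial_set"))
  if (nrow(fids$src) < 3) {
    stop("degenerate-geometry error: at least 3 fiducials are required for a unique rigid solution")
  }
  check_not_collinear(fids$src)
  cs <- colMeans(fids$src)
  cd <- colMeans(fids$dst)
  X <- sweep(fids$src, 2, cs, "-")
  Y <- sweep(fids$dst, 2, cd, "-")
  H <- crossprod(X, Y)           # 3x3 cross-covariance
  sv <- svd(H)
  S <- diag(c(1, 1, sign(det(sv$v %*% t(sv$u)))))
  R <- sv$v %*% S %*% t(sv$u)
  t <- cd - drop(R %*% cs)
  T <- rigid_transform(R, t, fids$frame_src, fids$frame_dst)
  list(transform = T, fre = fre(T, fids))
}

#' Fiducial registration error
#'
#' Root-mean-square residual `sqrt(mean_i || T(s_i) - d_i ||^2)` of a
#' transform over a fiducial set; zero iff the alignment is perfect.
#'
#' @param T a `rigid_transform` mapping src-frame points to the dst frame.
#' @param fids a `fiducial_set`.
#' @return FRE in mm.
#' @export
fre <- function(T, fids) {
  res <- apply_transform(T, fids$src) - fids$dst
  sqrt(mean(rowSums(res^2)))
}

all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1)
  out <- matrix(0L, 0, n)
  for (i in seq_len(n)) {
    rest <- setdiff(seq_len(n), i)
    out <- rbind(out, cbind(i, matrix(rest[sub], nrow(sub))))
  }
  out
}

#' Establish fiducial correspondence by exhaustive assignment
#'
#' Finds the label assignment between two equally sized point lists (at most
#' 8 points) that minimizes the post-registration FRE, by exhaustive search
#' over permutations; ties are broken by the lexicographically smallest
#' permutation. Used to match automatically detected disc-sensor centers to
#' live EM sensor readings, where the hardware order is unknown.
#'
#' @param detected N x 3 matrix (e.g. image-detected centers), mm.
#' @param live N x 3 matrix (e.g. live EM positions), mm.
#' @param frame_src,frame_dst frame labels for the returned set.
#' @return a `fiducial_set` with `src = detected` and `dst = live[perm, ]`;
#'   the chosen permutation is in attribute `"permutation"`.
#' @export
match_correspondence <- function(detected, live,
                                 frame_src = "src", frame_dst = "dst") {
  detected <- as_points(detected)
  live <- as_points(live)
  if (nrow(detected) != nrow(live)) {
    stop("cardinality error: detected and live point counts differ")
  }
  n <- nrow(detected)
  if (n > 8) stop("exhaustive correspondence search supports at most 8 points")
  perms <- all_permutations(n)
  dimnames(perms) <- NULL
  best <- NULL
  best_fre <- Inf
  for (i in seq_len(nrow(perms))) {
    p <- perms[i, ]
    f <- fiducial_set(detected, live[p, , drop = FALSE],
                      frame_src = frame_src, frame_dst = frame_dst)
    r <- register_points(f)
    # strictly-better rule + row-order search = lexicographic tie-break
    if (r$fre < best_fre - 1e-12) {
      best_fre <- r$fre
      best <- p
    }
  }
  out <- fiducial_set(detected, live[best, , drop = FALSE],
                      frame_src = frame_src, frame_dst = frame_dst)
  attr(out, "permutation") <- best
  out
}
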