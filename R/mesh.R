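# Triangle-mesh utilities: unit-sphere subdivision meshes for liver/tumor
# surfaces, exact point-to-surface distance, and a ray-parity containment test.

#' Build a triangle mesh
#'
#' @param vertices N x 3 matrix, mm.
#' @param faces M x 3 integer matrix of 1-based vertex indices.
#' @return object of class `tri_mesh`.
#' @export
tri_mesh <- function(vertices, faces) {
  vertices <- as_points(vertices)
  dimnames(vertices) <- NULL
  faces <- matrix(as.integer(faces), ncol = 3)
  if (nrow(faces) == 0) stop("mesh has no faces")
  if (max(faces) > nrow(vertices) || min(faces) < 1) stop("face index out of range")
  structure(list(vertices = vertices, faces = faces), class = "tri_mesh")
}

#' @export
print.tri_mesh <- function(x, ...) {
  cat(sprintf("tri_mesh: %d vertices, %d faces\n", nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

#' Icosphere-based ellipsoid mesh
#'
#' Subdivided icosahedron scaled to the given semi-axes; used for the phantom
#' liver and tumor surfaces.
#'
#' @param center 3-vector, mm.
#' @param semiaxes 3-vector of semi-axis lengths, mm (a sphere when equal).
#' @param subdivisions number of 4-to-1 triangle subdivisions (default 3,
#'   1280 faces).
#' @return a `tri_mesh`.
#' @export
mesh_ellipsoid <- function(center, semiaxes, subdivisions = 3) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  phi, 0), c(1,  phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1,  phi), c(0, 1,  phi), c(0, -1, -phi), c(0, 1, -phi),
    c( phi, 0, -1), c( phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (i in seq_len(subdivisions)) {
    edge_key <- function(a, b) paste0(pmin(a, b), "_", pmax(a, b))
    midpoints <- new.env(hash = TRUE)
    verts <- v
    get_mid <- function(a, b) {
      k <- edge_key(a, b)
      idx <- midpoints[[k]]
      if (is.null(idx)) {
        m <- (verts[a, ] + verts[b, ]) / 2
        m <- m / sqrt(sum(m^2))
        verts <<- rbind(verts, m)
        idx <- nrow(verts)
        midpoints[[k]] <- idx
      }
      idx
    }
    nf <- matrix(0L, nrow = 4 * nrow(f), ncol = 3)
    for (j in seq_len(nrow(f))) {
      a <- f[j, 1]; b <- f[j, 2]; cc <- f[j, 3]
      ab <- get_mid(a, b); bc <- get_mid(b, cc); ca <- get_mid(cc, a)
      nf[(4 * j - 3):(4 * j), ] <- rbind(c(a, ab, ca), c(b, bc, ab),
                                         c(cc, ca, bc), c(ab, bc, ca))
    }
    v <- verts
    f <- nf
  }
  v <- sweep(sweep(v, 2, semiaxes, "*"), 2, center, "+")
  tri_mesh(v, f)
}

# Precompute per-triangle corner/edge arrays used by the distance kernel.
mesh_triangles <- function(mesh) {
  a <- mesh$vertices[mesh$faces[, 1], , drop = FALSE]
  b <- mesh$vertices[mesh$faces[, 2], , drop = FALSE]
  c_ <- mesh$vertices[mesh$faces[, 3], , drop = FALSE]
  centroid <- (a + b + c_) / 3
  rad <- sqrt(pmax(rowSums((a - centroid)^2),
                   rowSums((b - centroid)^2),
                   rowSums((c_ - centroid)^2)))
  list(a = a, ab = b - a, ac = c_ - a, centroid = centroid, radius = rad)
}

# Closest point on each triangle to point p (Ericson's barycentric-region
# method, vectorized over triangles). Returns squared distances and feet.
point_triangles_closest <- function(p, tri) {
  a <- tri$a; ab <- tri$ab; ac <- tri$ac
  ap <- sweep(-a, 2, p, "+")              # p - a
  d1 <- rowSums(ab * ap); d2 <- rowSums(ac * ap)
  bp <- ap - ab                            # p - b
  d3 <- rowSums(ab * bp); d4 <- rowSums(ac * bp)
  cp <- ap - ac                            # p - c
  d5 <- rowSums(ab * cp); d6 <- rowSums(ac * cp)

  va <- d3 * d6 - d5 * d4
  vb <- d5 * d2 - d1 * d6
  vc <- d1 * d4 - d3 * d2

  n <- nrow(a)
  u <- numeric(n); v <- numeric(n)

  reg_a <- d1 <= 0 & d2 <= 0
  reg_b <- !reg_a & d3 >= 0 & d4 <= d3
  reg_ab <- !reg_a & !reg_b & vc <= 0 & d1 >= 0 & d3 <= 0
  reg_c <- !reg_a & !reg_b & !reg_ab & d6 >= 0 & d5 <= d6
  reg_ac <- !reg_a & !reg_b & !reg_ab & !reg_c & vb <= 0 & d2 >= 0 & d6 <= 0
  reg_bc <- !reg_a & !reg_b & !reg_ab & !reg_c & !reg_ac &
    va <= 0 & (d4 - d3) >= 0 & (d5 - d6) >= 0
  interior <- !(reg_a | reg_b | reg_ab | reg_c | reg_ac | reg_bc)

  u[reg_b] <- 1
  if (any(reg_ab)) u[reg_ab] <- d1[reg_ab] / (d1[reg_ab] - d3[reg_ab])
  v[reg_c] <- 1
  if (any(reg_ac)) v[reg_ac] <- d2[reg_ac] / (d2[reg_ac] - d6[reg_ac])
  if (any(reg_bc)) {
    w <- (d4[reg_bc] - d3[reg_bc]) /
      ((d4[reg_bc] - d3[reg_bc]) + (d5[reg_bc] - d6[reg_bc]))
    u[reg_bc] <- 1 - w
    v[reg_bc] <- w
  }
  if (any(interior)) {
    denom <- va[interior] + vb[interior] + vc[interior]
    u[interior] <- vb[interior] / denom
    v[interior] <- vc[interior] / denom
  }
  foot <- a + u * ab + v * ac
  diff <- sweep(-foot, 2, p, "+")
  list(d2 = rowSums(diff^2), foot = foot)
}

#' Exact point-to-mesh surface distance
#'
#' Minimum Euclidean distance from each query point to the triangle surface.
#' A bounding-sphere index prunes triangles that cannot contain the closest
#' point; set `index = FALSE` for the plain all-triangles scan (the
#' brute-force oracle used in tests).
#'
#' @param points 3-vector or N x 3 matrix of query points, mm.
#' @param mesh a `tri_mesh`.
#' @param index use the bounding-sphere pruning index (default TRUE).
#' @return list with `distance` (N), `foot` (N x 3 closest surface points).
#' @export
point_mesh_distance <- function(points, mesh, index = TRUE) {
  stopifnot(inherits(mesh, "tri_mesh"))
  pts <- as_points(points)
  tri <- mesh_triangles(mesh)
  n <- nrow(pts)
  dist <- numeric(n)
  foot <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    p <- pts[i, ]
    if (index) {
      lb <- sqrt(rowSums(sweep(tri$centroid, 2, p, "-")^2)) - tri$radius
      best_guess <- which.min(lb)
      sub0 <- point_triangles_closest(p, lapply(
        tri[c("a", "ab", "ac")], function(m) m[best_guess, , drop = FALSE]))
      keep <- lb <= sqrt(sub0$d2[1])
      sub <- lapply(tri[c("a", "ab", "ac")], function(m) m[keep, , drop = FALSE])
      res <- point_triangles_closest(p, sub)
      j <- which.min(res$d2)
      dist[i] <- sqrt(res$d2[j])
      foot[i, ] <- res$foot[j, ]
    } else {
      res <- point_triangles_closest(p, tri)
      j <- which.min(res$d2)
      dist[i] <- sqrt(res$d2[j])
      foot[i, ] <- res$foot[j, ]
    }
  }
  list(distance = dist, foot = foot)
}

#' Point-in-mesh test by ray parity
#'
#' Casts a ray along +x from each query point and counts triangle crossings;
#' odd parity means inside. Intended for closed, watertight meshes.
#'
#' @param points N x 3 matrix, mm.
#' @param mesh a `tri_mesh`.
#' @return logical vector.
#' @export
points_in_mesh <- function(points, mesh) {
  pts <- as_points(points)
  tri <- mesh_triangles(mesh)
  a <- tri$a; ab <- tri$ab; ac <- tri$ac
  dir <- c(1, 0, 0)
  # Moller-Trumbore, vectorized over triangles per query point.
  pvec <- cbind(0, -ac[, 3], ac[, 2])                    # dir x ac
  det <- rowSums(ab * pvec)
  ok0 <- abs(det) > 1e-12
  inside <- logical(nrow(pts))
  for (i in seq_len(nrow(pts))) {
    tvec <- sweep(-a, 2, pts[i, ], "+")
    u <- rowSums(tvec * pvec) / det
    qvec <- cbind(tvec[, 2] * ab[, 3] - tvec[, 3] * ab[, 2],
                  tvec[, 3] * ab[, 1] - tvec[, 1] * ab[, 3],
                  tvec[, 1] * ab[, 2] - tvec[, 2] * ab[, 1])
    v <- (qvec[, 1] * dir[1]) / det
    tt <- rowSums(ac * qvec) / det
    hits <- ok0 & u >= 0 & u <= 1 & v >= 0 & (u + v) <= 1 & tt > 1e-9
    inside[i] <- (sum(hits) %% 2) == 1
  }
  inside
}

#' Apply a rigid transform to a mesh
#'
#' @param mesh a `tri_mesh`.
#' @param T a `rigid_transform`.
#' @return the transformed mesh.
#' @export
transform_mesh <- function(mesh, T) {
  tri_mesh(apply_transform(T, mesh$vertices), mesh$faces)
}
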