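# On-disk formats. Volumes: NIfTI (.nii/.nii.gz, via RNifti; the internal
# LPS convention is converted to/from NIfTI's RAS affine) and MetaImage
# (.mha, local raw payload, written as doubles for bit-exact round trips).
# Meshes: ASCII STL and ASCII PLY. Pose streams: JSON-lines. Fiducials:
# CSV. Transforms: plain-text 4x4 row-major matrix + JSON frame sidecar.

lps_to_ras <- function(aff) {
  aff[1, ] <- -aff[1, ]
  aff[2, ] <- -aff[2, ]
  aff
}

volume_affine <- function(vol) {
  a <- diag(4)
  a[1:3, 1:3] <- vol$direction %*% diag(vol$spacing)
  a[1:3, 4] <- vol$origin
  a
}

#' Read and write volumes
#'
#' Supported formats (by extension): NIfTI `.nii` / `.nii.gz` and MetaImage
#' `.mha`. Geometry (spacing, origin, direction) round-trips within 1e-6 mm
#' and voxels bit-exactly for `.mha` (stored as doubles).
#'
#' @param vol a `volume_image`.
#' @param path file path.
#' @param frame frame label to attach on read (formats do not carry it).
#' @return `read_volume` returns a `volume_image`; `write_volume` the path,
#'   invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "volume_image"))
  ext <- tolower(sub("^.*?(\\.nii\\.gz|\\.[a-z]+)$", "\\1", path))
  if (ext %in% c(".nii", ".nii.gz")) {
    img <- RNifti::asNifti(vol$voxels)
    RNifti::pixdim(img) <- vol$spacing
    aff <- structure(lps_to_ras(volume_affine(vol)), code = 2L)
    RNifti::sform(img) <- aff
    RNifti::qform(img) <- aff
    RNifti::writeNifti(img, path)
  } else if (ext == ".mha") {
    write_mha(vol, path)
  } else {
    stop("format error: unsupported volume extension '", ext, "'")
  }
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path, frame = "world") {
  if (!file.exists(path)) stop("format error: file not found: ", path)
  ext <- tolower(sub("^.*?(\\.nii\\.gz|\\.[a-z]+)$", "\\1", path))
  if (ext %in% c(".nii", ".nii.gz")) {
    img <- RNifti::readNifti(path)
    aff <- lps_to_ras(structure(RNifti::xform(img), code = NULL))
    dirspc <- aff[1:3, 1:3]
    spacing <- sqrt(colSums(dirspc^2))
    direction <- sweep(dirspc, 2, spacing, "/")
    vox <- array(as.numeric(img), dim = dim(img))
    volume_image(vox, spacing, aff[1:3, 4], direction, frame)
  } else if (ext == ".mha") {
    read_mha(path, frame)
  } else {
    stop("format error: unsupported volume extension '", ext, "'")
  }
}

write_mha <- function(vol, path) {
  d <- dim(vol$voxels)
  hdr <- c(
    "ObjectType = Image",
    "NDims = 3",
    "BinaryData = True",
    "BinaryDataByteOrderMSB = False",
    "CompressedData = False",
    paste("TransformMatrix =", paste(format(t(vol$direction), digits = 17),
                                     collapse = " ")),
    paste("Offset =", paste(format(vol$origin, digits = 17), collapse = " ")),
    paste("ElementSpacing =", paste(format(vol$spacing, digits = 17),
                                    collapse = " ")),
    paste("DimSize =", paste(d, collapse = " ")),
    "ElementType = MET_DOUBLE",
    "ElementDataFile = LOCAL")
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(hdr, con)
  writeBin(as.numeric(vol$voxels), con, size = 8, endian = "little")
  invisible(path)
}

read_mha <- function(path, frame = "world") {
  con <- file(path, "rb")
  on.exit(close(con))
  fields <- list()
  repeat {
    line <- readLines(con, n = 1, warn = FALSE)
    if (length(line) == 0) stop("format error: truncated MetaImage header (no ElementDataFile)")
    kv <- strsplit(line, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2) stop("format error: malformed MetaImage header line: ", line)
    key <- trimws(kv[1]); val <- trimws(kv[2])
    fields[[key]] <- val
    if (key == "ElementDataFile") break
  }
  need <- c("DimSize", "ElementSpacing", "Offset", "TransformMatrix", "ElementType")
  for (k in need) {
    if (is.null(fields[[k]])) stop("format error: missing MetaImage field '", k, "'")
  }
  if (fields$ElementDataFile != "LOCAL") {
    stop("format error: only LOCAL MetaImage payloads are supported")
  }
  d <- as.integer(strsplit(fields$DimSize, "\\s+")[[1]])
  if (length(d) != 3 || any(is.na(d))) stop("format error: bad DimSize")
  spacing <- as.numeric(strsplit(fields$ElementSpacing, "\\s+")[[1]])
  origin <- as.numeric(strsplit(fields$Offset, "\\s+")[[1]])
  direction <- t(matrix(as.numeric(strsplit(fields$TransformMatrix, "\\s+")[[1]]), 3, 3))
  type <- fields$ElementType
  n <- prod(d)
  raw_vals <- switch(type,
    MET_DOUBLE = readBin(con, "numeric", n, size = 8, endian = "little"),
    MET_FLOAT = readBin(con, "numeric", n, size = 4, endian = "little"),
    MET_SHORT = readBin(con, "integer", n, size = 2, endian = "little"),
    MET_UCHAR = as.numeric(readBin(con, "integer", n, size = 1, signed = FALSE)),
    stop("format error: unsupported ElementType '", type, "'"))
  if (length(raw_vals) < n) stop("format error: truncated MetaImage payload")
  volume_image(array(as.numeric(raw_vals), dim = d), spacing, origin,
               direction, frame)
}

# --- meshes -----------------------------------------------------------------

#' Read and write triangle meshes (ASCII STL / PLY)
#'
#' PLY preserves vertex indexing (lossless round trip); STL stores
#' per-facet corners, so reading merges coincident vertices.
#'
#' @param mesh a `tri_mesh`.
#' @param path file path ending in `.stl` or `.ply`.
#' @return `read_mesh` returns a `tri_mesh`.
#' @export
write_mesh <- function(mesh, path) {
  stopifnot(inherits(mesh, "tri_mesh"))
  ext <- tolower(tools::file_ext(path))
  if (ext == "ply") {
    v <- mesh$vertices; f <- mesh$faces - 1L
    lines <- c("ply", "format ascii 1.0",
               paste("element vertex", nrow(v)),
               "property double x", "property double y", "property double z",
               paste("element face", nrow(f)),
               "property list uchar int vertex_indices", "end_header",
               apply(format(v, digits = 17, trim = TRUE), 1, paste, collapse = " "),
               paste(3, f[, 1], f[, 2], f[, 3]))
    writeLines(lines, path)
  } else if (ext == "stl") {
    v <- mesh$vertices; f <- mesh$faces
    facet <- function(i) {
      a <- v[f[i, 1], ]; b <- v[f[i, 2], ]; cc <- v[f[i, 3], ]
      nrm <- cross3(b - a, cc - a)
      nn <- sqrt(sum(nrm^2)); if (nn > 0) nrm <- nrm / nn
      fmt <- function(p) paste(format(p, digits = 17, trim = TRUE), collapse = " ")
      c(paste("facet normal", fmt(nrm)), "  outer loop",
        paste("    vertex", fmt(a)), paste("    vertex", fmt(b)),
        paste("    vertex", fmt(cc)), "  endloop", "endfacet")
    }
    writeLines(c("solid mesh",
                 unlist(lapply(seq_len(nrow(f)), facet)),
                 "endsolid mesh"), path)
  } else {
    stop("format error: unsupported mesh extension '", ext, "'")
  }
  invisible(path)
}

#' @rdname write_mesh
#' @export
read_mesh <- function(path) {
  if (!file.exists(path)) stop("format error: file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  lines <- readLines(path, warn = FALSE)
  if (ext == "ply") {
    if (length(lines) < 3 || lines[1] != "ply") stop("format error: not a PLY file")
    nv <- as.integer(sub("element vertex ", "", grep("^element vertex", lines, value = TRUE)))
    nf <- as.integer(sub("element face ", "", grep("^element face", lines, value = TRUE)))
    hdr_end <- which(lines == "end_header")
    if (length(hdr_end) != 1 || length(nv) != 1 || length(nf) != 1) {
      stop("format error: malformed PLY header")
    }
    vl <- lines[(hdr_end + 1):(hdr_end + nv)]
    fl <- lines[(hdr_end + nv + 1):(hdr_end + nv + nf)]
    v <- do.call(rbind, lapply(strsplit(vl, "\\s+"), as.numeric))
    f <- do.call(rbind, lapply(strsplit(fl, "\\s+"), function(x) as.integer(x[2:4]) + 1L))
    tri_mesh(v, f)
  } else if (ext == "stl") {
    if (!grepl("^solid", lines[1])) stop("format error: only ASCII STL is supported")
    vl <- grep("^\\s*vertex", lines, value = TRUE)
    pts <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"),
                                 function(x) as.numeric(x[2:4])))
    if (nrow(pts) %% 3 != 0) stop("format error: STL vertex count not a multiple of 3")
    key <- apply(pts, 1, function(p) paste(format(p, digits = 15), collapse = "_"))
    uid <- match(key, unique(key))
    v <- pts[!duplicated(key), , drop = FALSE]
    f <- matrix(uid, ncol = 3, byrow = TRUE)
    tri_mesh(v, f)
  } else {
    stop("format error: unsupported mesh extension '", ext, "'")
  }
}

# --- pose streams -----------------------------------------------------------

#' Read and write EM pose streams (JSON-lines)
#'
#' One JSON object per line with fields `timestamp`, `tool_id`, `dof`,
#' `position`, `orientation`. Reading validates the schema (with line
#' numbers) and per-tool timestamp monotonicity.
#'
#' @param stream list of `pose_sample`.
#' @param path file path.
#' @return `read_pose_stream` returns a list of `pose_sample`.
#' @export
write_pose_stream <- function(stream, path) {
  lines <- vapply(stream, function(s) {
    jsonlite::toJSON(list(timestamp = s$timestamp, tool_id = s$tool_id,
                          dof = s$dof, position = s$position,
                          orientation = s$orientation),
                     auto_unbox = TRUE, digits = NA)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_pose_stream
#' @export
read_pose_stream <- function(path) {
  if (!file.exists(path)) stop("format error: file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  stream <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    rec <- tryCatch(jsonlite::fromJSON(lines[i]),
                    error = function(e) NULL)
    if (is.null(rec)) stop(sprintf("parse error at line %d: invalid JSON", i))
    need <- c("timestamp", "tool_id", "dof", "position", "orientation")
    miss <- setdiff(need, names(rec))
    if (length(miss)) {
      stop(sprintf("parse error at line %d: missing field(s) %s",
                   i, paste(miss, collapse = ", ")))
    }
    stream[[i]] <- tryCatch(
      pose_sample(rec$timestamp, rec$tool_id, rec$position, rec$orientation,
                  rec$dof),
      error = function(e) stop(sprintf("parse error at line %d: %s",
                                       i, conditionMessage(e))))
  }
  validate_stream(stream)
  stream
}

# --- fiducials --------------------------------------------------------------

#' Read and write fiducial CSV files (label, x, y, z, frame)
#'
#' @param points N x 3 matrix, mm.
#' @param path file path.
#' @param labels fiducial labels.
#' @param frame frame label written to every row.
#' @return `read_fiducials` returns a list with `points`, `labels`, `frame`.
#' @export
write_fiducials <- function(points, path, labels = NULL, frame = "world") {
  pts <- as_points(points)
  if (is.null(labels)) labels <- paste0("f", seq_len(nrow(pts)))
  df <- data.frame(label = labels, x = pts[, 1], y = pts[, 2], z = pts[, 3],
                   frame = frame)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_fiducials
#' @export
read_fiducials <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("label", "x", "y", "z", "frame")
  if (!all(need %in% names(df))) {
    stop("format error: fiducial CSV must have columns label,x,y,z,frame")
  }
  list(points = as.matrix(df[, c("x", "y", "z")]), labels = df$label,
       frame = unique(df$frame)[1])
}

# --- transforms -------------------------------------------------------------

#' Read and write rigid transforms
#'
#' The matrix file holds the 4x4 homogeneous matrix (row-major, plain
#' text); a JSON sidecar (`<path>.json`) carries the frame labels.
#'
#' @param T a `rigid_transform`.
#' @param path matrix file path.
#' @return `read_transform` returns a `rigid_transform`.
#' @export
write_transform <- function(T, path) {
  m <- transform_matrix(T)
  writeLines(apply(format(m, digits = 17, trim = TRUE), 1, paste,
                   collapse = " "), path)
  jsonlite::write_json(list(frame_from = T$frame_from, frame_to = T$frame_to),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_transform
#' @param frame_from,frame_to frame labels used when no sidecar exists.
#' @export
read_transform <- function(path, frame_from = NULL, frame_to = NULL) {
  if (!file.exists(path)) stop("format error: file not found: ", path)
  m <- do.call(rbind, lapply(strsplit(readLines(path, warn = FALSE), "\\s+"),
                             as.numeric))
  if (!all(dim(m) == c(4, 4)) || anyNA(m)) {
    stop("format error: transform file must hold a 4x4 numeric matrix")
  }
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    fr <- jsonlite::fromJSON(sidecar)
    frame_from <- fr$frame_from
    frame_to <- fr$frame_to
  }
  if (is.null(frame_from) || is.null(frame_to)) {
    stop("format error: frame labels required (no sidecar found)")
  }
  transform_from_matrix(m, frame_from, frame_to)
}

# --- run configuration ------------------------------------------------------

#' Write / read a run configuration (YAML)
#'
#' @param config a named list (see [run_config()]).
#' @param path YAML file path.
#' @return `read_run_config` returns the list.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("format error: file not found: ", path)
  yaml::read_yaml(path)
}

# --- registration chains ----------------------------------------------------

#' Write / read a registration chain (JSON)
#'
#' Stores T1, T23, optional T4 as 4x4 row-major matrices with frame labels,
#' the liver-sensor snapshot pose and the tracker snapshot positions.
#'
#' @param chain a `registration_chain`.
#' @param path JSON file path.
#' @return `read_chain` returns a `registration_chain`.
#' @export
write_chain <- function(chain, path) {
  stopifnot(inherits(chain, "registration_chain"))
  tr <- function(T) if (is.null(T)) NULL else
    list(matrix = transform_matrix(T), frame_from = T$frame_from,
         frame_to = T$frame_to)
  obj <- list(
    T1 = tr(chain$T1), T23 = tr(chain$T23), T4 = tr(chain$T4),
    S_ref = list(timestamp = chain$S_ref$timestamp,
                 tool_id = chain$S_ref$tool_id,
                 position = chain$S_ref$position,
                 orientation = chain$S_ref$orientation,
                 dof = chain$S_ref$dof),
    tracker_ref = chain$tracker_ref)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_chain
#' @export
read_chain <- function(path) {
  if (!file.exists(path)) stop("format error: file not found: ", path)
  obj <- jsonlite::fromJSON(path)
  untr <- function(x) {
    if (is.null(x) || length(x) == 0) return(NULL)
    transform_from_matrix(matrix(unlist(x$matrix), 4, 4, byrow = FALSE),
                          x$frame_from, x$frame_to)
  }
  S_ref <- pose_sample(obj$S_ref$timestamp, obj$S_ref$tool_id,
                       obj$S_ref$position, obj$S_ref$orientation,
                       obj$S_ref$dof)
  tracker_ref <- if (is.null(obj$tracker_ref)) NULL else
    matrix(unlist(obj$tracker_ref), ncol = 3)
  build_chain(untr(obj$T1), untr(obj$T23), S_ref, tracker_ref,
              T4 = untr(obj$T4))
}
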