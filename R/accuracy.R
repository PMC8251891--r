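# Accuracy assessment of the navigation system: image-based clip-to-tumor
# distances (the Phase-II verification), the navigation-vs-image comparison
# statistics (mean +/- SD of the absolute difference, Pearson R), repeated-
# measurement variability, and target-registration-error (TRE) profiling on
# phantoms as a function of distance from the liver sensor.

#' Paired accuracy measurement at one marker
#'
#' @param marker_id marker label.
#' @param d_nav navigation-based shortest marker-to-tumor distance, mm.
#' @param d_img image-measured distance, mm; when `observer_values` is
#'   given, `d_img` is their mean (the observer-averaged image distance).
#' @param observer_values optional per-observer distances, mm.
#' @return object of class `accuracy_record`.
#' @export
accuracy_record <- function(marker_id, d_nav, d_img = NULL,
                            observer_values = NULL) {
  if (!is.null(observer_values)) {
    if (any(observer_values < 0)) stop("observer distances must be non-negative")
    ov_mean <- mean(observer_values)
    if (!is.null(d_img) && abs(d_img - ov_mean) > 1e-9) {
      stop("d_img must equal the mean of observer_values")
    }
    d_img <- ov_mean
  }
  if (is.null(d_img)) stop("d_img or observer_values required")
  if (d_nav < 0 || d_img < 0) stop("distances must be non-negative")
  structure(list(marker_id = as.character(marker_id),
                 d_nav = as.numeric(d_nav), d_img = as.numeric(d_img),
                 observer_values = observer_values),
            class = "accuracy_record")
}

#' Image-measured clip-to-tumor distance
#'
#' Minimum Euclidean distance from a clip center to the tumor edge, on
#' either representation: a surface mesh (exact point-to-triangle distance)
#' or a binary segmentation mask (distance to the nearest boundary voxel
#' center — the reproducible surrogate for the visually judged tumor edge).
#'
#' @param clip_center 3-vector, mm.
#' @param tumor a `tri_mesh` or a binary `volume_image` segmentation.
#' @return distance in mm (non-negative).
#' @export
image_distance <- function(clip_center, tumor) {
  p <- matrix(as.numeric(clip_center), 1)
  if (inherits(tumor, "tri_mesh")) {
    return(point_mesh_distance(p, tumor)$distance[1])
  }
  if (inherits(tumor, "volume_image")) {
    m <- tumor$voxels > 0.5
    if (!any(m)) stop("empty tumor segmentation")
    boundary <- m & !binary_erode1(m)
    idx <- which(boundary, arr.ind = TRUE) - 1
    pts <- index_to_world(tumor, idx)
    return(sqrt(min(rowSums(sweep(pts, 2, drop(p), "-")^2))))
  }
  stop("tumor must be a tri_mesh or a binary volume_image")
}

#' Navigation-vs-image accuracy statistics
#'
#' The accuracy measure is the absolute difference between the
#' navigation-based distance and the (observer-averaged) image-based
#' distance per marker; reported as mean +/- SD together with the Pearson
#' correlation between the two distance sets and its two-sided p-value from
#' the t-distribution with n - 2 degrees of freedom.
#'
#' @param records list of `accuracy_record` (n >= 3).
#' @return list with `mean_abs_diff`, `sd`, `pearson_r`, `p_value`, `n`,
#'   and `degenerate` (TRUE when either variable has zero variance, in
#'   which case the correlation is undefined and returned as NA).
#' @export
accuracy_stats <- function(records) {
  if (length(records) < 3) {
    stop("sample-size error: at least 3 accuracy records are required")
  }
  stopifnot(all(vapply(records, inherits, logical(1), "accuracy_record")))
  d_nav <- vapply(records, function(r) r$d_nav, numeric(1))
  d_img <- vapply(records, function(r) r$d_img, numeric(1))
  ad <- abs(d_nav - d_img)
  n <- length(ad)
  degenerate <- stats::sd(d_nav) < 1e-12 || stats::sd(d_img) < 1e-12
  if (degenerate) {
    warning("zero variance in the distances: Pearson correlation undefined")
    r <- NA_real_; p <- NA_real_
  } else {
    ct <- stats::cor.test(d_nav, d_img, method = "pearson",
                          alternative = "two.sided")
    r <- unname(ct$estimate)
    p <- ct$p.value
  }
  list(mean_abs_diff = mean(ad), sd = stats::sd(ad),
       pearson_r = r, p_value = p, n = n, degenerate = degenerate)
}

#' Repeated-measurement spread
#'
#' Per-point range (max - min) over repeated measurements of the same
#' accuracy point, and the across-point mean — the repeat-variability
#' statistic of the observer analysis.
#'
#' @param measurements named list; each element a numeric vector of
#'   repeated distances (mm) for one point (>= 2 repeats).
#' @return list with `per_point` (named ranges, mm) and `mean_spread` (mm).
#' @export
repeat_variability <- function(measurements) {
  if (length(measurements) == 0) stop("no measurements given")
  spread <- vapply(measurements, function(v) {
    if (length(v) < 2) {
      stop("single repeat: at least 2 repeated measurements per point are required")
    }
    max(v) - min(v)
  }, numeric(1))
  list(per_point = spread, mean_spread = mean(spread))
}

#' TRE profile by distance from the liver sensor
#'
#' For each tracking frame, the target registration error of a sample point
#' is the distance between its navigated position (semi-rigid model through
#' the chain) and its true position (phantom ground truth). Errors are
#' binned by the point's snapshot distance from the sensor, the quantity
#' the target-navigation-zone radius is defined on.
#'
#' @param scene_states list of `phantom_scene` at the tracked time points
#'   (ground truth).
#' @param nav_states list of `navigation_state` of equal length.
#' @param sample_points_mri N x 3 matrix of liver-attached sample points,
#'   MRI frame.
#' @param reference_scene the reference `phantom_scene` (for the sensor
#'   snapshot position); defaults to the first scene state.
#' @param breaks bin edges for distance-from-sensor, mm.
#' @return data.frame with `bin`, `n`, `mean_tre`, `sd_tre` (mm).
#' @export
tre_profile <- function(scene_states, nav_states, sample_points_mri,
                        reference_scene = scene_states[[1]],
                        breaks = c(0, 25, 50, 100, Inf)) {
  stopifnot(length(scene_states) == length(nav_states))
  pts <- as_points(sample_points_mri)
  d_sensor <- sqrt(rowSums(sweep(pts, 2,
                                 reference_scene$sensor$position, "-")^2))
  bin <- cut(d_sensor, breaks = breaks, include.lowest = TRUE, right = TRUE)
  tre <- matrix(NA_real_, length(scene_states), nrow(pts))
  for (i in seq_along(scene_states)) {
    true_em <- scene_points_em(scene_states[[i]], pts, "liver")
    nav_em <- locate_model(nav_states[[i]], pts)
    tre[i, ] <- sqrt(rowSums((true_em - nav_em)^2))
  }
  per_point <- colMeans(tre)
  out <- data.frame(
    bin = levels(bin),
    n = as.integer(table(bin)),
    mean_tre = as.numeric(tapply(per_point, bin, mean)),
    sd_tre = as.numeric(tapply(per_point, bin, stats::sd)))
  attr(out, "tre") <- tre
  attr(out, "distance_from_sensor") <- d_sensor
  out
}
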