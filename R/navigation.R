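# Semi-rigid tracking core. The registration chain brings the preoperative
# model (MRI frame) through the intraoperative CBCT into EM-tracking space;
# live motion of the single 6-DoF liver sensor is propagated to the model as
# a rigid transform (the semi-rigid approximation: the liver region near the
# sensor is treated as locally rigid). Guidance is claimed only inside the
# target navigation zone, a 50-mm-radius sphere around the sensor.

#' Semi-rigid liver tracking transform
#'
#' The rigid transform `pose(S_live) o pose(S_ref)^-1` in the EM frame: it
#' maps any point rigidly attached to the sensor from its snapshot position
#' to its live position. With `translation_only = TRUE` the sensor
#' orientation is ignored (ablation mode); the full 6-DoF pose is the
#' default since the tracking links the model orientation to the sensor.
#'
#' @param S_live,S_ref 6-DoF `pose_sample`s of the same tool.
#' @param translation_only use only the positional displacement.
#' @return a `rigid_transform` EM -> EM.
#' @export
liver_tracking_transform <- function(S_live, S_ref, translation_only = FALSE) {
  stopifnot(inherits(S_live, "pose_sample"), inherits(S_ref, "pose_sample"))
  if (S_live$dof != 6L || S_ref$dof != 6L) {
    stop("dof error: semi-rigid tracking needs 6-DoF poses (roll unobservable at 5 DoF)")
  }
  if (!identical(S_live$tool_id, S_ref$tool_id)) {
    stop(sprintf("tool mismatch: live '%s' vs reference '%s'",
                 S_live$tool_id, S_ref$tool_id))
  }
  if (translation_only) {
    return(rigid_transform(c(1, 0, 0, 0), S_live$position - S_ref$position,
                           "EM", "EM"))
  }
  lf <- paste0(S_live$tool_id, "_local")
  compose_transform(pose_to_transform(S_live, lf),
                    invert_transform(pose_to_transform(S_ref, lf)))
}

#' Build and validate a registration chain
#'
#' Validates that the transforms chain MRI -> CBCT -> EM without frame
#' gaps, that the liver-sensor snapshot is 6-DoF, and (when given) that T4
#' maps CT -> CBCT.
#'
#' @param T1 `rigid_transform` MRI -> CBCT (model-to-CBCT alignment).
#' @param T23 `rigid_transform` CBCT -> EM (six-point sensor registration).
#' @param S_ref 6-DoF `pose_sample` of the liver sensor captured at the
#'   CBCT snapshot.
#' @param tracker_ref 6 x 3 matrix of tracker-sensor positions at the
#'   snapshot (EM frame).
#' @param T4 optional `rigid_transform` CT -> CBCT (rib model).
#' @return object of class `registration_chain` with the composed
#'   `model_to_em` = T23 o T1.
#' @export
build_chain <- function(T1, T23, S_ref, tracker_ref = NULL, T4 = NULL) {
  stopifnot(is_rigid_transform(T1), is_rigid_transform(T23))
  if (!identical(T1$frame_from, "MRI") || !identical(T1$frame_to, "CBCT")) {
    stop(sprintf("frame error: T1 must map MRI->CBCT, got %s->%s",
                 T1$frame_from, T1$frame_to))
  }
  if (!identical(T23$frame_from, "CBCT") || !identical(T23$frame_to, "EM")) {
    stop(sprintf("frame error: T23 must map CBCT->EM, got %s->%s",
                 T23$frame_from, T23$frame_to))
  }
  if (!is.null(T4) &&
      (!identical(T4$frame_from, "CT") || !identical(T4$frame_to, "CBCT"))) {
    stop(sprintf("frame error: T4 must map CT->CBCT, got %s->%s",
                 T4$frame_from, T4$frame_to))
  }
  stopifnot(inherits(S_ref, "pose_sample"))
  if (S_ref$dof != 6L) stop("dof error: S_ref must be a 6-DoF sample")
  if (!is.null(tracker_ref)) {
    tracker_ref <- as_points(tracker_ref)
    if (nrow(tracker_ref) != 6) {
      stop("frame error: tracker_ref must hold the 6 tracker-sensor positions")
    }
  }
  structure(list(T1 = T1, T23 = T23, T4 = T4, S_ref = S_ref,
                 tracker_ref = tracker_ref,
                 model_to_em = compose_transform(T23, T1)),
            class = "registration_chain")
}

#' @export
print.registration_chain <- function(x, ...) {
  cat("registration_chain: MRI -> CBCT -> EM",
      if (!is.null(x$T4)) "(+ CT -> CBCT rib link)" else "", "\n")
  invisible(x)
}

#' Navigation state at one tracking frame
#'
#' Holds the chain, the live liver-sensor sample, and the derived
#' model-to-EM transform
#' `liver_tracking_transform(S_live, S_ref) o T23 o T1`.
#'
#' @param chain a `registration_chain`.
#' @param S_live live 6-DoF liver-sensor `pose_sample`.
#' @param pointer_live optional live pointer `pose_sample`.
#' @param zone_radius target-navigation-zone radius, mm (default 50).
#' @param translation_only propagate sensor translation only (ablation).
#' @return object of class `navigation_state`.
#' @export
navigation_state <- function(chain, S_live, pointer_live = NULL,
                             zone_radius = 50, translation_only = FALSE) {
  stopifnot(inherits(chain, "registration_chain"))
  if (zone_radius <= 0) stop("zone_radius must be positive")
  track <- liver_tracking_transform(S_live, chain$S_ref, translation_only)
  structure(list(chain = chain, S_live = S_live, pointer_live = pointer_live,
                 model_to_em_live = compose_transform(track, chain$model_to_em),
                 zone_radius = zone_radius),
            class = "navigation_state")
}

#' Locate model points in live EM coordinates
#'
#' Applies the live model-to-EM transform; when `S_live = S_ref` this
#' reduces to the static CBCT registration `T23 o T1`.
#'
#' @param state a `navigation_state`.
#' @param model_points_mri N x 3 matrix of model points, MRI frame, mm.
#' @return N x 3 matrix in the EM frame.
#' @export
locate_model <- function(state, model_points_mri) {
  stopifnot(inherits(state, "navigation_state"))
  apply_transform(state$model_to_em_live, as_points(model_points_mri))
}

#' Rib (body) reference frame from live tracker positions
#'
#' Rigid transform from the snapshot rib pose to the live rib pose, via
#' six-point registration of the tracker-sensor positions. Liver motion
#' relative to the ribs is `invert(rib_frame) o liver_tracking_transform`.
#'
#' @param tracker_live 6 x 3 matrix of live tracker-sensor positions, mm
#'   (EM frame), in the same order as `chain$tracker_ref`.
#' @param chain a `registration_chain` with `tracker_ref`.
#' @return a `rigid_transform` EM -> EM (snapshot -> live rib pose).
#' @export
rib_frame <- function(tracker_live, chain) {
  stopifnot(inherits(chain, "registration_chain"))
  if (is.null(chain$tracker_ref)) {
    stop("frame error: chain has no tracker_ref snapshot positions")
  }
  tracker_live <- as_points(tracker_live)
  if (nrow(tracker_live) != 6) {
    stop("cardinality error: expected 6 live tracker-sensor positions")
  }
  f <- fiducial_set(chain$tracker_ref, tracker_live,
                    frame_src = "EM", frame_dst = "EM")
  register_points(f)$transform
}

#' Liver motion relative to the rib frame
#'
#' @param state a `navigation_state`.
#' @param tracker_live 6 x 3 live tracker-sensor positions, mm.
#' @return a `rigid_transform` EM -> EM expressing the liver's motion with
#'   the body motion removed.
#' @export
liver_relative_to_ribs <- function(state, tracker_live) {
  ribs <- rib_frame(tracker_live, state$chain)
  track <- liver_tracking_transform(state$S_live, state$chain$S_ref)
  compose_transform(invert_transform(ribs), track)
}

#' Shortest pointer-to-tumor distance
#'
#' Minimum Euclidean distance from the pointer tip to the tumor surface as
#' displayed by the navigation system: the tumor mesh is carried from the
#' MRI frame into live EM coordinates by the chain, and the exact
#' point-to-triangle distance is computed (bounding-sphere index; the
#' brute-force scan is available as an oracle). Returns 0 when the tip is
#' inside the tumor.
#'
#' @param pointer_tip 3-vector, mm, EM frame.
#' @param state a `navigation_state`.
#' @param tumor_mesh_mri watertight `tri_mesh` in the MRI frame.
#' @param index use the pruning spatial index (default TRUE).
#' @return list with `distance` (mm), `foot` (closest surface point, EM
#'   frame) and `inside` (logical).
#' @export
pointer_to_tumor_distance <- function(pointer_tip, state, tumor_mesh_mri,
                                      index = TRUE) {
  stopifnot(inherits(state, "navigation_state"),
            inherits(tumor_mesh_mri, "tri_mesh"))
  mesh_em <- transform_mesh(tumor_mesh_mri, state$model_to_em_live)
  res <- point_mesh_distance(matrix(pointer_tip, 1), mesh_em, index = index)
  inside <- points_in_mesh(matrix(pointer_tip, 1), mesh_em)
  list(distance = if (inside) 0 else res$distance[1],
       foot = res$foot[1, ], inside = inside)
}

#' Target-navigation-zone membership
#'
#' A point is inside the zone iff its distance to the live sensor position
#' is at most `zone_radius` (closed boundary). Guidance outputs outside the
#' zone carry an explicit out-of-zone flag and are not accuracy-bearing.
#'
#' @param point 3-vector, mm, EM frame.
#' @param state a `navigation_state`.
#' @return list with `inside` (logical) and `distance_to_sensor` (mm).
#' @export
in_target_zone <- function(point, state) {
  stopifnot(inherits(state, "navigation_state"))
  d <- sqrt(sum((as.numeric(point) - state$S_live$position)^2))
  list(inside = d <= state$zone_radius, distance_to_sensor = d)
}
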