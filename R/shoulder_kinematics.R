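# Shoulder kinematics: locate the rotation centre by least-squares sphere
# fitting, calibrate the constant flange-to-shoulder transform, and express
# posture as two globographic angles (plane of elevation, elevation).
#
# Conventions (stated because they fix the numeric datum of the angles):
# world frame right-handed with Z vertical up; the subject sits with the
# coronal axis along world X and the sagittal axis along world Y.  Elevation
# is the angle between the centre-to-elbow direction and the downward
# vertical (-Z); plane of elevation is the azimuth of that direction about Z
# measured from world X.  Axial rotation of the upper arm is excluded by
# construction.

#' Algebraic least-squares sphere fit
#'
#' Fits centre and radius by the linear (Coope-style) formulation: each
#' point gives one row of `2 p . c + k = |p|^2` with `k = r^2 - |c|^2`,
#' solved in the least-squares sense.  Deterministic and closed-form.
#'
#' @param points numeric matrix with one 3-vector point per row (m), or a
#'   list of 3-vectors.
#' @return An object of class `sphere_fit`: `center` (3-vector, m), `radius`
#'   (m), `rms_residual` (RMS of signed point-to-sphere distances, m),
#'   `n_points`.
#' @export
fit_sphere <- function(points) {
  if (is.list(points) && !is.data.frame(points)) {
    points <- do.call(rbind, points)
  }
  points <- as.matrix(points)
  if (ncol(points) != 3L) stop("points must be n x 3", call. = FALSE)
  n <- nrow(points)
  if (n < 4L) stop("sphere fitting needs at least 4 points", call. = FALSE)
  a <- cbind(2 * points, 1)
  b <- rowSums(points^2)
  qr_a <- qr(a)
  if (qr_a$rank < 4L) {
    stop("degenerate geometry: points are coplanar or otherwise rank-deficient",
         call. = FALSE)
  }
  beta <- qr.coef(qr_a, b)
  center <- beta[1:3]
  r2 <- beta[4] + sum(center^2)
  if (r2 <= 0) {
    stop("degenerate geometry: non-positive fitted radius", call. = FALSE)
  }
  radius <- sqrt(r2)
  d <- sqrt(rowSums(sweep(points, 2, center)^2)) - radius
  structure(list(center = as.numeric(center), radius = radius,
                 rms_residual = sqrt(mean(d^2)), n_points = n),
            class = "sphere_fit")
}

#' @export
print.sphere_fit <- function(x, ...) {
  cat(sprintf(
    "<sphere_fit> center = (%.4f, %.4f, %.4f) m, radius = %.4f m, rms = %.2e m (n = %d)\n",
    x$center[1], x$center[2], x$center[3], x$radius, x$rms_residual,
    x$n_points))
  invisible(x)
}

#' Calibrate the constant flange-to-shoulder transform
#'
#' The upper limb and orthosis move as one rigid body bolted to the flange,
#' so the transform from the flange frame to the shoulder frame is constant.
#' It is determined at a reference pose where every shoulder angle is zero
#' (upper arm hanging vertically): there the shoulder frame coincides in
#' orientation with the world frame, so the rotation part is the transpose
#' of the reference flange rotation; the translation places the shoulder
#' origin at distance `radius` vertically above the elbow landmark, `radius`
#' being the fitted sphere radius (the centre-to-elbow distance).
#'
#' @param reference_axes numeric 7-vector: robot joint angles at the
#'   reference (all-zero shoulder angles) pose.
#' @param radius positive scalar (m): centre-to-elbow distance from the
#'   sphere fit.
#' @param params a `robot_params` object.
#' @param elbow_in_flange numeric 3-vector (m): the manually measured elbow
#'   landmark expressed in flange coordinates (default: flange origin).
#' @return An object of class `calibration_record` with fields
#'   `flange_to_shoulder` (`rigid_transform`), `reference_axes`,
#'   `elbow_in_flange`.
#' @export
calibrate <- function(reference_axes, radius, params = default_robot_params(),
                      elbow_in_flange = c(0, 0, 0)) {
  if (!is.numeric(radius) || length(radius) != 1L || radius <= 0) {
    stop("radius must be a positive scalar (m)", call. = FALSE)
  }
  tf_ref <- forward_kinematics(reference_axes, params)
  r_fs <- t(tf_ref$rotation)      # shoulder frame is world-aligned at reference
  # shoulder origin in world at reference: radius straight up from the elbow
  elbow_world <- rt_apply(tf_ref, as.numeric(elbow_in_flange))
  shoulder_world <- elbow_world + c(0, 0, radius)
  t_fs <- as.numeric(t(tf_ref$rotation) %*% (shoulder_world - tf_ref$translation))
  structure(list(flange_to_shoulder = rigid_transform(r_fs, t_fs),
                 reference_axes = as.numeric(reference_axes),
                 elbow_in_flange = as.numeric(elbow_in_flange)),
            class = "calibration_record")
}

#' Shoulder frame pose from robot joint angles
#'
#' Chains the flange pose with the calibrated constant transform:
#' `T_s = T_F %*% flange_to_shoulder`.
#'
#' @param q numeric 7-vector of joint angles (rad).
#' @param calib a `calibration_record`.
#' @param params a `robot_params` object.
#' @return A `rigid_transform` (shoulder frame in the world frame).
#' @export
shoulder_transform <- function(q, calib, params = default_robot_params()) {
  rt_compose(forward_kinematics(q, params), calib$flange_to_shoulder)
}

#' Project a point radially onto a fitted sphere
#'
#' Returns the intersection of the ray from the centre through the point
#' with the sphere surface: `center + radius * (point - center) / |point - center|`.
#'
#' @param point numeric 3-vector (m).
#' @param fit a `sphere_fit`.
#' @return numeric 3-vector on the sphere.
#' @export
project_to_sphere <- function(point, fit) {
  d <- as.numeric(point) - fit$center
  nd <- sqrt(sum(d^2))
  if (nd < 1e-12) {
    stop("projection direction undefined: point coincides with the sphere center",
         call. = FALSE)
  }
  fit$center + fit$radius * d / nd
}

#' Globographic shoulder angles of an elbow landmark
#'
#' Projects the elbow point radially onto the fitted sphere and decomposes
#' the centre-to-elbow direction into two angles: elevation (angle from the
#' downward vertical -Z, in `[0, pi]`) and plane of elevation (azimuth about
#' Z from world X, in `(-pi, pi]`).  Axial rotation of the upper arm does
#' not enter.  On the vertical axis the azimuth is undefined; it is reported
#' as 0 with `degenerate = TRUE`.
#'
#' @param elbow_world numeric 3-vector (m).
#' @param fit a `sphere_fit`.
#' @param timestamp optional time (s) carried through.
#' @return An object of class `shoulder_posture`: `plane_of_elevation`
#'   (rad), `elevation` (rad), `elbow_on_sphere` (3-vector), `degenerate`
#'   flag, `timestamp`.
#' @export
globographic_angles <- function(elbow_world, fit, timestamp = NA_real_) {
  p <- project_to_sphere(elbow_world, fit)
  u <- (p - fit$center) / fit$radius
  elevation <- acos(min(1, max(-1, -u[3])))
  rho <- sqrt(u[1]^2 + u[2]^2)
  degenerate <- rho < 1e-9
  plane <- if (degenerate) 0 else atan2(u[2], u[1])
  structure(list(plane_of_elevation = plane, elevation = elevation,
                 elbow_on_sphere = p, degenerate = degenerate,
                 timestamp = timestamp),
            class = "shoulder_posture")
}

#' Unit centre-to-elbow direction from globographic angles
#'
#' Inverse of the angular decomposition in [globographic_angles()]:
#' `u = (sin e cos p, sin e sin p, -cos e)` with `e` elevation and `p` plane
#' of elevation.
#'
#' @param plane_of_elevation azimuth (rad).
#' @param elevation elevation from the downward vertical (rad).
#' @return unit 3-vector in world axes.
#' @export
globographic_direction <- function(plane_of_elevation, elevation) {
  c(sin(elevation) * cos(plane_of_elevation),
    sin(elevation) * sin(plane_of_elevation),
    -cos(elevation))
}

#' Posture time series from a robot log
#'
#' Maps the fixed elbow landmark through the flange pose at every sample and
#' converts to globographic angles.  Following the observation that the
#' rotation centre drifts toward the end of a dragged trajectory, the sphere
#' is fitted on the former part of the trajectory only (`fit_fraction`).
#'
#' @param log a robot log `data.frame` (see [render_robot_log()]): columns
#'   `t`, `q1..q7`, `tau_e1..tau_e7`.
#' @param calib a `calibration_record`.
#' @param params a `robot_params`.
#' @param fit_fraction fraction of the samples (from the start) used for
#'   sphere fitting; default 0.7.
#' @param fit a pre-computed `sphere_fit` to reuse (e.g. across repeated
#'   runs); overrides `fit_fraction`.
#' @return list with `postures` (data.frame: `t`, `plane_of_elevation`,
#'   `elevation`, `degenerate`), `fit` (`sphere_fit`), `elbow_world`
#'   (n x 3 matrix).
#' @export
posture_series <- function(log, calib, params = default_robot_params(),
                           fit_fraction = 0.7, fit = NULL) {
  qcols <- paste0("q", 1:7)
  n <- nrow(log)
  elbow <- matrix(NA_real_, n, 3)
  for (i in seq_len(n)) {
    tf <- forward_kinematics(as.numeric(log[i, qcols]), params)
    elbow[i, ] <- rt_apply(tf, calib$elbow_in_flange)
  }
  if (is.null(fit)) {
    n_fit <- max(4L, floor(fit_fraction * n))
    fit <- fit_sphere(elbow[seq_len(n_fit), , drop = FALSE])
  }
  postures <- lapply(seq_len(n), function(i) {
    globographic_angles(elbow[i, ], fit, timestamp = log$t[i])
  })
  df <- data.frame(
    t = log$t,
    plane_of_elevation = vapply(postures, `[[`, 0, "plane_of_elevation"),
    elevation = vapply(postures, `[[`, 0, "elevation"),
    degenerate = vapply(postures, `[[`, NA, "degenerate")
  )
  list(postures = df, fit = fit, elbow_world = elbow)
}

#' Serialize a sphere fit or calibration record to JSON
#'
#' @param x a `sphere_fit` or `calibration_record`.
#' @param path output file path.
#' @export
write_calibration_json <- function(x, path) {
  obj <- if (inherits(x, "sphere_fit")) {
    list(type = "sphere_fit", center = x$center, radius = x$radius,
         rms_residual = x$rms_residual, n_points = x$n_points)
  } else if (inherits(x, "calibration_record")) {
    list(type = "calibration_record",
         flange_to_shoulder = rt_flatten(x$flange_to_shoulder),
         reference_axes = x$reference_axes,
         elbow_in_flange = x$elbow_in_flange)
  } else {
    stop("unsupported object", call. = FALSE)
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a sphere fit or calibration record written by [write_calibration_json()]
#' @param path JSON file path.
#' @return the deserialized object.
#' @export
read_calibration_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (identical(obj$type, "sphere_fit")) {
    structure(list(center = obj$center, radius = obj$radius,
                   rms_residual = obj$rms_residual, n_points = obj$n_points),
              class = "sphere_fit")
  } else if (identical(obj$type, "calibration_record")) {
    structure(list(flange_to_shoulder = rt_unflatten(obj$flange_to_shoulder),
                   reference_axes = obj$reference_axes,
                   elbow_in_flange = obj$elbow_in_flange),
              class = "calibration_record")
  } else {
    stop("unrecognized calibration JSON", call. = FALSE)
  }
}
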