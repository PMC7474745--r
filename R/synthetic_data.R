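# Synthetic scenes: a rigid upper limb on a ball-and-socket joint with a
# fixed rotation centre and a parametric passive torque field, dragged along
# abduction trajectories with a small secondary movement, rendered to
# flange-level or robot-level logs.  Every emitted sample satisfies the
# quasi-static balance equations by construction, so the whole pipeline can
# be validated against known ground truth.
#
# Generator wrench convention: the static system is over-determined (the
# flange constrains all 6 DoF and the ball joint adds more), so the
# decomposition into joint reaction and robot assist is fixed once: the
# shoulder provides zero reaction force (F_s = 0, an ideal ball joint under
# this convention), the robot carries the force balance minus limb gravity
# (F_R = -G) and closes the full moment balance at the shoulder centre.
# The pipeline only ever uses -M_R - M_FR, which is invariant to this
# choice.

#' Upper-limb inertial parameters (synthetic scenes)
#'
#' @param mass limb mass (kg).
#' @param com_offset distance of the limb centre of mass from the shoulder
#'   centre along the arm axis (m).
#' @return list of class `limb_params`.
#' @export
limb_params <- function(mass = 3.5, com_offset = 0.28) {
  stopifnot(mass >= 0, com_offset > 0)
  structure(list(mass = mass, com_offset = com_offset),
            class = "limb_params")
}

#' Parametric passive torque field
#'
#' The ground-truth torque-angle relationship of a synthetic shoulder:
#' gravity torque of the limb about the rotation centre plus a smooth
#' elastic soft-tissue resistance that is zero at the neutral (hanging)
#' posture and grows toward the range limits.  The resistance has a
#' component about the elevation axis (cubic-plus-exponential-edge in
#' elevation), a component about the vertical from out-of-plane deviation
#' (cubic in plane of elevation), and an axial-plane coupling term
#' quadratic in elevation about Z -- passive shoulder structures are not
#' aligned with any single anatomical axis, so all three world components
#' of the field are exercised.
#'
#' @param limb a `limb_params`.
#' @param k_cubic elevation resistance cubic coefficient (N m rad^-3).
#' @param k_edge amplitude of the end-range exponential stiffening (N m).
#' @param edge_width e-folding width of the stiffening (rad).
#' @param elevation_limit end-range elevation where stiffening is `k_edge`
#'   (rad).
#' @param k_plane out-of-plane cubic coefficient (N m rad^-3).
#' @param k_axial vertical-component coupling coefficient (N m rad^-2).
#' @param bump_amp amplitudes (N m) of the mid-range engagement bump about
#'   the elevation axis and the vertical: different capsuloligamentous
#'   structures engage over a limited angular region, producing a localized
#'   stiffness feature rather than a globally smooth monotone resistance.
#' @param bump_center elevation (rad) at which the bump peaks in the
#'   neutral plane.
#' @param bump_width Gaussian width of the bump (rad).
#' @param bump_shift displacement of the bump centre per radian of plane of
#'   elevation (rad/rad), coupling the feature's location to the plane.
#' @param gravity gravitational acceleration (m s^-2).
#' @return list of class `torque_field_params`.
#' @export
torque_field_params <- function(limb = limb_params(), k_cubic = 1.5,
                                k_edge = 2.0, edge_width = 0.15,
                                elevation_limit = 2.2, k_plane = 2.0,
                                k_axial = 1.0, bump_amp = c(6.0, 3.5),
                                bump_center = 1.0, bump_width = 0.08,
                                bump_shift = 1.0, gravity = 9.81) {
  structure(list(limb = limb, k_cubic = k_cubic, k_edge = k_edge,
                 edge_width = edge_width, elevation_limit = elevation_limit,
                 k_plane = k_plane, k_axial = k_axial,
                 bump_amp = as.numeric(bump_amp), bump_center = bump_center,
                 bump_width = bump_width, bump_shift = bump_shift,
                 gravity = gravity),
            class = "torque_field_params")
}

#' Evaluate the ground-truth passive torque field
#'
#' `M_P(plane, elevation)` in world axes (N m): gravity torque
#' `com_offset * u x (0, 0, -m g)` with `u` the arm direction from
#' [globographic_direction()], plus the elastic resistance described in
#' [torque_field_params()].  Zero at the neutral posture
#' (elevation = 0): the gravity moment arm vanishes and every resistance
#' term is zero there.
#'
#' @param plane_of_elevation azimuth (rad); may be a vector.
#' @param elevation elevation (rad); same length.
#' @param field a `torque_field_params`.
#' @return n x 3 matrix (or 3-vector for scalar input) of `M_P` (N m).
#' @export
torque_field <- function(plane_of_elevation, elevation,
                         field = torque_field_params()) {
  p <- as.numeric(plane_of_elevation); e <- as.numeric(elevation)
  stopifnot(length(p) == length(e))
  n <- length(p)
  out <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    u <- globographic_direction(p[i], e[i])
    g <- c(0, 0, -field$limb$mass * field$gravity)
    m_g <- cross3(field$limb$com_offset * u, g)
    # elevation resistance about the (horizontal) elevation axis, opposing
    # elevation; zero at e = 0 including the edge term
    a <- c(-sin(p[i]), cos(p[i]), 0)
    edge0 <- exp(-field$elevation_limit / field$edge_width)
    m_el <- -(field$k_cubic * e[i]^3 +
                field$k_edge * (exp((e[i] - field$elevation_limit) /
                                      field$edge_width) - edge0))
    # mid-range engagement bump: localized extra resistance whose position
    # couples to the plane of elevation; factor e^2/(bc^2+e^2) keeps the
    # whole field exactly zero at the neutral posture
    bc <- field$bump_center + field$bump_shift * p[i]
    bump <- exp(-((e[i] - bc) / field$bump_width)^2) *
      e[i]^2 / (field$bump_center^2 + e[i]^2)
    m_el <- m_el - field$bump_amp[1] * bump
    # out-of-plane and axial-coupling components about the vertical
    m_z <- -field$k_plane * p[i]^3 * sin(e[i]) + field$k_axial * e[i]^2 +
      field$bump_amp[2] * bump
    out[i, ] <- m_g + m_el * a + c(0, 0, m_z)
  }
  if (n == 1L) as.numeric(out) else out
}

#' Trajectory specification for a passive abduction run
#'
#' @param plane_of_elevation nominal plane of elevation (rad).
#' @param elevation_range length-2 numeric (rad): start < stop.
#' @param secondary_amplitude amplitude of the unconscious low-frequency
#'   wander in plane of elevation (rad).
#' @param n_samples number of samples (`>= 2`).
#' @param sample_rate sampling rate (Hz); default 50.
#' @param seed integer seed for the secondary-movement phases.
#' @return list of class `trajectory_spec`.
#' @export
trajectory_spec <- function(plane_of_elevation = 0,
                            elevation_range = c(10, 120) * pi / 180,
                            secondary_amplitude = 5 * pi / 180,
                            n_samples = 600L, sample_rate = 50,
                            seed = 1L) {
  stopifnot(length(elevation_range) == 2L,
            elevation_range[1] < elevation_range[2], n_samples >= 2L)
  structure(list(plane_of_elevation = plane_of_elevation,
                 elevation_range = as.numeric(elevation_range),
                 secondary_amplitude = secondary_amplitude,
                 n_samples = as.integer(n_samples),
                 sample_rate = sample_rate, seed = as.integer(seed)),
            class = "trajectory_spec")
}

#' Generate a posture time series for a dragged abduction
#'
#' Elevation ramps linearly (strictly increasing) across the range; the
#' plane of elevation wanders around its nominal value as a seeded sum of
#' three low-frequency sinusoids with random phases, scaled to the requested
#' amplitude -- the "secondary movement" that accompanies a designated
#' primary movement.
#'
#' @param spec a `trajectory_spec`.
#' @return `data.frame`: `t` (s), `plane_of_elevation`, `elevation` (rad).
#' @export
generate_trajectory <- function(spec = trajectory_spec()) {
  n <- spec$n_samples
  t <- (seq_len(n) - 1L) / spec$sample_rate
  elev <- seq(spec$elevation_range[1], spec$elevation_range[2],
              length.out = n)
  if (spec$secondary_amplitude > 0) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(spec$seed)
    phase <- stats::runif(3, 0, 2 * pi)
    amp <- stats::runif(3, 0.5, 1)
    s <- seq(0, 1, length.out = n)
    w <- amp[1] * sin(2 * pi * 0.5 * s + phase[1]) +
      amp[2] * sin(2 * pi * 1.1 * s + phase[2]) +
      amp[3] * sin(2 * pi * 1.9 * s + phase[3])
    w <- w / max(abs(w)) * spec$secondary_amplitude
  } else {
    w <- rep(0, n)
  }
  data.frame(t = t, plane_of_elevation = spec$plane_of_elevation + w,
             elevation = elev)
}

#' Scene geometry for synthetic renders
#'
#' Fixes the shoulder rotation centre in the robot world frame and the
#' centre-to-elbow distance (the sphere radius).  The flange is attached at
#' the elbow landmark and moves rigidly with the arm; its orientation is the
#' arm rotation composed with a constant mounting rotation (default: flange
#' axis pointing down toward the limb at the hanging reference, i.e. the
#' orthosis hangs beneath the wrist).  The calibration stage absorbs the
#' mounting rotation, and the default centre keeps the arm's configurations
#' well away from kinematic singularities over the standard trajectories.
#'
#' @param center shoulder rotation centre in world (m).
#' @param radius centre-to-elbow distance (m).
#' @param flange_mount 3x3 rotation: constant flange mounting orientation at
#'   the reference posture.
#' @param drift optional end-stage centre drift: a list
#'   `list(fraction =, offset =)` translating the centre linearly by
#'   `offset` (3-vector, m) over the final `fraction` of the trajectory.
#' @return list of class `scene_geometry`.
#' @export
scene_geometry <- function(center = c(0.50, 0.10, 0.45), radius = 0.30,
                           flange_mount = rot_y(pi), drift = NULL) {
  stopifnot(radius > 0)
  structure(list(center = as.numeric(center), radius = radius,
                 flange_mount = flange_mount, drift = drift),
            class = "scene_geometry")
}

# Arm rotation excluding axial rotation: Rz(p) Ry(-e) Rz(-p); identity at
# the hanging reference for any plane.
arm_rotation <- function(plane, elevation) {
  rot_z(plane) %*% rot_y(-elevation) %*% rot_z(-plane)
}

scene_center_at <- function(geom, frac_along) {
  c0 <- geom$center
  if (!is.null(geom$drift)) {
    start <- 1 - geom$drift$fraction
    if (frac_along > start) {
      c0 <- c0 + (frac_along - start) / geom$drift$fraction *
        as.numeric(geom$drift$offset)
    }
  }
  c0
}

#' Render a flange-level log from a trajectory and a torque field
#'
#' For each posture sample, places the rigid limb (flange at the elbow,
#' frame moving with the arm), evaluates the true passive torque
#' `M_P = M_s + M_G`, and solves the quasi-static balance for the robot
#' wrench under the generator's decomposition (`F_R = -G`, moment balance
#' closed at the shoulder centre).  The emitted measurement is the wrench
#' the limb applies to the flange (the reaction of the assist wrench),
#' with the orthosis weight added and optional isotropic Gaussian noise.
#'
#' @param traj trajectory `data.frame` from [generate_trajectory()].
#' @param field a `torque_field_params`.
#' @param geom a `scene_geometry`.
#' @param orthosis an `orthosis_params`.
#' @param noise_sd standard deviation of additive Gaussian noise on every
#'   wrench component (N / N m); 0 for noiseless.
#' @param seed seed for the noise draws.
#' @return list with `log` (data.frame: `t`, `pose1..pose16` row-major
#'   flange pose, `fx, fy, fz, mx, my, mz` measured wrench) and `truth`
#'   (class `scene_truth`: per-sample flange poses, elbow points, true
#'   `M_P`, true limb wrench, shoulder centre used).
#' @export
render_flange_log <- function(traj, field = torque_field_params(),
                              geom = scene_geometry(),
                              orthosis = orthosis_params(), noise_sd = 0,
                              seed = 1L) {
  n <- nrow(traj)
  g_vec <- c(0, 0, -field$limb$mass * field$gravity)
  poses <- vector("list", n)
  elbow <- matrix(0, n, 3)
  mp <- matrix(0, n, 3)
  wrench_meas <- matrix(0, n, 6)
  wrench_true <- matrix(0, n, 6)
  centers <- matrix(0, n, 3)
  mg <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    p <- traj$plane_of_elevation[i]; e <- traj$elevation[i]
    ci <- scene_center_at(geom, if (n > 1) (i - 1) / (n - 1) else 0)
    centers[i, ] <- ci
    u <- globographic_direction(p, e)
    pe <- ci + geom$radius * u
    tf <- rigid_transform(arm_rotation(p, e) %*% geom$flange_mount, pe)
    poses[[i]] <- tf
    elbow[i, ] <- pe
    mp_i <- torque_field(p, e, field)
    mp[i, ] <- mp_i
    mg[i, ] <- cross3(field$limb$com_offset * u, g_vec)
    # assist wrench: F_R = -G; moment balance about the centre gives
    # M_R = -M_P - (p_F - c) x F_R, with M_P = M_s + M_G
    f_r <- -g_vec
    m_r <- -mp_i - cross3(pe - ci, f_r)
    # limb-applied (measured) wrench is the reaction, at the flange origin
    f_limb <- -f_r
    m_limb <- -m_r
    wrench_true[i, ] <- c(f_limb, m_limb)
    # add orthosis weight as it appears in the raw measurement
    w_orth <- c(0, 0, -orthosis$mass * field$gravity)
    arm_vec <- as.numeric(tf$rotation %*% orthosis$com_in_flange)
    wrench_meas[i, ] <- c(f_limb + w_orth, m_limb + cross3(arm_vec, w_orth))
  }
  if (noise_sd > 0) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    wrench_meas <- wrench_meas + matrix(stats::rnorm(6 * n, 0, noise_sd), n, 6)
  }
  pose_flat <- t(vapply(poses, rt_flatten, numeric(16)))
  log <- data.frame(t = traj$t, pose_flat,
                    fx = wrench_meas[, 1], fy = wrench_meas[, 2],
                    fz = wrench_meas[, 3], mx = wrench_meas[, 4],
                    my = wrench_meas[, 5], mz = wrench_meas[, 6])
  names(log)[2:17] <- paste0("pose", 1:16)
  truth <- structure(list(poses = poses, elbow = elbow, mp = mp, mg = mg,
                          wrench_limb = wrench_true, centers = centers,
                          traj = traj, field = field, geom = geom),
                     class = "scene_truth")
  list(log = log, truth = truth)
}

#' Damped least-squares inverse kinematics
#'
#' Iterates `dq = J' (J J' + lambda^2 I)^-1 err` from `q0` until the mixed
#' pose error (position in m stacked with orientation in rad) drops below
#' `tol`.  The damping is error-adaptive (`lambda^2 + 0.1 |err|^2`), which
#' takes conservative steps far from the target and near-Newton steps close
#' to it; steps are capped at 0.5 rad in joint space.  Warm starting keeps
#' joint motion minimal sample to sample, which resolves the 7-DoF
#' redundancy.  If the iteration stalls in a singular local minimum, a
#' fixed, deterministic list of alternative starting configurations is tried
#' before declaring the pose unreachable.
#'
#' @param target `rigid_transform` flange target.
#' @param q0 numeric 7-vector warm start (rad).
#' @param params a `robot_params`.
#' @param tol convergence tolerance on the mixed error norm; default 1e-8.
#' @param max_iter iteration cap per start; default 400.
#' @param lambda base damping (default 1e-3).
#' @return numeric 7-vector of joint angles.
#' @export
numeric_ik <- function(target, q0, params = default_robot_params(),
                       tol = 1e-8, max_iter = 400L, lambda = 1e-3) {
  run <- function(q) {
    for (it in seq_len(max_iter)) {
      tf <- forward_kinematics(q, params)
      err <- c(target$translation - tf$translation,
               rotation_log(target$rotation %*% t(tf$rotation)))
      en <- sqrt(sum(err^2))
      if (en < tol) return(q)
      jac <- jacobian(q, params)
      lam2 <- lambda^2 + 0.1 * en^2
      dq <- as.numeric(t(jac) %*% solve(jac %*% t(jac) + lam2 * diag(6), err))
      nd <- sqrt(sum(dq^2))
      if (nd > 0.5) dq <- dq * 0.5 / nd
      q <- q + dq
    }
    NULL
  }
  starts <- c(list(check_q(q0)),
              list(c(0.2, 0.6, 0.1, -1.4, 0.1, 0.9, 0.1),
                   c(-0.2, 0.8, -0.1, -1.2, 0.2, -0.9, 0.0),
                   c(0.5, 1.2, 0.3, -0.8, -0.3, 1.2, 0.2),
                   c(0.0, -0.6, 0.0, 1.4, 0.0, -0.9, 0.0)))
  for (s in starts) {
    q <- run(s)
    if (!is.null(q)) return(q)
  }
  stop("numeric_ik: no convergence -- target pose unreachable from q0",
       call. = FALSE)
}

#' Render a robot-level log (axes angles + external joint torques)
#'
#' Tracks the flange poses of a rendered scene with [numeric_ik()] (warm
#' started sample to sample) and converts the measured limb wrench to
#' external joint torques through the virtual-work relation
#' `tau_e = t(J) %*% f`.  Optional per-joint Gaussian torque noise.
#'
#' @inheritParams render_flange_log
#' @param params a `robot_params`.
#' @param q_start warm start for the first sample's IK solve.
#' @param noise_sd standard deviation of per-joint torque noise (N m).
#' @return list with `log` (data.frame: `t`, `q1..q7`, `tau_e1..tau_e7`),
#'   `truth` (`scene_truth`), and `reference_axes` (joint angles realizing
#'   the hanging reference posture, for calibration).
#' @export
render_robot_log <- function(traj, field = torque_field_params(),
                             geom = scene_geometry(),
                             orthosis = orthosis_params(),
                             params = default_robot_params(), noise_sd = 0,
                             seed = 1L,
                             q_start = c(0.2, 0.6, 0.1, -1.4, 0.1, 0.9, 0.1)) {
  flange <- render_flange_log(traj, field, geom, orthosis, noise_sd = 0)
  n <- nrow(traj)
  qmat <- matrix(0, n, 7)
  tau <- matrix(0, n, 7)
  q_prev <- q_start
  for (i in seq_len(n)) {
    q <- numeric_ik(flange$truth$poses[[i]], q_prev, params)
    q_prev <- q
    qmat[i, ] <- q
    # measured wrench (limb + orthosis) mapped to joint torques
    w <- flange$log[i, c("fx", "fy", "fz", "mx", "my", "mz")]
    tau[i, ] <- as.numeric(t(jacobian(q, params)) %*% as.numeric(w))
  }
  if (noise_sd > 0) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    tau <- tau + matrix(stats::rnorm(7 * n, 0, noise_sd), n, 7)
  }
  # joint angles realizing the hanging reference posture (elevation 0),
  # needed by calibrate(); reached by IK from the first trajectory sample
  ref_tf <- rigid_transform(geom$flange_mount,
                            geom$center + geom$radius * c(0, 0, -1))
  ref_q <- numeric_ik(ref_tf, q_start, params)
  log <- data.frame(t = traj$t, qmat, tau)
  names(log) <- c("t", paste0("q", 1:7), paste0("tau_e", 1:7))
  list(log = log, truth = flange$truth, reference_axes = ref_q)
}

#' Standard synthetic scene: two passive abductions with sensor noise
#'
#' The package's reference study conditions: one subject-like scene (default
#' torque field and geometry), two abduction trajectories in the 0 and 30
#' degree planes of elevation (562 + 561 samples at 50 Hz, elevation 10-120
#' degrees, 5 degree secondary movement), rendered to robot-level logs with
#' Gaussian external-torque noise of 0.2 N m per joint -- the order of
#' magnitude of external-torque estimates from joint-torque-sensing arms.
#'
#' @param seed integer; seeds the secondary movement and the noise draws.
#' @param noise_sd per-joint torque noise (N m); default 0.2.
#' @param n_samples length-2 integer vector of samples per trajectory.
#' @param params a `robot_params`.
#' @return list: `logs` (two robot-log data.frames), `truths` (two
#'   `scene_truth`s), `calib` (`calibration_record`), `geom`, `field`,
#'   `reference_axes`.
#' @export
standard_scene <- function(seed = 1L, noise_sd = 0.2,
                           n_samples = c(562L, 561L),
                           params = default_robot_params()) {
  geom <- scene_geometry()
  field <- torque_field_params()
  planes <- c(0, 30 * pi / 180)
  renders <- lapply(1:2, function(k) {
    traj <- generate_trajectory(trajectory_spec(
      plane_of_elevation = planes[k], n_samples = n_samples[k],
      seed = seed + k))
    render_robot_log(traj, field, geom, orthosis_params(), params,
                     noise_sd = noise_sd, seed = seed + 10L + k)
  })
  calib <- calibrate(renders[[1]]$reference_axes, geom$radius, params)
  list(logs = lapply(renders, `[[`, "log"),
       truths = lapply(renders, `[[`, "truth"),
       calib = calib, geom = geom, field = field,
       reference_axes = renders[[1]]$reference_axes)
}

#' Write / read a robot log as CSV
#'
#' Columns `t, q1..q7, tau_e1..tau_e7` -- the DataRecorder-style layout of
#' the robot controller's logging facility (50 Hz by default).
#'
#' @param log robot log `data.frame`.
#' @param path CSV path.
#' @export
write_robot_log <- function(log, path) {
  utils::write.csv(log, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_robot_log
#' @return `read_robot_log`: the log `data.frame`.
#' @export
read_robot_log <- function(path) {
  log <- utils::read.csv(path)
  need <- c("t", paste0("q", 1:7), paste0("tau_e", 1:7))
  if (!all(need %in% names(log))) {
    stop("robot log is missing required columns", call. = FALSE)
  }
  log[, need]
}
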