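# Kinematic model of a 7-DoF serial manipulator: forward kinematics,
# geometric Jacobian, and recovery of the external wrench at the flange from
# the external joint torques via the principle of virtual work.

#' Robot kinematic parameters
#'
#' Describes a serial revolute manipulator as an ordered chain: for each
#' joint, a fixed link transform from the previous joint frame to the joint
#' frame, and a unit rotation axis expressed in that local frame; a final
#' fixed transform places the flange.  Forward kinematics is the ordered
#' product link_1 R_1(q_1) link_2 R_2(q_2) ... link_7 R_7(q_7) flange.
#'
#' @param link_translations list of 7 numeric 3-vectors, the fixed
#'   translation preceding each joint (m).  Link rotations are identity in
#'   the default model; supply `link_rotations` for a general chain.
#' @param joint_axes list of 7 unit 3-vectors, each joint's rotation axis in
#'   its local frame.
#' @param flange_offset numeric 3-vector, translation from the last joint
#'   frame to the flange origin (m).
#' @param link_rotations optional list of 7 rotation matrices (default all
#'   identity).
#' @param name text label.
#' @return An object of class `robot_params`.
#' @seealso [default_robot_params()] for the shipped 7-DoF default model.
#' @export
robot_params <- function(link_translations, joint_axes, flange_offset,
                         link_rotations = NULL, name = "custom") {
  if (length(link_translations) != 7L || length(joint_axes) != 7L) {
    stop("a 7-DoF chain requires 7 link translations and 7 joint axes",
         call. = FALSE)
  }
  joint_axes <- lapply(joint_axes, function(a) {
    a <- as.numeric(a)
    n <- sqrt(sum(a^2))
    if (!isTRUE(all.equal(n, 1, tolerance = 1e-8))) {
      stop("joint axes must have unit norm", call. = FALSE)
    }
    a / n
  })
  if (is.null(link_rotations)) {
    link_rotations <- replicate(7, diag(3), simplify = FALSE)
  }
  structure(list(joint_count = 7L,
                 link_translations = lapply(link_translations, as.numeric),
                 link_rotations = link_rotations,
                 joint_axes = joint_axes,
                 flange_offset = as.numeric(flange_offset),
                 name = name),
            class = "robot_params")
}

#' Default 7-DoF manipulator geometry
#'
#' A lightweight-collaborative-class arm ("default model"): seven revolute
#' joints with alternating Z/Y local axes and vertical link offsets
#' d = (0.34, 0, 0.4, 0, 0.4, 0, 0) m plus a 0.126 m flange offset, i.e. an
#' iiwa-style chain with all joints at zero giving an upright arm of reach
#' 1.266 m.  All downstream computations read the geometry from this object;
#' nothing is hard-coded elsewhere.
#'
#' @return A `robot_params` object.
#' @export
default_robot_params <- function() {
  d <- c(0.34, 0, 0.40, 0, 0.40, 0, 0)
  robot_params(
    link_translations = lapply(d, function(z) c(0, 0, z)),
    joint_axes = list(c(0, 0, 1), c(0, 1, 0), c(0, 0, 1), c(0, 1, 0),
                      c(0, 0, 1), c(0, 1, 0), c(0, 0, 1)),
    flange_offset = c(0, 0, 0.126),
    name = "default 7-DoF model"
  )
}

#' Read robot parameters from a YAML config file
#'
#' Expected structure: a top-level `robot` section with `link_translations`
#' (list of 7 length-3 numeric lists), `joint_axes` (idem), `flange_offset`
#' (length-3), and optional `name`.
#'
#' @param path path to a YAML file.
#' @return A `robot_params` object.
#' @export
robot_params_from_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  r <- cfg$robot
  if (is.null(r)) stop("config has no 'robot' section", call. = FALSE)
  robot_params(
    link_translations = lapply(r$link_translations, as.numeric),
    joint_axes = lapply(r$joint_axes, as.numeric),
    flange_offset = as.numeric(r$flange_offset),
    name = if (is.null(r$name)) "config" else r$name
  )
}

check_q <- function(q) {
  q <- as.numeric(q)
  if (length(q) != 7L || !all(is.finite(q))) {
    stop("q must be a finite numeric 7-vector of joint angles (rad)",
         call. = FALSE)
  }
  q
}

# Poses of every joint frame plus the flange: list of rigid_transforms
# (length 8, elements 1..7 are the frames *after* each joint rotation).
chain_poses <- function(q, params) {
  q <- check_q(q)
  poses <- vector("list", 8L)
  tf <- rigid_transform()
  for (i in 1:7) {
    link <- rigid_transform(params$link_rotations[[i]],
                            params$link_translations[[i]])
    tf <- rt_compose(tf, link)
    tf <- rt_compose(tf, rigid_transform(
      rot_axis_angle(params$joint_axes[[i]], q[i]), c(0, 0, 0)))
    poses[[i]] <- tf
  }
  poses[[8L]] <- rt_compose(tf, rigid_transform(diag(3), params$flange_offset))
  poses
}

#' Forward kinematics of the 7-DoF arm
#'
#' Returns the pose of the flange frame in the robot world frame (right-
#' handed, Z vertical up) for a given joint configuration.
#'
#' @param q numeric 7-vector of joint angles (rad).
#' @param params a `robot_params` object.
#' @return A `rigid_transform` (flange pose `T_F`).
#' @export
forward_kinematics <- function(q, params = default_robot_params()) {
  chain_poses(q, params)[[8L]]
}

#' Geometric Jacobian of the flange
#'
#' 6x7 matrix in world axes: rows 1-3 map joint rates to flange linear
#' velocity, rows 4-6 to angular velocity.  Column i is
#' `(z_i x (p_flange - p_i); z_i)` with `z_i` the world-frame axis of joint i
#' and `p_i` its origin.
#'
#' @inheritParams forward_kinematics
#' @return 6x7 numeric matrix.
#' @export
jacobian <- function(q, params = default_robot_params()) {
  poses <- chain_poses(q, params)
  pf <- poses[[8L]]$translation
  jac <- matrix(0, 6, 7)
  for (i in 1:7) {
    zi <- as.numeric(poses[[i]]$rotation %*% params$joint_axes[[i]])
    pi_ <- poses[[i]]$translation
    jac[1:3, i] <- cross3(zi, pf - pi_)
    jac[4:6, i] <- zi
  }
  jac
}

#' External wrench at the flange from external joint torques
#'
#' Inverts the virtual-work relation `tau_e = t(J) %*% f`: returns the
#' least-squares wrench `f = pinv(t(J)) %*% tau_e` applied to the flange by
#' the environment, expressed in world axes about the flange origin.  The
#' pseudo-inverse is Moore-Penrose via SVD with singular values below
#' `1e-10 * sigma_max` truncated.  At a singular configuration
#' (rank(J) < 6) the result carries a `singular` attribute set to `TRUE`.
#'
#' @inheritParams forward_kinematics
#' @param tau_e numeric 7-vector of external joint torques (N m).
#' @return A `wrench` object: `list(force, moment, frame = "world")`, force
#'   in N and moment in N m about the flange origin.
#' @export
external_wrench <- function(q, tau_e, params = default_robot_params()) {
  tau_e <- as.numeric(tau_e)
  if (length(tau_e) != 7L || !all(is.finite(tau_e))) {
    stop("tau_e must be a finite numeric 7-vector (N m)", call. = FALSE)
  }
  jt <- t(jacobian(q, params))          # 7 x 6
  sv <- svd(jt)
  tol <- 1e-10 * max(sv$d)
  keep <- sv$d > tol
  singular <- sum(keep) < 6L
  dinv <- ifelse(keep, 1 / sv$d, 0)
  f <- as.numeric(sv$v %*% (dinv * (t(sv$u) %*% tau_e)))
  w <- wrench(force = f[1:3], moment = f[4:6])
  attr(w, "singular") <- singular
  if (singular) {
    warning("Jacobian rank < 6: wrench recovered at a singular configuration",
            call. = FALSE)
  }
  w
}

#' Construct a wrench
#'
#' A force/moment pair in world axes, applied at the flange origin.
#'
#' @param force numeric 3-vector (N).
#' @param moment numeric 3-vector (N m).
#' @param frame frame tag (always `"world"` in this package).
#' @return An object of class `wrench`.
#' @export
wrench <- function(force, moment, frame = "world") {
  force <- as.numeric(force); moment <- as.numeric(moment)
  stopifnot(length(force) == 3L, length(moment) == 3L,
            all(is.finite(force)), all(is.finite(moment)))
  structure(list(force = force, moment = moment, frame = frame),
            class = "wrench")
}

#' @export
print.wrench <- function(x, ...) {
  cat(sprintf("<wrench [%s]> F = (%.4g, %.4g, %.4g) N, M = (%.4g, %.4g, %.4g) N m\n",
              x$frame, x$force[1], x$force[2], x$force[3],
              x$moment[1], x$moment[2], x$moment[3]))
  invisible(x)
}
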