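# Quasi-static extraction of the shoulder passive torque from the flange
# wrench and geometry, with external-torque smoothing and orthosis gravity
# compensation.
#
# Force balance on the limb: F_s + F_R + G = 0.
# Moment balance about the shoulder centre: M_s + M_R + M_G + M_FR = 0,
# with M_FR = (p_flange - center) x F_R.  The passive torque is
# M_P = M_s + M_G = -M_R - M_FR.  All wrenches handled here are the wrench
# the limb applies to the flange (the output of external_wrench); the robot
# assist wrench (F_R, M_R) is its reaction.

GRAVITY <- 9.81  # m s^-2

#' Centred moving average with symmetric edge shrinking
#'
#' Smooths each column of a series with a centred window of odd length.
#' Near the ends the window shrinks symmetrically to the largest centred
#' window that fits, so output length equals input length and no phase lag
#' is introduced.
#'
#' @param series numeric vector or matrix (samples in rows).
#' @param window odd positive integer window length in samples.
#' @return smoothed series, same shape as the input.
#' @export
moving_average <- function(series, window) {
  if (!is.numeric(window) || length(window) != 1L || window < 1 ||
      window %% 2 == 0) {
    stop("window must be a positive odd integer", call. = FALSE)
  }
  vec <- !is.matrix(series)
  x <- if (vec) matrix(series, ncol = 1) else series
  n <- nrow(x)
  if (n == 0L) stop("series must be nonempty", call. = FALSE)
  h <- (window - 1) / 2
  cs <- apply(x, 2, function(col) cumsum(c(0, col)))
  cs <- matrix(cs, nrow = n + 1)
  out <- x
  for (i in seq_len(n)) {
    hi <- min(h, i - 1, n - i)
    out[i, ] <- (cs[i + hi + 1, ] - cs[i - hi, ]) / (2 * hi + 1)
  }
  if (vec) as.numeric(out) else out
}

#' Orthosis parameters
#'
#' Mass and centre of mass (in flange coordinates) of the orthosis rigidly
#' mounted on the flange; both determined in advance of a session.
#'
#' @param mass orthosis mass (kg), `>= 0`.
#' @param com_in_flange numeric 3-vector (m): centre of mass in the flange
#'   frame.
#' @return An object of class `orthosis_params`.
#' @export
orthosis_params <- function(mass = 0, com_in_flange = c(0, 0, 0)) {
  stopifnot(is.numeric(mass), length(mass) == 1L, mass >= 0)
  structure(list(mass = mass, com_in_flange = as.numeric(com_in_flange)),
            class = "orthosis_params")
}

#' Remove the orthosis gravity contribution from a measured wrench
#'
#' The orthosis hangs from the flange, so its weight `(0, 0, -m g)` and the
#' moment of that weight about the flange origin,
#' `(R_F com_in_flange) x (0, 0, -m g)`, appear in the measured interaction
#' wrench and are subtracted here.
#'
#' @param wrench a `wrench` (limb-plus-orthosis wrench on the flange, world
#'   axes, about the flange origin).
#' @param flange_pose `rigid_transform` of the flange.
#' @param orthosis an `orthosis_params`.
#' @return the compensated `wrench`.
#' @export
compensate_orthosis <- function(wrench, flange_pose, orthosis) {
  w_orth <- c(0, 0, -orthosis$mass * GRAVITY)
  arm <- as.numeric(flange_pose$rotation %*% orthosis$com_in_flange)
  wrench(force = wrench$force - w_orth,
         moment = wrench$moment - cross3(arm, w_orth),
         frame = wrench$frame)
}

#' Shoulder passive torque from the compensated flange wrench
#'
#' With the interaction wrench the limb applies to the flange (force `F`,
#' moment `M` about the flange origin, both world axes), the robot assist
#' wrench is `F_R = -F`, `M_R = -M`, its moment about the shoulder centre is
#' `M_FR = (p_flange - center) x F_R`, and the passive torque is
#' `M_P = -M_R - M_FR` -- equivalently the limb-applied wrench moment
#' transported to the shoulder centre.  Reported in world axes.
#'
#' @param wrench orthosis-compensated `wrench` (limb on flange).
#' @param flange_pose `rigid_transform` of the flange.
#' @param center numeric 3-vector (m): shoulder rotation centre in world.
#' @return numeric 3-vector `M_P` (N m, world axes).
#' @export
passive_torque <- function(wrench, flange_pose, center) {
  f_r <- -wrench$force
  m_r <- -wrench$moment
  m_fr <- cross3(flange_pose$translation - as.numeric(center), f_r)
  -m_r - m_fr
}

#' Passive-torque time series from a robot log
#'
#' Runs the statics stage over a full log: smooths the external joint
#' torques with a centred moving average (filtering precedes wrench
#' recovery), recovers the flange wrench per sample, removes the orthosis
#' gravity, and transports the result to the shoulder centre.  Samples whose
#' flange speed exceeds `speed_limit` are flagged as violating the
#' quasi-static assumption (`quasistatic = FALSE`) but are not dropped.
#'
#' @param log robot log `data.frame` with columns `t`, `q1..q7`,
#'   `tau_e1..tau_e7`.
#' @param posture output of [posture_series()] for the same log.
#' @param orthosis an `orthosis_params`.
#' @param params a `robot_params`.
#' @param window moving-average window (odd samples); default 25 (0.5 s at
#'   50 Hz).
#' @param speed_limit quasi-static flange-speed gate (m/s); default 0.1.
#' @return `data.frame` of passive-torque samples: `t`,
#'   `plane_of_elevation`, `elevation`, `mp_x`, `mp_y`, `mp_z`,
#'   `quasistatic`.
#' @export
torque_series <- function(log, posture, orthosis = orthosis_params(),
                          params = default_robot_params(), window = 25,
                          speed_limit = 0.1) {
  qcols <- paste0("q", 1:7)
  taucols <- paste0("tau_e", 1:7)
  n <- nrow(log)
  tau <- moving_average(as.matrix(log[, taucols]), window)
  mp <- matrix(NA_real_, n, 3)
  pf <- matrix(NA_real_, n, 3)
  for (i in seq_len(n)) {
    q <- as.numeric(log[i, qcols])
    tf <- forward_kinematics(q, params)
    pf[i, ] <- tf$translation
    w <- suppressWarnings(external_wrench(q, tau[i, ], params))
    w <- compensate_orthosis(w, tf, orthosis)
    mp[i, ] <- passive_torque(w, tf, posture$fit$center)
  }
  dt <- diff(log$t)
  speed <- c(0, sqrt(rowSums(diff(pf)^2)) / pmax(dt, .Machine$double.eps))
  data.frame(
    t = log$t,
    plane_of_elevation = posture$postures$plane_of_elevation,
    elevation = posture$postures$elevation,
    mp_x = mp[, 1], mp_y = mp[, 2], mp_z = mp[, 3],
    quasistatic = speed <= speed_limit
  )
}

#' Repeatability check between two runs of the same trajectory
#'
#' The protocol repeats each trajectory twice; if the two torque profiles
#' differ substantially the recording is invalid.  Both runs are resampled
#' by linear interpolation onto a common elevation grid over their
#' overlapping elevation range; the metric is the RMS torque difference
#' (pooled over the three components) normalized by the pooled torque range.
#'
#' @param run1,run2 passive-torque `data.frame`s from [torque_series()].
#' @param tol pass threshold on the normalized metric; default 0.1.
#' @param n_grid number of grid points for resampling.
#' @return list with `metric` (normalized RMS difference), `pass` (logical),
#'   `tol`.
#' @export
repeatability_check <- function(run1, run2, tol = 0.1, n_grid = 100L) {
  lo <- max(min(run1$elevation), min(run2$elevation))
  hi <- min(max(run1$elevation), max(run2$elevation))
  if (!(hi > lo)) {
    stop("runs have non-overlapping posture ranges; cannot compare",
         call. = FALSE)
  }
  grid <- seq(lo, hi, length.out = n_grid)
  comp <- c("mp_x", "mp_y", "mp_z")
  interp <- function(run, col) {
    stats::approx(run$elevation, run[[col]], xout = grid, ties = mean)$y
  }
  diffs <- unlist(lapply(comp, function(cn) interp(run1, cn) - interp(run2, cn)))
  pooled <- c(as.matrix(run1[, comp]), as.matrix(run2[, comp]))
  rng <- diff(range(pooled))
  rms <- sqrt(mean(diffs^2))
  metric <- if (rng > 0) rms / rng else if (rms > 0) Inf else 0
  list(metric = metric, pass = metric <= tol, tol = tol)
}
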