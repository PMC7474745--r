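# Shared oracles and fixtures, all built in code.

# Central finite-difference Jacobian of the flange pose: independent oracle
# for the analytic geometric Jacobian.
fd_jacobian <- function(q, params, h = 1e-6) {
  jac <- matrix(0, 6, 7)
  r0 <- forward_kinematics(q, params)$rotation
  for (i in 1:7) {
    qp <- q; qp[i] <- qp[i] + h
    qm <- q; qm[i] <- qm[i] - h
    tp <- forward_kinematics(qp, params)
    tm <- forward_kinematics(qm, params)
    jac[1:3, i] <- (tp$translation - tm$translation) / (2 * h)
    w <- (tp$rotation - tm$rotation) %*% t(r0) / (2 * h)
    jac[4:6, i] <- c(w[3, 2], w[1, 3], w[2, 1])
  }
  jac
}

# Points on (or near) a sphere, deterministic under seed.
sphere_points <- function(n, center, radius, noise_sd = 0, seed = 1) {
  set.seed(seed)
  u <- matrix(rnorm(3 * n), n, 3)
  u <- u / sqrt(rowSums(u^2))
  pts <- sweep(radius * u, 2, center, `+`)
  if (noise_sd > 0) pts <- pts + matrix(rnorm(3 * n, 0, noise_sd), n, 3)
  pts
}

# Independent iterative geometric sphere fit: minimizes the sum of squared
# point-to-surface distances with a general-purpose optimizer (never the
# package's own algebraic path).
geometric_sphere_fit <- function(pts) {
  obj <- function(par) {
    d <- sqrt(rowSums(sweep(pts, 2, par[1:3])^2))
    sum((d - par[4])^2)
  }
  start <- c(colMeans(pts), mean(sqrt(rowSums(sweep(pts, 2, colMeans(pts))^2))))
  fit <- optim(start, obj, method = "BFGS",
               control = list(maxit = 500, reltol = 1e-14))
  list(center = fit$par[1:3], radius = fit$par[4])
}

# The standard scene and its pipeline products are expensive (~10 s); build
# once per test run and share.
.scene_cache <- new.env(parent = emptyenv())

cached_standard_scene <- function() {
  if (is.null(.scene_cache$scene)) {
    .scene_cache$scene <- standard_scene(seed = 1)
  }
  .scene_cache$scene
}

cached_pipeline_result <- function() {
  if (is.null(.scene_cache$result)) {
    sc <- cached_standard_scene()
    .scene_cache$result <- suppressMessages(
      run_pipeline(sc$logs, sc$calib, seed = 1))
  }
  .scene_cache$result
}

# A small noiseless robot-level scene for fast unit tests.
small_robot_scene <- function(n = 60, plane = 0, seed = 3, noise_sd = 0) {
  traj <- generate_trajectory(trajectory_spec(
    plane_of_elevation = plane, n_samples = n, seed = seed))
  render_robot_log(traj, noise_sd = noise_sd, seed = seed)
}
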