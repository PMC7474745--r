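# Sphere fitting, calibration, and the globographic angle decomposition.

test_that("algebraic sphere fit is exact on noiseless data", {
  pts <- sphere_points(100, c(0.10, -0.20, 0.30), 0.25)
  fit <- fit_sphere(pts)
  expect_lt(max(abs(fit$center - c(0.10, -0.20, 0.30))), 1e-9)
  expect_lt(abs(fit$radius - 0.25), 1e-9)
  expect_lt(fit$rms_residual, 1e-9)
  expect_identical(fit$n_points, 100L)
})

test_that("sphere fit degrades gracefully and rejects degenerate input", {
  expect_error(fit_sphere(matrix(rnorm(9), 3, 3)), "at least 4")
  coplanar <- cbind(matrix(runif(8), 4, 2), 0)
  expect_error(fit_sphere(coplanar), "degenerate")
})

test_that("noisy sphere fit recovers the centre within 5 mm at n = 500", {
  # points on a cap (not the full sphere), 1 mm isotropic noise
  set.seed(21)
  e <- runif(500, 10, 120) * pi / 180
  p <- runif(500, -0.3, 0.8)
  u <- t(mapply(globographic_direction, p, e))
  pts <- sweep(0.25 * u, 2, c(0.1, -0.2, 0.3), `+`) +
    matrix(rnorm(1500, 0, 0.001), 500, 3)
  fit <- fit_sphere(pts)
  expect_lt(sqrt(sum((fit$center - c(0.1, -0.2, 0.3))^2)), 0.005)
  # cross-check against the independent iterative geometric fit
  geo <- geometric_sphere_fit(pts)
  expect_lt(sqrt(sum((fit$center - geo$center)^2)), 0.001)
  expect_lt(abs(fit$radius - geo$radius), 0.001)
  # centre error shrinks with n on full-sphere data
  errs <- vapply(c(50, 500, 5000), function(n) {
    f <- fit_sphere(sphere_points(n, c(0, 0, 0.5), 0.3, noise_sd = 0.001,
                                  seed = n))
    sqrt(sum((f$center - c(0, 0, 0.5))^2))
  }, 0)
  expect_true(errs[3] < errs[1])
})

test_that("radial projection onto the sphere behaves as a projection", {
  fit <- fit_sphere(sphere_points(50, c(0.1, 0.2, 0.3), 0.25))
  on_sphere <- fit$center + c(fit$radius, 0, 0)
  expect_equal(project_to_sphere(on_sphere, fit), on_sphere,
               tolerance = 1e-9)
  expect_equal(project_to_sphere(fit$center + c(2 * fit$radius, 0, 0), fit),
               fit$center + c(fit$radius, 0, 0), tolerance = 1e-9)
  expect_error(project_to_sphere(fit$center, fit), "undefined")
})

test_that("globographic angles follow the declared convention", {
  fit <- structure(list(center = c(0.5, 0.1, 0.45), radius = 0.3,
                        rms_residual = 0, n_points = 100L),
                   class = "sphere_fit")
  # elbow straight below the centre: the pole
  pole <- globographic_angles(fit$center + c(0, 0, -0.3), fit)
  expect_equal(pole$elevation, 0)
  expect_true(pole$degenerate)
  expect_equal(pole$plane_of_elevation, 0)
  # 90 degree abduction in the coronal (X) plane
  cor90 <- globographic_angles(fit$center + c(0.3, 0, 0), fit)
  expect_equal(cor90$elevation, pi / 2, tolerance = 1e-12)
  expect_equal(cor90$plane_of_elevation, 0, tolerance = 1e-12)
  expect_false(cor90$degenerate)
})

test_that("angle decomposition round-trips and ignores axial rotation", {
  fit <- structure(list(center = c(0, 0, 0), radius = 1,
                        rms_residual = 0, n_points = 100L),
                   class = "sphere_fit")
  set.seed(5)
  for (k in 1:25) {
    plane <- runif(1, -pi + 0.01, pi)
    elev <- runif(1, 0.05, pi - 0.05)
    u <- globographic_direction(plane, elev)
    post <- globographic_angles(u, fit)
    expect_equal(post$plane_of_elevation, plane, tolerance = 1e-9)
    expect_equal(post$elevation, elev, tolerance = 1e-9)
    # rotating the elbow point about the centre-to-elbow axis changes nothing
    r_ax <- rot_axis_angle(u, runif(1, -pi, pi))
    post2 <- globographic_angles(as.numeric(r_ax %*% u), fit)
    expect_equal(post2$plane_of_elevation, plane, tolerance = 1e-9)
    expect_equal(post2$elevation, elev, tolerance = 1e-9)
  }
})

test_that("calibration recovers the scene transform and zeroes the reference", {
  par <- default_robot_params()
  sc <- small_robot_scene(n = 40)
  geom <- scene_geometry()
  calib <- calibrate(sc$reference_axes, geom$radius, par)
  # at the reference pose the shoulder frame must be world-aligned with its
  # origin at the rotation centre
  ts <- shoulder_transform(sc$reference_axes, calib, par)
  expect_lt(max(abs(ts$rotation - diag(3))), 1e-8)
  expect_lt(max(abs(ts$translation - geom$center)), 1e-8)
  # composing with the inverse calibration transform recovers T_F
  tf <- forward_kinematics(sc$reference_axes, par)
  back <- rt_compose(ts, rt_inverse(calib$flange_to_shoulder))
  expect_lt(max(abs(back$rotation - tf$rotation)), 1e-10)
  expect_lt(max(abs(back$translation - tf$translation)), 1e-10)
  # the shoulder origin stays fixed along a rotation-only trajectory
  qcols <- paste0("q", 1:7)
  for (i in c(1, 20, 40)) {
    tsi <- shoulder_transform(as.numeric(sc$log[i, qcols]), calib, par)
    expect_lt(max(abs(tsi$translation - geom$center)), 1e-6)
  }
  expect_error(calibrate(sc$reference_axes, -0.3, par), "positive")
})

test_that("posture recovery from a noiseless robot log matches the truth", {
  par <- default_robot_params()
  sc <- small_robot_scene(n = 50)
  calib <- calibrate(sc$reference_axes, scene_geometry()$radius, par)
  ps <- posture_series(sc$log, calib, par, fit_fraction = 0.7)
  expect_lt(max(abs(ps$fit$center - scene_geometry()$center)), 1e-6)
  expect_lt(abs(ps$fit$radius - scene_geometry()$radius), 1e-6)
  expect_lt(max(abs(ps$postures$elevation - sc$truth$traj$elevation)), 1e-6)
  expect_lt(max(abs(ps$postures$plane_of_elevation -
                      sc$truth$traj$plane_of_elevation)), 1e-5)
})

test_that("fitting the former part beats the full trajectory under drift", {
  # end-stage centre drift: the last 30% of the motion drags the centre
  traj <- generate_trajectory(trajectory_spec(n_samples = 200, seed = 9))
  geom <- scene_geometry(drift = list(fraction = 0.3,
                                      offset = c(0.03, 0.02, -0.02)))
  sc <- render_flange_log(traj, geom = geom)
  former <- fit_sphere(sc$truth$elbow[1:140, ])
  full <- fit_sphere(sc$truth$elbow)
  expect_lt(former$rms_residual, full$rms_residual)
  expect_lt(former$rms_residual, 1e-6)  # pre-drift part is exact
})

test_that("calibration records serialize to JSON and back", {
  par <- default_robot_params()
  sc <- small_robot_scene(n = 20)
  calib <- calibrate(sc$reference_axes, 0.3, par)
  path <- tempfile(fileext = ".json")
  write_calibration_json(calib, path)
  back <- read_calibration_json(path)
  expect_equal(back$flange_to_shoulder$rotation,
               calib$flange_to_shoulder$rotation, tolerance = 1e-12)
  expect_equal(back$reference_axes, calib$reference_axes)
  fit <- fit_sphere(sphere_points(30, c(0.1, 0.2, 0.3), 0.25))
  write_calibration_json(fit, path)
  expect_equal(read_calibration_json(path)$center, fit$center,
               tolerance = 1e-12)
})
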