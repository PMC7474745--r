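# The scene generator: torque field, trajectories, renders, IK.

test_that("torque field vanishes at the neutral posture and obeys statics", {
  field <- torque_field_params()
  expect_equal(torque_field(0, 0, field), rep(0, 3), tolerance = 1e-12)
  expect_equal(torque_field(0.8, 0, field), rep(0, 3), tolerance = 1e-12)
  # gravity-only field at 90 degree abduction: m g l about the horizontal
  # axis normal to the arm
  g_only <- torque_field_params(limb = limb_params(mass = 3.5,
                                                   com_offset = 0.28),
                                k_cubic = 0, k_edge = 0, k_plane = 0,
                                k_axial = 0, bump_amp = c(0, 0))
  mp <- torque_field(0, pi / 2, g_only)
  expect_equal(sqrt(sum(mp^2)), 3.5 * 9.81 * 0.28, tolerance = 1e-12)
  expect_equal(mp[1], 0, tolerance = 1e-12)  # axis normal to the X-Z arm plane
  expect_equal(mp[3], 0, tolerance = 1e-12)
})

test_that("torque field is continuous on a 1 degree grid", {
  field <- torque_field_params()
  e <- seq(10, 120, by = 1) * pi / 180
  mp <- torque_field(rep(0.3, length(e)), e, field)
  step <- max(abs(diff(mp)))
  # Lipschitz estimate from a 10x finer grid
  ef <- seq(10, 120, by = 0.1) * pi / 180
  mpf <- torque_field(rep(0.3, length(ef)), ef, field)
  lip <- max(abs(diff(mpf))) / (0.1 * pi / 180)
  expect_lt(step, lip * (pi / 180) * 1.5)
})

test_that("trajectories ramp monotonically with seeded secondary movement", {
  spec <- trajectory_spec(n_samples = 200, seed = 5)
  tr <- generate_trajectory(spec)
  expect_true(all(diff(tr$elevation) > 0))
  expect_equal(max(abs(tr$plane_of_elevation - spec$plane_of_elevation)),
               spec$secondary_amplitude, tolerance = 1e-9)
  expect_identical(generate_trajectory(spec), tr)
  still <- generate_trajectory(trajectory_spec(secondary_amplitude = 0,
                                               n_samples = 50))
  expect_equal(still$plane_of_elevation, rep(0, 50))
  # 50 Hz timestamps
  expect_equal(diff(tr$t), rep(1 / 50, 199), tolerance = 1e-12)
})

test_that("rendered flange scenes satisfy the balance equations exactly", {
  traj <- generate_trajectory(trajectory_spec(n_samples = 80, seed = 2))
  sc <- render_flange_log(traj)
  tr <- sc$truth
  for (i in seq(1, 80, by = 13)) {
    f_limb <- tr$wrench_limb[i, 1:3]
    m_limb <- tr$wrench_limb[i, 4:6]
    f_r <- -f_limb
    m_r <- -m_limb
    g <- c(0, 0, -tr$field$limb$mass * tr$field$gravity)
    # force balance with the generator's F_s = 0 convention
    expect_lt(max(abs(f_r + g)), 1e-10)
    # moment balance about the centre: M_s + M_R + M_G + M_FR = 0
    m_s <- tr$mp[i, ] - tr$mg[i, ]
    arm <- tr$elbow[i, ] - tr$centers[i, ]
    m_fr <- c(arm[2] * f_r[3] - arm[3] * f_r[2],
              arm[3] * f_r[1] - arm[1] * f_r[3],
              arm[1] * f_r[2] - arm[2] * f_r[1])
    expect_lt(max(abs(m_s + m_r + tr$mg[i, ] + m_fr)), 1e-10)
  }
})

test_that("statics stage recovers the field from a noiseless flange log", {
  traj <- generate_trajectory(trajectory_spec(n_samples = 60, seed = 4))
  orth <- orthosis_params(mass = 0.8, com_in_flange = c(0.01, 0, 0.06))
  sc <- render_flange_log(traj, orthosis = orth)
  worst <- 0
  for (i in seq_len(60)) {
    tf <- rt_unflatten(as.numeric(sc$log[i, paste0("pose", 1:16)]))
    w <- wrench(as.numeric(sc$log[i, c("fx", "fy", "fz")]),
                as.numeric(sc$log[i, c("mx", "my", "mz")]))
    w <- compensate_orthosis(w, tf, orth)
    mp <- passive_torque(w, tf, sc$truth$centers[i, ])
    worst <- max(worst, max(abs(mp - sc$truth$mp[i, ])))
  }
  expect_lt(worst, 1e-6)
})

test_that("numeric IK solves poses the forward kinematics confirms", {
  par <- default_robot_params()
  geom <- scene_geometry()
  target <- rigid_transform(
    rot_z(0.3) %*% rot_y(-1.1) %*% rot_z(-0.3) %*% geom$flange_mount,
    geom$center + geom$radius * globographic_direction(0.3, 1.1))
  q0 <- c(0.2, 0.6, 0.1, -1.4, 0.1, 0.9, 0.1)
  q <- numeric_ik(target, q0, par)
  tf <- forward_kinematics(q, par)
  expect_lt(max(abs(tf$translation - target$translation)), 1e-6)
  expect_lt(max(abs(tf$rotation - target$rotation)), 1e-6)
  expect_identical(numeric_ik(target, q0, par), q)  # deterministic
  out_of_reach <- rigid_transform(diag(3), c(3, 0, 0))
  expect_error(numeric_ik(out_of_reach, q0, par, max_iter = 60),
               "unreachable")
})

test_that("robot-level logs round-trip the wrench through the Jacobian", {
  par <- default_robot_params()
  sc <- small_robot_scene(n = 50, seed = 6)
  qcols <- paste0("q", 1:7)
  taucols <- paste0("tau_e", 1:7)
  for (i in seq(1, 50, by = 9)) {
    w <- external_wrench(as.numeric(sc$log[i, qcols]),
                         as.numeric(sc$log[i, taucols]), par)
    expect_lt(max(abs(c(w$force, w$moment) - sc$truth$wrench_limb[i, ])),
              1e-6)
  }
})

test_that("wrench recovery error scales linearly with torque noise", {
  par <- default_robot_params()
  traj <- generate_trajectory(trajectory_spec(n_samples = 40, seed = 8))
  errs <- vapply(c(0.01, 0.05, 0.1), function(s) {
    sc <- render_robot_log(traj, noise_sd = s, seed = 23)
    qcols <- paste0("q", 1:7)
    taucols <- paste0("tau_e", 1:7)
    e <- vapply(seq_len(40), function(i) {
      w <- external_wrench(as.numeric(sc$log[i, qcols]),
                           as.numeric(sc$log[i, taucols]), par)
      sqrt(sum((c(w$force, w$moment) - sc$truth$wrench_limb[i, ])^2))
    }, 0)
    mean(e)
  }, 0)
  expect_gt(errs[3], errs[1])
  # same noise realization scaled: the ratio is close to the sigma ratio
  expect_equal(errs[3] / errs[1], 10, tolerance = 0.15)
})

test_that("renders are reproducible and pass the repeatability gate", {
  par <- default_robot_params()
  traj <- generate_trajectory(trajectory_spec(n_samples = 40, seed = 13))
  a <- render_robot_log(traj, noise_sd = 0.05, seed = 31)
  b <- render_robot_log(traj, noise_sd = 0.05, seed = 31)
  expect_identical(a$log, b$log)
  calib <- calibrate(a$reference_axes, scene_geometry()$radius, par)
  ps <- posture_series(a$log, calib, par)
  tq <- torque_series(a$log, ps, params = par, window = 5)
  chk <- repeatability_check(tq, tq)
  expect_equal(chk$metric, 0)
  expect_true(chk$pass)
})

test_that("robot logs survive the CSV round trip", {
  sc <- small_robot_scene(n = 10)
  path <- tempfile(fileext = ".csv")
  write_robot_log(sc$log, path)
  back <- read_robot_log(path)
  expect_equal(back$q3, sc$log$q3, tolerance = 1e-12)
  expect_equal(back$tau_e5, sc$log$tau_e5, tolerance = 1e-12)
  expect_error(read_robot_log(textConnection("a,b\n1,2")), "columns")
})
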