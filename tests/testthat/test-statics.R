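# Smoothing, orthosis compensation, passive-torque extraction, repeatability.

test_that("moving average: identity on constants, plateau on impulses", {
  expect_equal(moving_average(rep(3.5, 40), 7), rep(3.5, 40))
  n <- 41
  imp <- rep(0, n); imp[21] <- 1
  sm <- moving_average(imp, 5)
  expect_equal(sm[19:23], rep(1 / 5, 5))
  expect_equal(sm[c(1:16, 26:41)], rep(0, 32))
  expect_error(moving_average(1:10, 4), "odd")
  expect_error(moving_average(1:10, -3), "odd")
})

test_that("moving average attenuates a sinusoid by the Dirichlet kernel", {
  f <- 0.05  # cycles per sample
  w <- 9
  n <- 400
  x <- sin(2 * pi * f * seq_len(n))
  sm <- moving_average(x, w)
  gain <- abs(sin(pi * f * w) / (w * sin(pi * f)))
  interior <- 50:350
  fit <- lm(sm[interior] ~ x[interior] + 0)
  expect_equal(unname(coef(fit)[1]), gain, tolerance = 1e-3)
})

test_that("moving average on matrices smooths each column and keeps length", {
  m <- cbind(a = rnorm(30), b = rnorm(30))
  sm <- moving_average(m, 5)
  expect_identical(dim(sm), dim(m))
  expect_equal(sm[, 1], moving_average(m[, 1], 5))
})

test_that("orthosis compensation removes exactly the orthosis weight", {
  tf <- rigid_transform(rot_y(-0.8) %*% rot_z(0.3), c(0.4, 0.1, 0.3))
  orth <- orthosis_params(mass = 1.2, com_in_flange = c(0.02, -0.01, 0.10))
  w <- wrench(c(1, 2, 3), c(0.1, 0.2, 0.3))
  # zero mass: no change
  w0 <- compensate_orthosis(w, tf, orthosis_params(mass = 0))
  expect_equal(w0$force, w$force)
  expect_equal(w0$moment, w$moment)
  # a scene containing only the hanging orthosis compensates to zero
  g <- c(0, 0, -orth$mass * 9.81)
  arm <- as.numeric(tf$rotation %*% orth$com_in_flange)
  w_orth_only <- wrench(g, c(arm[2] * g[3] - arm[3] * g[2],
                             arm[3] * g[1] - arm[1] * g[3],
                             arm[1] * g[2] - arm[2] * g[1]))
  wc <- compensate_orthosis(w_orth_only, tf, orth)
  expect_lt(max(abs(c(wc$force, wc$moment))), 1e-9)
  # the moment changes by exactly (R com) x (0, 0, -m g)
  wg <- compensate_orthosis(w, tf, orth)
  expect_equal(w$moment - wg$moment,
               c(arm[2] * g[3] - arm[3] * g[2],
                 arm[3] * g[1] - arm[1] * g[3],
                 arm[1] * g[2] - arm[2] * g[1]), tolerance = 1e-12)
})

test_that("passive torque recovers a constructed static equilibrium", {
  # hand-built scene: known M_P and limb weight, robot closes the balance
  center <- c(0.5, 0.0, 0.4)
  p_f <- center + 0.3 * globographic_direction(0.2, 1.1)
  tf <- rigid_transform(diag(3), p_f)
  g <- c(0, 0, -3.5 * 9.81)
  mp_true <- c(0.8, -4.2, 1.1)
  f_r <- -g
  m_r <- -mp_true - c((p_f - center)[2] * f_r[3] - (p_f - center)[3] * f_r[2],
                      (p_f - center)[3] * f_r[1] - (p_f - center)[1] * f_r[3],
                      (p_f - center)[1] * f_r[2] - (p_f - center)[2] * f_r[1])
  w_limb <- wrench(-f_r, -m_r)
  expect_lt(max(abs(passive_torque(w_limb, tf, center) - mp_true)), 1e-9)
  # zero wrench: massless, resistance-free limb
  expect_equal(passive_torque(wrench(rep(0, 3), rep(0, 3)), tf, center),
               rep(0, 3))
  # force-balance companion: the limb transmits its weight to the flange,
  # so F_s = -F_R - G = 0 under the generator's convention
  expect_equal(w_limb$force, g)
})

test_that("passive torque is frame-covariant", {
  r <- rot_z(0.7) %*% rot_x(-0.3)
  center <- c(0.5, 0.1, 0.4)
  tf <- rigid_transform(rot_y(-0.9), center + c(0.2, 0.05, -0.18))
  w <- wrench(c(2, -1, 34), c(0.5, 1.2, -0.8))
  mp <- passive_torque(w, tf, center)
  # rotate the whole scene
  tf_r <- rigid_transform(r %*% tf$rotation, as.numeric(r %*% tf$translation))
  w_r <- wrench(as.numeric(r %*% w$force), as.numeric(r %*% w$moment))
  mp_r <- passive_torque(w_r, tf_r, as.numeric(r %*% center))
  expect_equal(mp_r, as.numeric(r %*% mp), tolerance = 1e-12)
})

test_that("repeatability gate: identical runs pass, offset runs fail", {
  run <- data.frame(t = seq(0, 1, length.out = 50),
                    elevation = seq(0.2, 2.0, length.out = 50),
                    mp_x = sin(seq(0, 3, length.out = 50)),
                    mp_y = seq(-2, 5, length.out = 50),
                    mp_z = rep(0.5, 50))
  same <- repeatability_check(run, run)
  expect_equal(same$metric, 0)
  expect_true(same$pass)
  shifted <- run
  shifted[, c("mp_x", "mp_y", "mp_z")] <-
    shifted[, c("mp_x", "mp_y", "mp_z")] + 2
  bad <- repeatability_check(run, shifted, tol = 0.1)
  expect_false(bad$pass)
  # symmetry
  expect_equal(repeatability_check(run, shifted)$metric,
               repeatability_check(shifted, run)$metric, tolerance = 1e-12)
  # disjoint posture ranges cannot be compared
  apart <- run
  apart$elevation <- apart$elevation + 5
  expect_error(repeatability_check(run, apart), "non-overlapping")
})

test_that("filtering precedes wrench recovery in the torque series", {
  # with noise on tau, smoothing inside torque_series must match smoothing
  # the log by hand first and running with window 1
  par <- default_robot_params()
  sc <- small_robot_scene(n = 40, noise_sd = 0.3, seed = 12)
  calib <- calibrate(sc$reference_axes, scene_geometry()$radius, par)
  ps <- posture_series(sc$log, calib, par)
  tq <- torque_series(sc$log, ps, params = par, window = 11)
  log_pre <- sc$log
  taucols <- paste0("tau_e", 1:7)
  log_pre[, taucols] <- moving_average(as.matrix(sc$log[, taucols]), 11)
  tq_pre <- torque_series(log_pre, ps, params = par, window = 1)
  expect_equal(tq$mp_x, tq_pre$mp_x, tolerance = 1e-10)
  expect_equal(tq$mp_z, tq_pre$mp_z, tolerance = 1e-10)
})
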