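test_that("zero-lag filter preserves DC and has the designed roll-off", {
  rate <- 100
  t <- (0:499) / rate
  expect_lt(max(abs(filter_signal(rep(3.7, 500), rate, 6) - 3.7)), 1e-6)
  # 1 Hz passes a 6 Hz cutoff with < 1% attenuation
  lo <- filter_signal(sin(2 * pi * 1 * t), rate, 6)
  expect_gt(max(lo[100:400]), 0.99)
  # 40 Hz is attenuated by > 99%
  hi <- filter_signal(sin(2 * pi * 40 * t), rate, 6)
  expect_lt(max(abs(hi[100:400])), 0.01)
  expect_error(filter_signal(t, rate, 50), "Nyquist")
  expect_error(filter_signal(t, rate, -1), "positive")
})

test_that("finite differences are exact on polynomials and accurate on sines", {
  dt <- 0.01
  t <- seq(0, 1, by = dt)
  expect_equal(differentiate(rep(5, 50), dt), rep(0, 50))
  # second derivative of t^2 is exactly 2 (stencil exact for quadratics)
  d2 <- differentiate(t^2, dt, order = 2)
  expect_lt(max(abs(d2 - 2)), 1e-9)
  # sine derivative error < 0.1% of amplitude at interior points
  d1 <- differentiate(sin(2 * pi * t), dt)
  truth <- 2 * pi * cos(2 * pi * t)
  interior <- 3:(length(t) - 2)
  expect_lt(max(abs(d1[interior] - truth[interior])) / (2 * pi), 1e-3)
  expect_error(differentiate(c(1, 2), dt), "3 samples")
  expect_error(differentiate(t, dt, order = 3), "order")
})

test_that("gait events are detected at sustained threshold crossings", {
  rate <- 1000
  t <- (0:999) / rate
  # single stance from 0.1 s to 0.7 s
  fz <- ifelse(t >= 0.1 & t <= 0.7, 400 * sin(pi * (t - 0.1) / 0.6) + 50, 0)
  fp <- forceplate_record(cbind(0, fz, 0), matrix(0, 1000, 3),
                          matrix(0, 1000, 3), rate = rate)
  ev <- detect_gait_events(fp, threshold = 20, marker_rate = 100)
  expect_length(ev$heel_strike, 1)
  expect_length(ev$toe_off, 1)
  expect_lt(abs(ev$heel_strike - 0.1), 0.01)
  expect_lt(abs(ev$toe_off - 0.7), 0.01)
  # 5 ms chatter below threshold inside stance is debounced away
  fz2 <- fz; fz2[300:304] <- 0
  fp2 <- forceplate_record(cbind(0, fz2, 0), matrix(0, 1000, 3),
                           matrix(0, 1000, 3), rate = rate)
  ev2 <- detect_gait_events(fp2, threshold = 20)
  expect_length(ev2$heel_strike, 1)
  # degenerate inputs: no force, or threshold above the peak
  fp0 <- forceplate_record(matrix(0, 100, 3), matrix(0, 100, 3),
                           matrix(0, 100, 3), rate = rate)
  expect_warning(ev0 <- detect_gait_events(fp0), "no threshold")
  expect_length(ev0$heel_strike, 0)
  expect_warning(ev3 <- detect_gait_events(fp, threshold = 1e5), "no threshold")
  expect_length(ev3$heel_strike, 0)
})

test_that("rigid fits recover exact poses and match the quaternion oracle", {
  set.seed(11)
  local <- matrix(runif(15, -0.2, 0.2), 5, 3)
  # identity
  fit0 <- fit_rigid_transform(local, local)
  expect_lt(max(abs(fit0$rotation - diag(3))), 1e-12)
  expect_lt(max(abs(fit0$origin)), 1e-12)
  # exact rigid motion is recovered to machine precision
  R <- oagait:::rot_z(30 * pi / 180)
  world <- local %*% t(R) + matrix(c(0.3, -0.2, 0.5), 5, 3, byrow = TRUE)
  fit <- fit_rigid_transform(local, world)
  expect_lt(max(abs(fit$rotation - R)), 1e-9)
  expect_lt(max(abs(fit$origin - c(0.3, -0.2, 0.5))), 1e-9)
  # noisy cluster: SVD fit agrees with Horn's quaternion oracle and the
  # orientation error on a 0.4 m cluster with 1 mm noise stays below 1 degree
  local_big <- matrix(runif(30, -0.2, 0.2), 10, 3)
  for (rep in 1:5) {
    noisy <- local_big %*% t(R) + matrix(rnorm(30, 0, 0.001), 10, 3)
    fit_n <- fit_rigid_transform(local_big, noisy)
    R_quat <- quat_procrustes_rotation(local_big, noisy)
    expect_lt(oagait:::rotation_angle_between(fit_n$rotation, R_quat), 1e-6)
    expect_lt(oagait:::rotation_angle_between(fit_n$rotation, R), 1 * pi / 180)
  }
  # collinear clusters are rejected
  collinear <- cbind(seq(0, 1, length.out = 4), 0, 0)
  expect_error(fit_rigid_transform(collinear, collinear), "collinear")
})

test_that("joint angle decomposition round-trips through the rotation", {
  set.seed(21)
  for (i in 1:20) {
    abc <- runif(3, -1.2, 1.2)
    R <- oagait:::euler_zxy_to_rot(abc)
    back <- oagait:::euler_zxy(R)
    expect_equal(back, abc, tolerance = 1e-9)
    expect_lt(max(abs(oagait:::euler_zxy_to_rot(back) - R)), 1e-9)
  }
  # identical poses give zero angles; a pure flexion-axis rotation maps to
  # (flexion, 0, 0)
  expect_equal(oagait:::euler_zxy(diag(3)), c(0, 0, 0))
  expect_equal(oagait:::euler_zxy(oagait:::rot_z(0.7)), c(0.7, 0, 0))
})

test_that("angular rates recover prescribed spins and match a quaternion oracle", {
  dt <- 0.01
  n <- 200
  # constant rotation: zero rates
  Rconst <- array(rep(diag(3), each = n), c(n, 3, 3))
  rates0 <- angular_rates_from_rotations(Rconst, dt)
  expect_lt(max(abs(rates0$omega)), 1e-12)
  # uniform 2 rad/s spin about Z
  Rspin <- array(NA_real_, c(n, 3, 3))
  for (f in 1:n) Rspin[f, , ] <- oagait:::rot_z(2 * (f - 1) * dt)
  rates <- angular_rates_from_rotations(Rspin, dt)
  interior <- 3:(n - 2)
  # central-difference truncation error ~ dt^2 * omega^3 / 6 = 1.3e-4
  expect_lt(max(abs(rates$omega[interior, 3] - 2)), 2e-4)
  expect_lt(max(abs(rates$omega[interior, 1:2])), 2e-4)
  expect_lt(max(abs(rates$alpha[interior, ])), 1e-4)
  # wobbling motion: omega agrees with the quaternion-derivative oracle
  Rw <- array(NA_real_, c(n, 3, 3))
  for (f in 1:n) {
    t <- (f - 1) * dt
    Rw[f, , ] <- oagait:::rot_z(1.5 * t) %*% oagait:::rot_x(0.8 * sin(2 * t))
  }
  rates_w <- angular_rates_from_rotations(Rw, dt)
  q <- t(vapply(1:n, function(f) oagait:::rot_to_quat(matrix(Rw[f, , ], 3, 3)),
                numeric(4)))
  # enforce continuity of the quaternion sign before differentiating
  for (f in 2:n) if (sum(q[f, ] * q[f - 1, ]) < 0) q[f, ] <- -q[f, ]
  qd <- differentiate(q, dt)
  for (f in interior) {
    w <- q[f, 1]; v <- q[f, 2:4]
    wd <- qd[f, 1]; vd <- qd[f, 2:4]
    # omega = 2 * (qdot * conj(q))_vec for unit quaternions
    omega_q <- 2 * (w * vd - wd * v + c(v[2]*vd[3]-v[3]*vd[2],
                                        v[3]*vd[1]-v[1]*vd[3],
                                        v[1]*vd[2]-v[2]*vd[1]))
    expect_lt(max(abs(rates_w$omega[f, ] - omega_q)), 1e-8 + 1e-3 * max(abs(omega_q)))
  }
})

test_that("cycle normalization yields 100 points and averages cycles", {
  rate <- 100
  n <- 301
  x <- seq(0, 3, length.out = n)   # linear ramp
  hs <- c(0.5, 1.5, 2.5)
  norm1 <- normalize_cycle(x, rate, hs[1:2])
  expect_equal(nrow(norm1), 100)
  # linear ramp stays linear with preserved endpoints (0% and 99%)
  expected <- seq(0.5, 1.5, length.out = 101)[1:100] / 1   # x(t) = t
  expect_equal(norm1[, 1], expected, tolerance = 1e-9)
  # averaging two identical cycles is idempotent
  norm2 <- normalize_cycle(x, rate, hs)
  expect_equal(attr(norm2, "n_cycles"), 2)
  expect_equal(norm2[, 1], norm1[, 1] + 0.5, tolerance = 1e-9)  # mean of the two shifted ramps
  # matrix input, arbitrary signals: always exactly 100 samples
  xm <- cbind(sin(x), cos(x))
  expect_equal(dim(normalize_cycle(xm, rate, hs)), c(100, 2))
  expect_error(normalize_cycle(x, rate, hs[1]), "complete")
})

test_that("segment poses from synthetic walking recover template joint angles", {
  m <- test_model
  tpl <- gait_template(test_params, marker_noise_sd = 0)
  tr <- generate_trial(m, tpl, seed = 5, n_cycles = 1)
  poses <- compute_segment_poses(tr$markers, m)
  expect_length(poses$bad_frames, 0)
  # orthonormality of every recovered rotation
  for (f in c(1, 50, 100)) {
    for (s in names(poses$segments)) {
      R <- matrix(poses$segments[[s]]$rotation[f, , ], 3, 3)
      expect_lt(max(abs(t(R) %*% R - diag(3))), 1e-9)
    }
  }
  ang <- compute_joint_angles(poses, m)
  nf <- dim(tr$markers$positions)[1]
  phase <- (((seq_len(nf) - 1) / 100) - tr$lead_in) / tr$cycle_time
  for (j in c("knee_r", "hip_r")) {
    nm <- if (j == "knee_r") "knee_flexion" else "hip_flexion"
    truth <- oagait:::eval_fourier(tpl$angles[[nm]], phase %% 1)
    expect_lt(sqrt(mean((ang[[j]][, "flexion"] - truth)^2)), 1e-6)
  }
  # left knee flexion is the half-cycle-shifted template
  truth_l <- oagait:::eval_fourier(tpl$angles$knee_flexion, (phase + 0.5) %% 1)
  expect_lt(sqrt(mean((ang$knee_l[, "flexion"] - truth_l)^2)), 1e-6)
})
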