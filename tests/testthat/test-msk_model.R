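test_that("segment masses conserve subject mass and scale linearly", {
  for (bm in c(45, 58.5, 73.1, 100)) {
    m <- build_scaled_model(bm, params = test_params)
    expect_lt(abs(sum(vapply(m$segments, `[[`, numeric(1), "mass")) - bm), 1e-9)
  }
  m1 <- build_scaled_model(60, params = test_params)
  m2 <- build_scaled_model(120, params = test_params)
  for (s in names(m1$segments)) {
    expect_equal(m2$segments[[s]]$mass, 2 * m1$segments[[s]]$mass)
    expect_equal(m2$segments[[s]]$inertia, 2 * m1$segments[[s]]$inertia)
  }
})

test_that("reference subject reproduces the embedded table exactly", {
  m <- build_scaled_model(test_params$reference$body_mass, params = test_params)
  expect_true(all(m$scale == 1))
  mus_r <- m$muscles[m$muscles$side == "right", ]
  expect_equal(mus_r$ox, test_params$muscles$ox)
  expect_equal(mus_r$iy, test_params$muscles$iy)
  expect_equal(mus_r$pcsa, test_params$muscles$pcsa)
  mk <- m$marker_local
  expect_equal(mk$x, test_params$markers$x)
})

test_that("model construction is deterministic and validates inputs", {
  m1 <- build_scaled_model(58.5, params = test_params)
  m2 <- build_scaled_model(58.5, params = test_params)
  expect_identical(m1$muscles, m2$muscles)
  expect_identical(m1$segments, m2$segments)
  expect_error(build_scaled_model(-1, params = test_params), "positive")
  expect_error(build_scaled_model(60, segment_lengths = list(thigh = 0.4),
                                  params = test_params), "missing for")
  expect_error(build_scaled_model(60,
    segment_lengths = list(pelvis = 0.24, thigh = -0.1, shank = 0.4, foot = 0.24),
    params = test_params), "positive")
})

test_that("inertia tensors are symmetric positive definite", {
  m <- build_scaled_model(70, params = test_params)
  for (s in m$segments) {
    expect_equal(s$inertia, t(s$inertia))
    expect_true(all(eigen(s$inertia, symmetric = TRUE)$values > 0))
  }
})

test_that("muscle group tags are exactly the 4 extensors and 8 flexors", {
  mus <- test_model$muscles
  for (sd in c("right", "left")) {
    ms <- mus[mus$side == sd, ]
    expect_setequal(ms$name[ms$group == "knee_extensor"],
                    c("VINT", "VLAT", "VMED", "RF"))
    expect_setequal(ms$name[ms$group == "knee_flexor"],
                    c("SM", "ST", "BFLH", "BFSH", "GASM", "GASL", "SAR", "GRA"))
  }
  # exactly the 12 tagged muscles cross the knee
  crossing <- test_model$muscles$name[muscles_crossing(test_model, "knee_r")]
  expect_setequal(crossing, c("VINT", "VLAT", "VMED", "RF", "SM", "ST",
                              "BFLH", "BFSH", "GASM", "GASL", "SAR", "GRA"))
})

test_that("maximum isometric force is sigma times PCSA", {
  expect_equal(max_isometric_force(list(pcsa = 10, max_stress = 61)), 610)
  expect_error(max_isometric_force(list(pcsa = 0, max_stress = 61)), "positive")
  expect_error(max_isometric_force(list(pcsa = 10, max_stress = -1)), "positive")
  # halving the stress bound halves fmax and changes the active set of a
  # solution that was interior at the higher bound
  Rm <- matrix(c(0.04, 0.03, 0.05), 1, 3)
  A <- c(10, 6, 1.5)
  sol_hi <- solve_static_optimization(Rm, 18, A, 61 * A)
  sol_lo <- solve_static_optimization(Rm, 18, A, 30.5 * A)
  expect_equal(sol_hi$status, "converged")
  expect_equal(sol_lo$status, "converged")
  at_bound_hi <- sum(sol_hi$forces > 0.999 * 61 * A)
  at_bound_lo <- sum(sol_lo$forces > 0.999 * 30.5 * A)
  expect_equal(at_bound_hi, 0)
  expect_gt(at_bound_lo, 0)
})

test_that("moment arms follow cross-product geometry and isometry invariance", {
  poses <- standing_poses()
  geo <- muscle_line_of_action(test_model, poses, "knee_r")
  expect_false(any(geo$degenerate))
  # |tau| = 1
  expect_true(all(abs(sqrt(geo$tau_x^2 + geo$tau_y^2 + geo$tau_z^2) - 1) < 1e-12))
  # r x tau recomputed independently
  for (k in seq_len(nrow(geo))) {
    r <- c(geo$r_x[k], geo$r_y[k], geo$r_z[k])
    tau <- c(geo$tau_x[k], geo$tau_y[k], geo$tau_z[k])
    m <- c(r[2]*tau[3] - r[3]*tau[2], r[3]*tau[1] - r[1]*tau[3],
           r[1]*tau[2] - r[2]*tau[1])
    expect_equal(unlist(geo[k, c("marm_x", "marm_y", "marm_z")]), m,
                 ignore_attr = TRUE)
  }
  # rigid rotation of the whole body leaves moment-arm magnitudes unchanged
  Rrot <- oagait:::rot_z(0.5) %*% oagait:::rot_y(0.3)
  shift <- c(0.2, -0.1, 0.4)
  poses_rot <- lapply(poses, function(p)
    list(rotation = Rrot %*% p$rotation, origin = as.vector(Rrot %*% p$origin) + shift))
  geo_rot <- muscle_line_of_action(test_model, poses_rot, "knee_r")
  m0 <- sqrt(geo$marm_x^2 + geo$marm_y^2 + geo$marm_z^2)
  m1 <- sqrt(geo_rot$marm_x^2 + geo_rot$marm_y^2 + geo_rot$marm_z^2)
  expect_equal(m0, m1, tolerance = 1e-12)
  # rotated tau equals Rrot %*% tau
  expect_equal(as.matrix(geo_rot[, c("tau_x", "tau_y", "tau_z")]),
               as.matrix(geo[, c("tau_x", "tau_y", "tau_z")]) %*% t(Rrot),
               ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("geometric moment arm matches the tendon-excursion derivative", {
  # 1-DOF toy: flex the right knee by angle q, moment arm about the flexion
  # axis must equal -dL/dq for each knee-crossing muscle
  model <- test_model
  poses0 <- standing_poses()
  knee_c <- joint_centers_world(model, poses0)[["knee_r"]]
  poses_at_q <- function(q) {
    p <- poses0
    Rq <- oagait:::rot_z(-q)   # knee flexion rotates the shank about -Z
    for (s in c("shank_r", "foot_r")) {
      p[[s]]$rotation <- Rq %*% p[[s]]$rotation
      p[[s]]$origin <- as.vector(Rq %*% (p[[s]]$origin - knee_c)) + knee_c
    }
    p
  }
  mus <- model$muscles[muscles_crossing(model, "knee_r"), ]
  for (q in c(0.2, 0.6, 1.0)) {
    p <- poses_at_q(q)
    geo <- muscle_line_of_action(model, p, "knee_r")
    h <- 1e-6
    for (k in seq_len(nrow(mus))) {
      dL <- (oagait:::muscle_length_world(model, poses_at_q(q + h), mus[k, ]) -
             oagait:::muscle_length_world(model, poses_at_q(q - h), mus[k, ])) / (2 * h)
      # with flexion measured about -Z, the tendon-excursion identity reads
      # d(length)/d(flexion) = marm_z (extensors lengthen as the knee flexes)
      arm_z <- geo$marm_z[match(mus$name[k], geo$name)]
      expect_lt(abs(arm_z - dL), 1e-6)
    }
  }
})

test_that("parameter file schema violations are rejected", {
  p <- test_params
  p$muscles <- p$muscles[-1, ]
  expect_error(build_scaled_model(60, params = p), "26 rows")
  p2 <- test_params
  p2$muscles$group[p2$muscles$name == "RF"] <- "other"
  expect_error(build_scaled_model(60, params = p2), "extensor")
  p3 <- test_params
  p3$markers <- p3$markers[-1, ]
  expect_error(build_scaled_model(60, params = p3), "37 rows")
})
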