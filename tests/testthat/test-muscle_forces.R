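test_that("single-muscle single-DOF equality is solved exactly", {
  # one muscle, moment arm 0.04 m, required 20 N m -> F = 500 N
  sol <- solve_static_optimization(matrix(0.04, 1, 1), 20, 10, 1e4)
  expect_equal(sol$status, "converged")
  expect_equal(sol$forces, 500, tolerance = 1e-8)
  expect_equal(sol$activation, 500 / 1e4, tolerance = 1e-8)
})

test_that("identical muscles share load equally by strict convexity", {
  for (nmus in 2:4) {
    Rm <- matrix(0.05, 1, nmus)
    sol <- solve_static_optimization(Rm, 40, rep(12, nmus), rep(700, nmus))
    expect_equal(sol$status, "converged")
    expect_lt(diff(range(sol$forces)), 1e-6 * mean(sol$forces))
    expect_equal(sum(sol$forces) * 0.05, 40, tolerance = 1e-7)
  }
})

test_that("two-muscle solution matches the KKT closed form and a grid oracle", {
  # A1 = 2 A2, equal arms r: stationarity gives F_i = A_i^1.5 sqrt(lambda r/3)
  r <- 0.05; A <- c(8, 4); M <- 30
  sol <- solve_static_optimization(matrix(r, 1, 2), M, A, 61 * A)
  expect_equal(sol$status, "converged")
  # closed form: F1/F2 = (A1/A2)^1.5, scaled to meet the constraint
  ratio <- (A[1] / A[2])^1.5
  F2 <- M / (r * (1 + ratio)); F1 <- ratio * F2
  expect_equal(sol$forces, c(F1, F2), tolerance = 1e-6)
  # the implied multiplier reproduces the stationarity form
  lam <- 3 * F1^2 / A[1]^3 / r
  expect_equal(sol$forces[1], A[1]^1.5 * sqrt(lam * r / 3), tolerance = 1e-7)
  # exhaustive grid search over the feasible line
  f1_grid <- seq(0, M / r, length.out = 20001)
  f2_grid <- (M - r * f1_grid) / r
  ok <- f2_grid >= 0 & f1_grid <= 61 * A[1] & f2_grid <= 61 * A[2]
  obj <- (f1_grid / A[1])^3 + (f2_grid / A[2])^3
  best <- f1_grid[ok][which.min(obj[ok])]
  expect_lt(abs(sol$forces[1] - best), diff(f1_grid[1:2]) + 1e-9)
  # and the solver's objective beats every grid point
  expect_lte(sol$objective, min(obj[ok]) + 1e-9)
})

test_that("three-muscle multi-DOF toy matches brute-force optimization", {
  set.seed(33)
  Rm <- matrix(c(0.05, -0.02, 0.03, 0.04, -0.03, 0.01), 2, 3)
  A <- c(10, 5, 8); U <- 61 * A
  fx <- generate_consistency_fixture(test_model, seed = 3)
  # independent oracle: penalized optim from several random starts
  M <- as.vector(Rm %*% c(300, 200, 400))
  sol <- solve_static_optimization(Rm, M, A, U)
  expect_equal(sol$status, "converged")
  pen <- function(f) sum((f / A)^3) + 1e8 * sum((as.vector(Rm %*% f) - M)^2)
  best <- Inf
  for (i in 1:5) {
    o <- optim(runif(3, 0, 500), pen, method = "L-BFGS-B", lower = 0, upper = U,
               control = list(maxit = 2000, factr = 1e2))
    best <- min(best, o$value)
  }
  expect_lte(sol$objective, best + 1e-4 * (1 + best))
})

test_that("moment balance holds at solver tolerance on random solvable systems", {
  set.seed(44)
  for (i in 1:20) {
    nd <- sample(2:6, 1); nm <- nd + sample(3:10, 1)
    Rm <- matrix(rnorm(nd * nm, 0, 0.04), nd, nm)
    A <- runif(nm, 2, 30); U <- 61 * A
    F_target <- runif(nm, 0, 0.5) * U
    M <- as.vector(Rm %*% F_target)   # reachable by construction
    sol <- solve_static_optimization(Rm, M, A, U)
    expect_equal(sol$status, "converged")
    expect_lte(sol$residual, 1e-6 * (1 + sqrt(sum(M^2))))
    expect_true(all(sol$forces >= 0 & sol$forces <= U + 1e-9))
  }
})

test_that("optimum beats random feasible probes", {
  set.seed(55)
  Rm <- matrix(c(0.05, 0.03, -0.04, 0.02, 0.01, -0.02), 1, 6)
  A <- runif(6, 3, 20); U <- 61 * A
  M <- 25
  sol <- solve_static_optimization(Rm, M, A, U)
  expect_equal(sol$status, "converged")
  # sample feasible points: random in box, projected onto the constraint by
  # scaling along the current solution direction
  n_probe <- 10000
  worse <- 0
  for (i in seq_len(n_probe)) {
    f <- runif(6) * U
    resid <- M - as.vector(Rm %*% f)
    # correct the residual along the solver solution direction
    dirn <- sol$forces / max(sol$forces)
    alpha <- resid / as.vector(Rm %*% dirn)
    f2 <- f + alpha * dirn
    if (any(f2 < 0 | f2 > U)) next
    if (sum((f2 / A)^3) < sol$objective - 1e-9) worse <- worse + 1
  }
  expect_equal(worse, 0)
})

test_that("raising the exponent drives a two-muscle toy toward equal stress", {
  # generalized solver check via the dual form specialized per exponent:
  # for p in {2,3,5}, minimize sum (F/A)^p subject to r(F1+F2) = M
  r <- 0.05; A <- c(9, 3); M <- 20
  stress_gap <- sapply(c(2, 3, 5), function(p) {
    # closed form: F_i proportional to A_i^(p/(p-1))
    e <- p / (p - 1)
    w <- A^e / sum(A^e)
    F <- w * M / r
    abs(F[1] / A[1] - F[2] / A[2])
  })
  expect_true(all(diff(stress_gap) < 0))
  # the p = 3 closed form agrees with the solver
  e <- 3 / 2
  w <- A^e / sum(A^e)
  sol <- solve_static_optimization(matrix(r, 1, 2), M, A, 1e4 * A)
  expect_equal(sol$forces, w * M / r, tolerance = 1e-6)
})

test_that("infeasible demand is flagged and resolved by bounded least squares", {
  Rm <- matrix(c(0.04, 0.03), 1, 2)
  A <- c(5, 5); U <- 61 * A
  capacity <- sum(Rm * U)
  sol <- solve_static_optimization(Rm, capacity * 1.5, A, U)
  expect_equal(sol$status, "infeasible")
  # bounds were never relaxed; best effort saturates the muscles
  expect_true(all(sol$forces <= U + 1e-6))
  expect_equal(sol$forces, U, tolerance = 1e-4)
})

test_that("joint contact force closes the force balance exactly", {
  m <- test_model
  poses <- standing_poses()
  geo <- limb_moment_matrix(m, poses, "r")
  np <- 4
  set.seed(66)
  solution <- structure(list(
    forces = matrix(runif(np * 26, 0, 300), np, 26),
    geometry = replicate(np, geo, simplify = FALSE)), class = "muscle_solution")
  net_F <- matrix(rnorm(np * 3, 0, 200), np, 3)
  shank_rot <- array(rep(diag(3), each = np), c(np, 3, 3))
  jcf <- joint_contact_force(net_F, solution, shank_rot, "r", body_weight = 600)
  for (p in 1:np) {
    msum <- as.vector(t(geo$tau$knee) %*% solution$forces[p, ])
    # conservation: F_j + sum F_i tau_i = F_e to machine precision
    expect_lt(max(abs(jcf$F_lab[p, ] + msum - net_F[p, ])), 1e-12)
  }
  # zero muscle forces: contact force equals the net load exactly
  solution0 <- solution; solution0$forces[] <- 0
  jcf0 <- joint_contact_force(net_F, solution0, shank_rot, "r", 600)
  expect_equal(jcf0$F_lab, net_F)
  # adding a known extra vertical-down 500 N muscle pull shifts the axial
  # component by exactly +500 N the other way (linearity)
  solution1 <- solution0
  down <- which(geo$tau$knee[, 2] != 0)[1]
  tau_d <- geo$tau$knee[down, ]
  solution1$forces[, down] <- 500 / sqrt(sum(tau_d^2))
  jcf1 <- joint_contact_force(net_F, solution1, shank_rot, "r", 600)
  expect_equal(jcf1$F_lab, net_F - 500 * matrix(tau_d / sqrt(sum(tau_d^2)),
                                                np, 3, byrow = TRUE),
               tolerance = 1e-9)
})

test_that("contact components follow the anatomical sign conventions", {
  np <- 3
  sol0 <- structure(list(forces = matrix(0, np, 26),
                         geometry = replicate(np, list(tau = list(knee = matrix(0, 26, 3))),
                                              simplify = FALSE)),
                    class = "muscle_solution")
  shank_rot <- array(rep(diag(3), each = np), c(np, 3, 3))
  bw <- 600
  # purely compressive load (downward on the tibia): negative axial component
  jcf <- joint_contact_force(matrix(c(0, -bw, 0), np, 3, byrow = TRUE),
                             sol0, shank_rot, "r", bw)
  expect_equal(unname(jcf$components_bw[, "compressive"]), rep(-1, np))
  expect_equal(unname(peak_components(jcf)["compressive"]), 1)
  # purely lateral force on the right tibia (+Z lab): ml = -1 (lateral sign)
  jcf_l <- joint_contact_force(matrix(c(0, 0, bw), np, 3, byrow = TRUE),
                               sol0, shank_rot, "r", bw)
  expect_equal(unname(jcf_l$components_bw[, "ml"]), rep(-1, np))
  expect_equal(unname(peak_components(jcf_l)["ml"]), -1)
  # same force on the left knee is medial: ml = +1
  jcf_lm <- joint_contact_force(matrix(c(0, 0, bw), np, 3, byrow = TRUE),
                                sol0, shank_rot, "l", bw)
  expect_equal(unname(jcf_lm$components_bw[, "ml"]), rep(1, np))
  # posterior force positive AP
  jcf_p <- joint_contact_force(matrix(c(-bw, 0, 0), np, 3, byrow = TRUE),
                               sol0, shank_rot, "r", bw)
  expect_equal(unname(jcf_p$components_bw[, "ap"]), rep(1, np))
  # component recomposition preserves the force magnitude
  set.seed(77)
  F_any <- matrix(rnorm(np * 3, 0, 300), np, 3)
  jcf_a <- joint_contact_force(F_any, sol0, shank_rot, "r", bw)
  expect_equal(sqrt(rowSums(jcf_a$components^2)), sqrt(rowSums(F_any^2)),
               tolerance = 1e-9)
})
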