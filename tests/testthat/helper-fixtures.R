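# Shared fixtures: one reference-subject model and small numeric oracles
# used across test files.

test_model <- build_scaled_model(58.5)
test_params <- test_model$params

# Horn's quaternion-based absolute orientation: an independent oracle for
# the SVD rigid fit (rotation part only, for centered point clouds).
quat_procrustes_rotation <- function(local, world) {
  A <- scale(local, scale = FALSE)
  B <- scale(world, scale = FALSE)
  M <- t(A) %*% B
  Sxx <- M[1,1]; Sxy <- M[1,2]; Sxz <- M[1,3]
  Syx <- M[2,1]; Syy <- M[2,2]; Syz <- M[2,3]
  Szx <- M[3,1]; Szy <- M[3,2]; Szz <- M[3,3]
  N <- matrix(c(
    Sxx+Syy+Szz, Syz-Szy,     Szx-Sxz,     Sxy-Syx,
    Syz-Szy,     Sxx-Syy-Szz, Sxy+Syx,     Szx+Sxz,
    Szx-Sxz,     Sxy+Syx,     -Sxx+Syy-Szz, Syz+Szy,
    Sxy-Syx,     Szx+Sxz,     Syz+Szy,     -Sxx-Syy+Szz), 4, 4, byrow = TRUE)
  q <- eigen(N, symmetric = TRUE)$vectors[, 1]
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1-2*(y^2+z^2), 2*(x*y-w*z),   2*(x*z+w*y),
           2*(x*y+w*z),   1-2*(x^2+z^2), 2*(y*z-w*x),
           2*(x*z-w*y),   2*(y*z+w*x),   1-2*(x^2+y^2)), 3, 3, byrow = TRUE)
}

# two-sided permutation test for a difference in group means
permutation_p <- function(a, b, n_perm = 10000, seed = 1) {
  obs <- abs(mean(a) - mean(b))
  pool <- c(a, b)
  na <- length(a)
  set.seed(seed)
  hits <- 0
  for (i in seq_len(n_perm)) {
    idx <- sample.int(length(pool), na)
    if (abs(mean(pool[idx]) - mean(pool[-idx])) >= obs - 1e-12) hits <- hits + 1
  }
  hits / n_perm
}

# standing poses of the reference model (shared by solver geometry tests)
standing_poses <- function(model = test_model) {
  tpl <- gait_template(model$params, static = TRUE, marker_noise_sd = 0)
  oagait:::all_poses_at(model, tpl, 0, 1, 0, 0)
}
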