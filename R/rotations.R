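# Rotation and rigid-transform utilities shared across the pipeline.
# Frames are right-handed: X anterior, Y superior, Z to the subject's right.

#' Elementary rotation matrices
#'
#' @param theta Angle in radians.
#' @return A 3x3 rotation matrix.
#' @keywords internal
#' @name elementary-rotations
NULL

#' @rdname elementary-rotations
rot_x <- function(theta) {
  c <- cos(theta); s <- sin(theta)
  matrix(c(1, 0, 0, 0, c, s, 0, -s, c), 3, 3)
}

#' @rdname elementary-rotations
rot_y <- function(theta) {
  c <- cos(theta); s <- sin(theta)
  matrix(c(c, 0, -s, 0, 1, 0, s, 0, c), 3, 3)
}

#' @rdname elementary-rotations
rot_z <- function(theta) {
  c <- cos(theta); s <- sin(theta)
  matrix(c(c, s, 0, -s, c, 0, 0, 0, 1), 3, 3)
}

#' Skew-symmetric (hat) matrix of a 3-vector
#' @param v Numeric length-3 vector.
#' @keywords internal
skew <- function(v) {
  matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
}

#' Vee map: extract the axial vector of an (approximately) skew matrix
#' @param W 3x3 matrix; the skew part (W - t(W))/2 is used.
#' @keywords internal
vee <- function(W) {
  S <- (W - t(W)) / 2
  c(S[3, 2], S[1, 3], S[2, 1])
}

#' Decompose a relative rotation into Z-X-Y intrinsic Euler angles
#'
#' The sequence matches the joint coordinate system convention used for the
#' lower-limb joints: first rotation about Z (flexion axis), then X
#' (adduction axis), then Y (internal rotation axis), i.e.
#' `R = rot_z(a) %*% rot_x(b) %*% rot_y(c)`.
#'
#' @param R 3x3 rotation matrix.
#' @return Numeric vector `c(a, b, c)` in radians.
#' @keywords internal
euler_zxy <- function(R) {
  b <- asin(max(-1, min(1, R[3, 2])))
  a <- atan2(-R[1, 2], R[2, 2])
  cc <- atan2(-R[3, 1], R[3, 3])
  c(a, b, cc)
}

#' Compose a rotation from Z-X-Y intrinsic Euler angles
#' @param abc Numeric vector `c(a, b, c)` in radians.
#' @keywords internal
euler_zxy_to_rot <- function(abc) {
  rot_z(abc[1]) %*% rot_x(abc[2]) %*% rot_y(abc[3])
}

#' Least-squares rigid transform between two point clouds (Kabsch)
#'
#' Finds rotation `R` and translation `t` minimizing
#' `sum_i || R x_i + t - y_i ||^2` over proper rotations.
#'
#' @param local n x 3 matrix of points in the segment frame.
#' @param world n x 3 matrix of the corresponding measured points.
#' @param compute_rmsd Also return the fit residual (skipped in the per-frame
#'   hot path).
#' @return List with `rotation` (3x3), `origin` (length 3, the world position
#'   of the local frame origin) and `rmsd` (root-mean-square residual, m; NA
#'   unless requested).
#' @export
fit_rigid_transform <- function(local, world, compute_rmsd = TRUE) {
  local <- as.matrix(local); world <- as.matrix(world)
  stopifnot(nrow(local) == nrow(world), ncol(local) == 3, ncol(world) == 3)
  if (nrow(local) < 3) stop("at least 3 points are required for a rigid fit")
  cl <- colMeans(local); cw <- colMeans(world)
  A <- local; A[, 1] <- A[, 1] - cl[1]; A[, 2] <- A[, 2] - cl[2]; A[, 3] <- A[, 3] - cl[3]
  B <- world; B[, 1] <- B[, 1] - cw[1]; B[, 2] <- B[, 2] - cw[2]; B[, 3] <- B[, 3] - cw[3]
  H <- crossprod(A, B)
  s <- svd(H)
  # collinear clusters leave the rotation about the cluster axis undefined
  if (s$d[2] < 1e-10 * max(s$d[1], 1e-300)) {
    stop("marker cluster is collinear; segment pose is undefined")
  }
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  origin <- cw - as.vector(R %*% cl)
  rmsd <- NA_real_
  if (compute_rmsd) {
    res <- world - (local %*% t(R) + matrix(origin, nrow(local), 3, byrow = TRUE))
    rmsd <- sqrt(mean(rowSums(res^2)))
  }
  list(rotation = R, origin = origin, rmsd = rmsd)
}

#' Apply a pose (rotation + origin) to local points
#' @param pose List with `rotation`, `origin`.
#' @param pts n x 3 matrix or length-3 vector of local coordinates.
#' @keywords internal
pose_apply <- function(pose, pts) {
  if (is.null(dim(pts))) {
    as.vector(pose$rotation %*% pts) + pose$origin
  } else {
    pts %*% t(pose$rotation) + matrix(pose$origin, nrow(pts), 3, byrow = TRUE)
  }
}

#' Convert a rotation matrix to a unit quaternion (w, x, y, z)
#' @keywords internal
rot_to_quat <- function(R) {
  tr <- R[1, 1] + R[2, 2] + R[3, 3]
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(0.25 * s, (R[3, 2] - R[2, 3]) / s, (R[1, 3] - R[3, 1]) / s,
           (R[2, 1] - R[1, 2]) / s)
  } else {
    i <- which.max(c(R[1, 1], R[2, 2], R[3, 3]))
    if (i == 1) {
      s <- sqrt(1 + R[1, 1] - R[2, 2] - R[3, 3]) * 2
      q <- c((R[3, 2] - R[2, 3]) / s, 0.25 * s,
             (R[1, 2] + R[2, 1]) / s, (R[1, 3] + R[3, 1]) / s)
    } else if (i == 2) {
      s <- sqrt(1 + R[2, 2] - R[1, 1] - R[3, 3]) * 2
      q <- c((R[1, 3] - R[3, 1]) / s, (R[1, 2] + R[2, 1]) / s,
             0.25 * s, (R[2, 3] + R[3, 2]) / s)
    } else {
      s <- sqrt(1 + R[3, 3] - R[1, 1] - R[2, 2]) * 2
      q <- c((R[2, 1] - R[1, 2]) / s, (R[1, 3] + R[3, 1]) / s,
             (R[2, 3] + R[3, 2]) / s, 0.25 * s)
    }
  }
  q / sqrt(sum(q^2))
}

#' Angle (radians) between two rotation matrices
#' @keywords internal
rotation_angle_between <- function(R1, R2) {
  Rd <- t(R1) %*% R2
  acos(max(-1, min(1, (sum(diag(Rd)) - 1) / 2)))
}
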