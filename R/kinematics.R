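# Marker trajectories -> segment poses, joint angles, angular rates, COM
# accelerations, gait events and cycle normalization.
#
# Pose estimation is cluster-based: the pelvis pose comes from a least-squares
# rigid fit of its four markers; distal segments are fitted to their two
# anatomical markers plus the shared joint center reconstructed from the
# proximal segment (hip from the pelvis regression offsets, knee and ankle as
# the midpoints of the condyle and malleolus marker pairs).

#' Zero-lag low-pass Butterworth filter
#'
#' Second-order Butterworth applied forward and backward (zero net phase,
#' doubled order), with odd-reflection end padding so start-up transients do
#' not bleed into the data.
#'
#' @param x Numeric vector or matrix (filtered column-wise).
#' @param rate Sampling rate (Hz).
#' @param cutoff Low-pass cutoff (Hz); must be below the Nyquist rate.
#' @return Filtered series, same shape as `x`.
#' @export
filter_signal <- function(x, rate, cutoff) {
  if (cutoff >= rate / 2) stop("cutoff must be below the Nyquist frequency")
  if (cutoff <= 0) stop("cutoff must be positive")
  bf <- signal::butter(2, cutoff / (rate / 2), type = "low")
  filt1 <- function(v) {
    n <- length(v)
    p <- min(n - 1, max(12L, ceiling(3 * rate / cutoff)))
    # odd (point-symmetric) reflection padding
    head_pad <- 2 * v[1] - v[(p + 1):2]
    tail_pad <- 2 * v[n] - v[(n - 1):(n - p)]
    vf <- signal::filtfilt(bf, c(head_pad, v, tail_pad))
    vf[(p + 1):(p + n)]
  }
  if (is.matrix(x)) apply(x, 2, filt1) else filt1(x)
}

#' Finite-difference differentiation
#'
#' Second-order central differences at interior samples and second-order
#' one-sided stencils `(-3 f0 + 4 f1 - f2) / (2 dt)` at the endpoints; exact
#' for quadratics. `order = 2` applies the first-derivative scheme twice.
#'
#' @param x Numeric vector or matrix (columns are channels).
#' @param dt Sample interval (s).
#' @param order Derivative order, 1 or 2.
#' @return Derivative series, same shape as `x`.
#' @export
differentiate <- function(x, dt, order = 1) {
  if (!order %in% c(1, 2)) stop("order must be 1 or 2")
  d1 <- function(v) {
    n <- length(v)
    if (n < 3) stop("at least 3 samples are required to differentiate")
    dv <- numeric(n)
    dv[2:(n - 1)] <- (v[3:n] - v[1:(n - 2)]) / (2 * dt)
    dv[1] <- (-3 * v[1] + 4 * v[2] - v[3]) / (2 * dt)
    dv[n] <- (3 * v[n] - 4 * v[n - 1] + v[n - 2]) / (2 * dt)
    dv
  }
  f <- if (is.matrix(x)) function(v) apply(v, 2, d1) else d1
  out <- f(x)
  if (order == 2) out <- f(out)
  out
}

#' Detect gait cycle events from a force-plate record
#'
#' Heel strike is an upward crossing of the vertical-force threshold sustained
#' for at least `min_duration`; toe off is the matching downward crossing.
#' Shorter excursions on either side of the threshold are treated as chatter
#' and merged. Event times are also reported as indices on the marker clock.
#'
#' @param fp A `forceplate_record` (see [read_forceplates()]).
#' @param threshold Vertical force threshold (N).
#' @param min_duration Debounce duration (s).
#' @param marker_rate Marker sampling rate (Hz) for clock conversion.
#' @return An object of class `gait_events`: `heel_strike` / `toe_off` times
#'   (s), marker-frame indices, and the source `plate_id`.
#' @export
detect_gait_events <- function(fp, threshold = 20, min_duration = 0.02,
                               marker_rate = 100) {
  fz <- fp$force[, 2]
  loaded <- fz >= threshold
  if (!any(loaded)) {
    warning("no threshold crossings found on plate ", fp$plate_id)
    return(structure(list(heel_strike = numeric(0), toe_off = numeric(0),
                          heel_strike_frame = integer(0),
                          toe_off_frame = integer(0), plate_id = fp$plate_id),
                     class = "gait_events"))
  }
  min_samp <- max(1L, round(min_duration * fp$rate))
  r <- rle(loaded)
  # absorb runs shorter than the debounce window into their neighbours
  while (length(r$lengths) > 1 && any(r$lengths < min_samp)) {
    i <- which(r$lengths < min_samp)[1]
    r$values[i] <- !r$values[i]
    r <- rle(inverse.rle(r))
  }
  loaded <- inverse.rle(r)
  d <- diff(c(FALSE, loaded))
  hs_i <- which(d == 1)
  to_i <- which(d == -1)
  t <- (seq_along(fz) - 1) / fp$rate
  hs <- t[hs_i]
  to <- t[to_i]
  structure(list(heel_strike = hs, toe_off = to,
                 heel_strike_frame = as.integer(round(hs * marker_rate)) + 1L,
                 toe_off_frame = as.integer(round(to * marker_rate)) + 1L,
                 plate_id = fp$plate_id),
            class = "gait_events")
}

# pose containers: per segment a list(rotation = n x 3 x 3, origin = n x 3)
pose_at <- function(seg_poses, frame) {
  list(rotation = matrix(seg_poses$rotation[frame, , ], 3, 3),
       origin = seg_poses$origin[frame, ])
}

poses_at_frame <- function(poses, frame) {
  lapply(poses$segments, pose_at, frame = frame)
}

#' Estimate per-frame segment poses from marker trajectories
#'
#' @param markers A `marker_set` from [read_markers()] or the synthetic
#'   generator.
#' @param model A `limb_model` whose scaled marker table defines the local
#'   marker coordinates.
#' @return An object of class `segment_poses`: per segment, arrays of
#'   rotations (frames x 3 x 3) and origins (frames x 3); `bad_frames` lists
#'   frames where a required marker was missing; `rate` is carried over.
#' @export
compute_segment_poses <- function(markers, model) {
  mk <- model$marker_local
  nframes <- dim(markers$positions)[1]
  midx <- match(mk$name, markers$marker_names)
  if (anyNA(midx)) {
    stop("markers required by the model are absent: ",
         paste(mk$name[is.na(midx)], collapse = ", "))
  }
  widx <- function(names) match(names, markers$marker_names)
  get_world <- function(frame, i) matrix(markers$positions[frame, i, ], ncol = 3)
  local_of <- function(names) {
    i <- match(names, mk$name)
    as.matrix(mk[i, c("x", "y", "z")])
  }
  seg_names <- c("pelvis", "thigh_r", "shank_r", "foot_r",
                 "thigh_l", "shank_l", "foot_l")
  empty <- function() list(rotation = array(NA_real_, c(nframes, 3, 3)),
                           origin = matrix(NA_real_, nframes, 3))
  segs <- stats::setNames(lapply(seg_names, function(s) empty()), seg_names)
  bad <- logical(nframes)

  pelvis_names <- mk$name[mk$segment == "pelvis"]
  pelvis_local <- local_of(pelvis_names)
  pelvis_idx <- widx(pelvis_names)
  side_tab <- list(
    r = list(knee = c("R.Knee.Lat", "R.Knee.Med"),
             ankle = c("R.Ankle.Lat", "R.Ankle.Med"),
             foot = c("R.Heel", "R.Toe")),
    l = list(knee = c("L.Knee.Lat", "L.Knee.Med"),
             ankle = c("L.Ankle.Lat", "L.Ankle.Med"),
             foot = c("L.Heel", "L.Toe")))
  # per-side precomputed local clusters (joint-center virtual point first)
  # and marker column indices
  pre <- lapply(side_tab, function(st) list(
    knee_i = widx(st$knee), ankle_i = widx(st$ankle), foot_i = widx(st$foot),
    thigh_local = rbind(c(0, 0, 0), local_of(st$knee)),
    shank_local = rbind(c(0, 0, 0), local_of(st$ankle)),
    foot_local = rbind(c(0, 0, 0), local_of(st$foot))))

  for (f in seq_len(nframes)) {
    pw <- get_world(f, pelvis_idx)
    if (anyNA(pw)) { bad[f] <- TRUE; next }
    fit <- fit_rigid_transform(pelvis_local, pw, compute_rmsd = FALSE)
    segs$pelvis$rotation[f, , ] <- fit$rotation
    segs$pelvis$origin[f, ] <- fit$origin
    pelvis_pose <- list(rotation = fit$rotation, origin = fit$origin)
    for (side in c("r", "l")) {
      st <- pre[[side]]
      hip_w <- pose_apply(pelvis_pose, model$hip_center_local[[side]])
      kn_w <- get_world(f, st$knee_i)
      an_w <- get_world(f, st$ankle_i)
      ft_w <- get_world(f, st$foot_i)
      if (anyNA(kn_w) || anyNA(an_w) || anyNA(ft_w)) { bad[f] <- TRUE; next }
      thigh <- paste0("thigh_", side); shank <- paste0("shank_", side)
      foot <- paste0("foot_", side)
      # thigh: hip center (frame origin) + the two femoral condyle markers
      th_fit <- fit_rigid_transform(st$thigh_local, rbind(hip_w, kn_w),
                                    compute_rmsd = FALSE)
      segs[[thigh]]$rotation[f, , ] <- th_fit$rotation
      segs[[thigh]]$origin[f, ] <- th_fit$origin
      # shank: knee center (midpoint of condyles) + malleolus markers
      sh_fit <- fit_rigid_transform(st$shank_local, rbind(colMeans(kn_w), an_w),
                                    compute_rmsd = FALSE)
      segs[[shank]]$rotation[f, , ] <- sh_fit$rotation
      segs[[shank]]$origin[f, ] <- sh_fit$origin
      # foot: ankle center (midpoint of malleoli) + heel and toe markers
      ft_fit <- fit_rigid_transform(st$foot_local, rbind(colMeans(an_w), ft_w),
                                    compute_rmsd = FALSE)
      segs[[foot]]$rotation[f, , ] <- ft_fit$rotation
      segs[[foot]]$origin[f, ] <- ft_fit$origin
    }
  }
  structure(list(segments = segs, bad_frames = which(bad),
                 rate = markers$rate, n_frames = nframes),
            class = "segment_poses")
}

JOINT_ANGLE_SIGNS <- list(
  hip = c(flexion = 1, adduction = 1, internal_rotation = 1),
  knee = c(flexion = -1, adduction = 1, internal_rotation = 1),
  ankle = c(flexion = 1, adduction = 1, internal_rotation = 1))

#' Joint angles from segment poses
#'
#' Decomposes the parent-to-child relative rotation in the intrinsic Z-X-Y
#' (flexion, adduction, internal rotation) sequence, unwraps each angle
#' series for continuity, applies the side- and joint-specific sign map
#' (flexion positive at every joint, dorsiflexion positive at the ankle,
#' adduction/internal rotation positive on both sides) and flags frames near
#' gimbal lock (|adduction| > 85 deg).
#'
#' @param poses A `segment_poses` object.
#' @param model A `limb_model`.
#' @return Named list per joint: matrix (frames x 3) with columns `flexion`,
#'   `adduction`, `internal_rotation` in degrees; attribute `gimbal_frames`.
#' @export
compute_joint_angles <- function(poses, model) {
  out <- list()
  for (jname in names(model$joints)) {
    j <- model$joints[[jname]]
    base <- sub("_[rl]$", "", jname)
    side <- if (endsWith(jname, "_r")) "r" else "l"
    Rp <- poses$segments[[j$parent]]$rotation
    Rc <- poses$segments[[j$child]]$rotation
    n <- dim(Rp)[1]
    ang <- matrix(NA_real_, n, 3)
    for (f in seq_len(n)) {
      Rrel <- t(matrix(Rp[f, , ], 3, 3)) %*% matrix(Rc[f, , ], 3, 3)
      if (anyNA(Rrel)) next
      ang[f, ] <- euler_zxy(Rrel)
    }
    ok <- !is.na(ang[, 1])
    if (any(ok)) for (k in 1:3) {
      # enforce continuity: unwrap jumps larger than pi
      v <- ang[ok, k]
      dv <- diff(v)
      jumps <- cumsum(c(0, round(dv / (2 * pi))))
      ang[ok, k] <- v - 2 * pi * jumps
    }
    signs <- JOINT_ANGLE_SIGNS[[base]]
    if (side == "l") signs[c("adduction", "internal_rotation")] <-
        -signs[c("adduction", "internal_rotation")]
    deg <- sweep(ang, 2, unname(signs), `*`) * 180 / pi
    colnames(deg) <- c("flexion", "adduction", "internal_rotation")
    gimbal <- which(abs(ang[, 2]) > 85 * pi / 180)
    attr(deg, "gimbal_frames") <- gimbal
    out[[jname]] <- deg
  }
  out
}

#' Angular velocity and acceleration from a rotation series
#'
#' The lab-frame angular velocity is the axial vector of the skew part of
#' `Rdot %*% t(R)`, with `Rdot` from finite differences; the angular
#' acceleration differentiates the angular velocity.
#'
#' @param R Rotation array, frames x 3 x 3, orthonormal per frame.
#' @param dt Sample interval (s).
#' @return List with `omega` and `alpha` (frames x 3 matrices, rad/s and
#'   rad/s^2, lab frame).
#' @export
angular_rates_from_rotations <- function(R, dt) {
  n <- dim(R)[1]
  flat <- matrix(R, n, 9)
  dflat <- differentiate(flat, dt, order = 1)
  omega <- matrix(NA_real_, n, 3)
  for (f in seq_len(n)) {
    W <- matrix(dflat[f, ], 3, 3) %*% t(matrix(flat[f, ], 3, 3))
    omega[f, ] <- vee(W)
  }
  alpha <- differentiate(omega, dt, order = 1)
  list(omega = omega, alpha = alpha)
}

#' Full segment kinematics for inverse dynamics
#'
#' Combines poses with the model's inertial table: per segment, angular
#' velocity and acceleration from the rotation series and the COM world
#' trajectory differentiated twice.
#'
#' @param poses A `segment_poses` object.
#' @param model A `limb_model`.
#' @return Object of class `segment_kinematics`: per segment `rotation`,
#'   `origin`, `omega`, `alpha`, `com` (m), `com_acc` (m/s^2), plus the rate.
#' @export
segment_kinematics <- function(poses, model) {
  dt <- 1 / poses$rate
  out <- list()
  for (sname in names(poses$segments)) {
    sp <- poses$segments[[sname]]
    seg <- model$segments[[sname]]
    rates <- angular_rates_from_rotations(sp$rotation, dt)
    n <- dim(sp$rotation)[1]
    com <- matrix(NA_real_, n, 3)
    for (f in seq_len(n)) {
      com[f, ] <- pose_at(sp, f)$origin +
        as.vector(matrix(sp$rotation[f, , ], 3, 3) %*% seg$com_offset)
    }
    out[[sname]] <- list(rotation = sp$rotation, origin = sp$origin,
                         omega = rates$omega, alpha = rates$alpha,
                         com = com, com_acc = differentiate(com, dt, order = 2))
  }
  structure(list(segments = out, rate = poses$rate, n_frames = poses$n_frames),
            class = "segment_kinematics")
}

#' Normalize a time series onto the gait cycle
#'
#' Interpolates each complete heel-strike-to-heel-strike cycle onto 100
#' evenly spaced points (0%, 1%, ..., 99% of the cycle) and averages cycles
#' pointwise.
#'
#' @param x Numeric vector or matrix (rows are frames).
#' @param rate Sampling rate of `x` (Hz).
#' @param heel_strikes Heel-strike times (s) of the analyzed side; consecutive
#'   pairs delimit cycles.
#' @param n_points Number of cycle points (default 100).
#' @return Matrix `n_points x d` (vector input returns a 1-column matrix) with
#'   attribute `n_cycles`.
#' @export
normalize_cycle <- function(x, rate, heel_strikes, n_points = 100) {
  if (length(heel_strikes) < 2) stop("no complete gait cycle in the record")
  if (is.null(dim(x))) x <- matrix(x, ncol = 1)
  t <- (seq_len(nrow(x)) - 1) / rate
  cycles <- list()
  for (k in seq_len(length(heel_strikes) - 1)) {
    t0 <- heel_strikes[k]; t1 <- heel_strikes[k + 1]
    if (t0 < t[1] - 1e-9 || t1 > t[length(t)] + 1e-9) next
    tq <- t0 + (0:(n_points - 1)) / n_points * (t1 - t0)
    cyc <- apply(x, 2, function(v) stats::approx(t, v, xout = tq, rule = 2)$y)
    cycles[[length(cycles) + 1]] <- matrix(cyc, n_points)
  }
  if (length(cycles) == 0) stop("no complete gait cycle inside the record")
  out <- Reduce(`+`, cycles) / length(cycles)
  attr(out, "n_cycles") <- length(cycles)
  out
}
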