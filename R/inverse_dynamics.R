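# Bottom-up Newton-Euler recursion: foot -> shank -> thigh. Each segment's
# equations of motion are solved for the force and moment its proximal
# neighbour applies at the joint center, starting from the measured ground
# reaction applied at the center of pressure (with the free moment channel).

#' Net (intersegmental) joint loads for one limb
#'
#' For segment i with mass `m`, world inertia `I` about the COM, COM
#' acceleration `a`, angular velocity/acceleration `omega`/`alpha`, distal
#' load `F_d`, `M_d` applied at point `p_d`, the proximal joint load at `p_p`
#' follows from
#' `F_p = m (a - g) - F_d` and
#' `M_p = I alpha + omega x (I omega) - M_d - (p_p - com) x F_p - (p_d - com) x F_d`.
#' The recursion starts at the foot with the ground reaction at the COP and
#' hands `-F_p`, `-M_p` down as the next segment's distal load.
#'
#' @param model A `limb_model`.
#' @param kin A `segment_kinematics` object.
#' @param grf A `forceplate_record` for this foot, already resampled onto the
#'   marker clock ([resample_to_marker_clock()]).
#' @param side `"r"` or `"l"`.
#' @param load_threshold Vertical force (N) above which the foot counts as
#'   loaded; loaded frames lacking a defined COP are an error. Swing frames
#'   use zero external force.
#' @return Object of class `net_joint_loads`: per joint (`ankle`, `knee`,
#'   `hip`) matrices `F` and `M` (frames x 3, N and N m, lab frame, the load
#'   the proximal segment applies to the distal one at the joint center), the
#'   joint center trajectories, rate and stored body weight.
#' @export
net_loads <- function(model, kin, grf, side = "r", load_threshold = 20) {
  stopifnot(side %in% c("r", "l"))
  n <- kin$n_frames
  if (!is.null(grf)) {
    if (abs(grf$rate - kin$rate) > 1e-9) {
      stop("ground reaction record must be on the marker clock (",
           kin$rate, " Hz), got ", grf$rate, " Hz")
    }
    if (nrow(grf$force) < n) stop("ground reaction record shorter than kinematics")
  }
  g <- model$gravity
  chain <- paste0(c("foot", "shank", "thigh"), "_", side)
  prox_joint <- paste0(c("ankle", "knee", "hip"), "_", side)
  out <- list()
  # joint center world trajectories
  centers <- list()
  for (jn in prox_joint) {
    j <- model$joints[[jn]]
    src <- kin$segments[[j$center_frame]]
    cw <- matrix(NA_real_, n, 3)
    for (f in seq_len(n)) {
      cw[f, ] <- src$origin[f, ] +
        as.vector(matrix(src$rotation[f, , ], 3, 3) %*% j$center_local)
    }
    centers[[jn]] <- cw
  }

  F_dist <- matrix(0, n, 3); M_dist <- matrix(0, n, 3)
  p_dist <- NULL  # n x 3 application points of the distal load
  for (k in seq_along(chain)) {
    segname <- chain[k]
    seg <- model$segments[[segname]]
    sk <- kin$segments[[segname]]
    if (k == 1) {
      p_dist <- matrix(NA_real_, n, 3)
      if (!is.null(grf)) {
        loaded <- grf$force[seq_len(n), 2] > load_threshold
        bad <- loaded & !grf$cop_defined[seq_len(n)]
        if (any(bad)) {
          stop("loaded frames without a defined COP on plate ", grf$plate_id,
               " (first at frame ", which(bad)[1], ")")
        }
        F_dist[loaded, ] <- grf$force[seq_len(n), ][loaded, , drop = FALSE]
        M_dist[loaded, ] <- grf$moment[seq_len(n), ][loaded, , drop = FALSE]
        p_dist[loaded, ] <- grf$cop[seq_len(n), ][loaded, , drop = FALSE]
      }
    }
    Fp <- matrix(NA_real_, n, 3); Mp <- matrix(NA_real_, n, 3)
    for (f in seq_len(n)) {
      R <- matrix(sk$rotation[f, , ], 3, 3)
      if (anyNA(R)) next
      Iw <- R %*% seg$inertia %*% t(R)
      a <- sk$com_acc[f, ]; w <- sk$omega[f, ]; al <- sk$alpha[f, ]
      com <- sk$com[f, ]
      pp <- centers[[prox_joint[k]]][f, ]
      Fp[f, ] <- seg$mass * (a - g) - F_dist[f, ]
      gyro <- crossv(w, as.vector(Iw %*% w))
      lever_d <- c(0, 0, 0)
      if (!anyNA(p_dist[f, ]) && any(F_dist[f, ] != 0)) {
        lever_d <- crossv(p_dist[f, ] - com, F_dist[f, ])
      }
      Mp[f, ] <- as.vector(Iw %*% al) + gyro - M_dist[f, ] -
        crossv(pp - com, Fp[f, ]) - lever_d
    }
    out[[sub("_[rl]$", "", prox_joint[k])]] <-
      list(joint = prox_joint[k], F = Fp, M = Mp,
           center = centers[[prox_joint[k]]])
    # next segment's distal load: reaction at this joint
    F_dist <- -Fp; M_dist <- -Mp
    p_dist <- centers[[prox_joint[k]]]
  }
  structure(list(loads = out, side = side, rate = kin$rate, n_frames = n,
                 body_weight = model$body_mass * 9.81),
            class = "net_joint_loads")
}

crossv <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Express a net joint load in the distal-segment anatomical frame
#'
#' Rotates lab-frame force and moment series into the frame of the joint's
#' child segment (shank for the knee), the frame in which the contact-force
#' components are reported.
#'
#' @param load List with `F`, `M` (n x 3 lab-frame matrices).
#' @param poses A `segment_poses` or `segment_kinematics` object.
#' @param segment Name of the distal segment, e.g. `"shank_r"`.
#' @return The load with `F`, `M` rotated into the segment frame.
#' @export
to_distal_frame <- function(load, poses, segment) {
  sp <- poses$segments[[segment]]
  if (is.null(sp)) stop("pose missing for segment: ", segment)
  n <- nrow(load$F)
  Fl <- matrix(NA_real_, n, 3); Ml <- matrix(NA_real_, n, 3)
  for (f in seq_len(n)) {
    R <- matrix(sp$rotation[f, , ], 3, 3)
    if (anyNA(R)) next
    Fl[f, ] <- as.vector(t(R) %*% load$F[f, ])
    Ml[f, ] <- as.vector(t(R) %*% load$M[f, ])
  }
  out <- load
  out$F <- Fl; out$M <- Ml
  out$frame <- segment
  out
}
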