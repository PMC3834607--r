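# End-to-end orchestration: events -> poses -> kinematics -> net loads ->
# static optimization -> contact force -> cocontraction metrics, per cycle,
# with cycles averaged after all per-cycle computation; then the group-level
# comparison report.

#' Default pipeline configuration
#'
#' @param side Which limb(s) to analyze: `"right"`, `"left"` or `"both"`.
#' @param marker_cutoff Marker low-pass cutoff (Hz).
#' @param grf_cutoff Force-plate anti-alias cutoff (Hz).
#' @param event_threshold Gait-event vertical force threshold (N).
#' @param solver_tol Relative moment-balance tolerance of the optimizer.
#' @param plate_map Named list mapping side (`r`, `l`) to plate id.
#' @param n_points Cycle points (100 intervals per cycle).
#' @param constrained_dofs Indices of the moment-balance DOF
#'   ([default_constrained_dofs()] unless given).
#' @return Named list of configuration values.
#' @export
pipeline_config <- function(side = "both", marker_cutoff = 6, grf_cutoff = 20,
                            event_threshold = 20, solver_tol = 1e-8,
                            plate_map = list(r = 1L, l = 2L),
                            n_points = 100,
                            constrained_dofs = default_constrained_dofs()) {
  if (!side %in% c("right", "left", "both")) {
    stop("side must be 'right', 'left' or 'both'")
  }
  list(side = side, marker_cutoff = marker_cutoff, grf_cutoff = grf_cutoff,
       event_threshold = event_threshold, solver_tol = solver_tol,
       plate_map = plate_map, n_points = n_points,
       constrained_dofs = constrained_dofs)
}

filter_marker_set <- function(markers, cutoff) {
  pos <- markers$positions
  n <- dim(pos)[1]
  if (n < 13) return(markers)   # too short for stable zero-lag filtering
  for (i in seq_len(dim(pos)[2])) {
    slab <- matrix(pos[, i, ], n, 3)
    if (anyNA(slab)) next       # gap frames are flagged, never interpolated
    pos[, i, ] <- filter_signal(slab, markers$rate, cutoff)
  }
  marker_set(markers$marker_names, pos, markers$rate)
}

interp_series <- function(x, rate, tq) {
  t <- (seq_len(nrow(x)) - 1) / rate
  apply(x, 2, function(v) stats::approx(t, v, xout = tq, rule = 2)$y)
}

analyze_side <- function(model, kin, poses, plate, config, side) {
  events <- detect_gait_events(plate, threshold = config$event_threshold,
                               marker_rate = kin$rate)
  if (length(events$heel_strike) < 2) {
    stop("stage=events side=", side, ": fewer than two heel strikes detected")
  }
  grf_m <- resample_to_marker_clock(plate, kin$rate, cutoff = config$grf_cutoff)
  net <- net_loads(model, kin, grf_m, side = side,
                   load_threshold = config$event_threshold)
  bw <- net$body_weight
  angles <- compute_joint_angles(poses, model)
  np <- config$n_points
  shank <- paste0("shank_", side)

  hs <- events$heel_strike
  n_cyc <- length(hs) - 1
  acc <- NULL
  for (k in seq_len(n_cyc)) {
    t0 <- hs[k]; t1 <- hs[k + 1]
    tq <- t0 + (0:(np - 1)) / np * (t1 - t0)
    fidx <- pmin(pmax(round(tq * kin$rate) + 1, 1), kin$n_frames)
    geometry <- lapply(fidx, function(f)
      limb_moment_matrix(model, poses_at_frame(poses, f), side))
    mom9 <- cbind(interp_series(net$loads$hip$M, kin$rate, tq),
                  interp_series(net$loads$knee$M, kin$rate, tq),
                  interp_series(net$loads$ankle$M, kin$rate, tq))
    sol <- solve_cycle(geometry, mom9, tol = config$solver_tol,
                       dofs = config$constrained_dofs)
    knee_F <- interp_series(net$loads$knee$F, kin$rate, tq)
    shank_rot <- poses$segments[[shank]]$rotation[fidx, , , drop = FALSE]
    jcf <- joint_contact_force(knee_F, sol, shank_rot, side, bw)
    knee_axis <- t(vapply(seq_len(np), function(p)
      matrix(shank_rot[p, , ], 3, 3)[, 3], numeric(3)))
    cc <- cocontraction_ratios(sol, knee_axis)
    ang_cyc <- lapply(angles[paste0(c("hip", "knee", "ankle"), "_", side)],
                      function(a) interp_series(unclass(a), kin$rate, tq))
    cyc <- list(forces = sol$forces, activation = sol$activation,
                residual = sol$residual, status = sol$status,
                jcf_components_bw = jcf$components_bw,
                A_e = cc$A_e, A_f = cc$A_f, T_e = cc$T_e, T_f = cc$T_f,
                net_knee_M_bw = interp_series(net$loads$knee$M, kin$rate, tq) / bw,
                angles = ang_cyc, sol = sol, jcf = jcf)
    if (is.null(acc)) {
      acc <- cyc
      acc$n <- 1
    } else {
      for (nm in c("forces", "activation", "jcf_components_bw",
                   "A_e", "A_f", "T_e", "T_f", "net_knee_M_bw")) {
        acc[[nm]] <- acc[[nm]] + cyc[[nm]]
      }
      for (j in names(acc$angles)) acc$angles[[j]] <- acc$angles[[j]] + cyc$angles[[j]]
      acc$residual <- pmax(acc$residual, cyc$residual)
      acc$status <- ifelse(cyc$status == "converged", acc$status, cyc$status)
      acc$n <- acc$n + 1
    }
  }
  for (nm in c("forces", "activation", "jcf_components_bw",
               "A_e", "A_f", "T_e", "T_f", "net_knee_M_bw")) {
    acc[[nm]] <- acc[[nm]] / acc$n
  }
  for (j in names(acc$angles)) acc$angles[[j]] <- acc$angles[[j]] / acc$n

  floor_ <- 1e-6
  efar <- mean(acc$A_e) / max(mean(acc$A_f), floor_)
  eftr <- mean(acc$T_e) / max(mean(acc$T_f), floor_)
  # compressive and medial peaks are tabulated as positive magnitudes,
  # matching the positive-medial component convention; AP keeps the signed
  # extremum (posterior positive)
  peaks <- c(compressive = max(pmax(-acc$jcf_components_bw[, "compressive"], 0)),
             ml = max(acc$jcf_components_bw[, "ml"]),
             ap = acc$jcf_components_bw[, "ap"][which.max(abs(acc$jcf_components_bw[, "ap"]))])
  knee_names <- c(KNEE_EXTENSORS, KNEE_FLEXORS)
  mean_forces <- colMeans(acc$activation[, knee_names, drop = FALSE])
  names(mean_forces) <- paste0("force_", knee_names)
  metrics <- c(mean_forces,
               peak_compressive = unname(peaks["compressive"]),
               peak_ml = unname(peaks["ml"]),
               peak_ap = unname(peaks["ap"]),
               flexor_activation = mean(acc$A_f) / 8,
               flexor_torque = mean(acc$T_f) / bw,
               extensor_activation = mean(acc$A_e) / 4,
               extensor_torque = mean(acc$T_e) / bw,
               EFAR = efar, EFTR = eftr)
  list(side = side, n_cycles = acc$n, metrics = metrics,
       series = list(activation = acc$activation,
                     forces = acc$forces,
                     jcf_components_bw = acc$jcf_components_bw,
                     A_e = acc$A_e, A_f = acc$A_f,
                     T_e = acc$T_e, T_f = acc$T_f,
                     net_knee_M_bw = acc$net_knee_M_bw,
                     angles = acc$angles),
       diagnostics = list(max_residual = max(acc$residual),
                          n_infeasible = sum(acc$status != "converged"),
                          events = events))
}

#' Run the full per-subject pipeline
#'
#' Filters the marker trajectories, estimates segment poses and kinematics,
#' detects gait events per side from its force plate, computes net joint
#' loads, solves the static optimization at each of the 100 cycle points,
#' decomposes the knee contact force and computes the cocontraction metrics;
#' multiple cycles are averaged pointwise after all per-cycle computation.
#'
#' @param model A `limb_model` for the subject.
#' @param trial List with `markers` (a `marker_set`) and `plates` (list of
#'   `forceplate_record`s), e.g. from [generate_trial()].
#' @param config Configuration from [pipeline_config()].
#' @return Object of class `subject_bundle`: per analyzed side the 100-point
#'   normalized series, the Table-style summary metrics, and solver
#'   diagnostics. Any stage failure raises an error naming the stage.
#' @export
run_subject <- function(model, trial, config = pipeline_config()) {
  stopifnot(inherits(model, "limb_model"))
  if (!inherits(trial$markers, "marker_set")) {
    stop("stage=gait_io: trial has no marker_set")
  }
  markers <- filter_marker_set(trial$markers, config$marker_cutoff)
  poses <- tryCatch(compute_segment_poses(markers, model),
                    error = function(e) stop("stage=kinematics: ",
                                             conditionMessage(e), call. = FALSE))
  kin <- segment_kinematics(poses, model)
  plate_of <- function(side) {
    id <- config$plate_map[[side]]
    for (p in trial$plates) if (p$plate_id == id) return(p)
    stop("stage=gait_io: no plate with id ", id, " for side ", side)
  }
  sides <- switch(config$side, right = "r", left = "l", both = c("r", "l"))
  res <- lapply(sides, function(s)
    analyze_side(model, kin, poses, plate_of(s), config, s))
  names(res) <- sides
  structure(list(sides = res, config = config,
                 body_weight = model$body_mass * 9.81),
            class = "subject_bundle")
}

#' @export
print.subject_bundle <- function(x, ...) {
  for (s in names(x$sides)) {
    r <- x$sides[[s]]
    cat("Side", s, ":", r$n_cycles, "cycle(s); EFAR",
        round(r$metrics[["EFAR"]], 3), "EFTR", round(r$metrics[["EFTR"]], 3),
        "; peak compressive", round(r$metrics[["peak_compressive"]], 2), "BW\n")
  }
  invisible(x)
}

GROUP_METRICS <- c(paste0("force_", c(KNEE_EXTENSORS, KNEE_FLEXORS)),
                   "peak_compressive", "peak_ml", "peak_ap",
                   "flexor_activation", "flexor_torque",
                   "extensor_activation", "extensor_torque", "EFAR", "EFTR")

#' Group comparison report
#'
#' Builds the Table-style report: per metric, group means and SDs, Welch t
#' statistic, two-sided P value and the significance flag at 0.05. The
#' anteroposterior peak row compares magnitudes; the mediolateral row is the
#' peak medial component (positive-medial convention).
#'
#' @param bundles List of `subject_bundle`s.
#' @param labels Character vector of group labels, one per bundle (exactly
#'   two distinct groups, >= 2 subjects each).
#' @param side Which analyzed side to compare (`"r"` or `"l"`).
#' @param var_equal Pooled-variance t test instead of Welch.
#' @return Data frame with one row per metric (12 muscles + 3 contact-force
#'   components + 6 extensor/flexor summaries = 21 rows).
#' @export
run_group_comparison <- function(bundles, labels, side = "r",
                                 var_equal = FALSE) {
  groups <- unique(labels)
  if (length(groups) != 2) stop("exactly two groups are required")
  if (any(table(labels) < 2)) stop("each group needs at least 2 subjects")
  vals <- t(vapply(bundles, function(b) {
    if (is.null(b$sides[[side]])) stop("bundle lacks analyzed side ", side)
    b$sides[[side]]$metrics[GROUP_METRICS]
  }, numeric(length(GROUP_METRICS))))
  colnames(vals) <- GROUP_METRICS
  rows <- lapply(GROUP_METRICS, function(m) {
    v <- vals[, m]
    if (m == "peak_ap") v <- abs(v)
    a <- v[labels == groups[1]]; b <- v[labels == groups[2]]
    tt <- independent_t_test(a, b, var_equal = var_equal)
    data.frame(metric = m,
               mean_1 = mean(a), sd_1 = stats::sd(a),
               mean_2 = mean(b), sd_2 = stats::sd(b),
               t = tt$t, p = tt$p, significant = tt$p < 0.05,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "groups") <- groups
  attr(out, "side") <- side
  out
}
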