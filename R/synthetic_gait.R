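# Deterministic synthetic gait generator: joint-angle templates (Fourier
# series) -> forward kinematics -> 37-marker trajectories at 100 Hz, plus
# parametric double-hump ground reaction forces at 1000 Hz with a
# heel-to-toe COP progression. The OA-like mode displaces the load line
# medially at the foot (the severity knob, meters), which raises the external
# knee adduction moment, and adds the sagittal signatures of medial knee OA
# gait: a knee flexion contracture and a reduced dynamic flexion range.
#
# Kinematics are prescribed and the GRF is parametric, so dynamic
# consistency is approximate (vertical impulse per step is matched to body
# weight x step time within a few percent by the template shape); the exact
# optimizer oracle is the KKT consistency fixture, not the gait generator.

eval_fourier <- function(coef, phase) {
  K <- (length(coef) - 1) / 2
  y <- rep(coef[1], length(phase))
  for (k in seq_len(K)) {
    y <- y + coef[2 * k] * cos(2 * pi * k * phase) +
      coef[2 * k + 1] * sin(2 * pi * k * phase)
  }
  y
}

with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    set.seed(seed)
    on.exit({
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
  }
  force(code)
}

#' Build a gait template
#'
#' Assembles the waveform template driving the synthetic generator from the
#' embedded parameter file, with optional overrides.
#'
#' @param params Parameter list from [load_model_parameters()] (or NULL for
#'   the packaged defaults).
#' @param cadence Steps per minute.
#' @param stance_fraction Fraction of the cycle each foot is loaded.
#' @param cop_medial_offset Medial COP shift (m) in the foot frame; the
#'   OA-severity lever offset (0 = normal load line). Positive values move
#'   the center of pressure toward the midline, increasing the external knee
#'   adduction moment as in varus-aligned medial OA.
#' @param knee_rom_scale Multiplier on the knee flexion range about its cycle
#'   mean (OA mode uses values below 1).
#' @param knee_contracture_deg Constant knee flexion offset (deg) added to
#'   the whole waveform, emulating the flexion contracture of OA gait.
#' @param marker_noise_sd Isotropic marker noise SD (m).
#' @param static If TRUE, a standing template: all joint angles zero,
#'   stationary pelvis, each plate carrying half body weight.
#' @return Object of class `gait_template`.
#' @export
gait_template <- function(params = NULL, cadence = NULL, stance_fraction = NULL,
                          cop_medial_offset = 0, knee_rom_scale = 1,
                          knee_contracture_deg = 0,
                          marker_noise_sd = NULL, static = FALSE) {
  if (is.null(params) || is.character(params)) params <- load_model_parameters(params)
  g <- params$gait_template
  tpl <- list(
    cadence = if (is.null(cadence)) g$cadence else cadence,
    stride_length = g$stride_length,
    stance_fraction = if (is.null(stance_fraction)) g$stance_fraction else stance_fraction,
    pelvis_height = g$pelvis_height,
    grf_knot_t = unlist(g$grf$knot_t),
    grf_knot_bw = unlist(g$grf$knot_bw),
    ap_peak_bw = g$grf$ap_peak_bw,
    ml_peak_bw = g$grf$ml_peak_bw,
    angles = lapply(g$angles_deg, unlist),
    marker_noise_sd = if (is.null(marker_noise_sd)) g$marker_noise_sd else marker_noise_sd,
    cop_medial_offset = cop_medial_offset,
    knee_rom_scale = knee_rom_scale,
    knee_contracture_deg = knee_contracture_deg,
    static = static)
  if (tpl$stance_fraction <= 0.4 || tpl$stance_fraction >= 0.8) {
    stop("stance fraction must lie in (0.4, 0.8)")
  }
  pk <- tpl$grf_knot_bw[-c(1, length(tpl$grf_knot_bw))]
  if (!static && !(max(pk) > min(pk) && min(pk) > 0)) {
    stop("GRF template must have positive peaks above a positive valley")
  }
  class(tpl) <- "gait_template"
  tpl
}

template_angles <- function(tpl, phase) {
  a <- lapply(tpl$angles, eval_fourier, phase = phase)
  m <- tpl$angles$knee_flexion[1]   # cycle mean = Fourier DC term
  a$knee_flexion <- tpl$knee_contracture_deg + m +
    tpl$knee_rom_scale * (a$knee_flexion - m)
  if (tpl$static) a <- lapply(a, function(v) v * 0)
  a
}

# world poses of all frames for one side at given cycle phases
limb_poses_at <- function(model, tpl, pelvis_pose, phase, side) {
  ang <- template_angles(tpl, phase)
  sgn_add <- if (side == "r") 1 else -1
  d2r <- pi / 180
  hip_R <- rot_z(ang$hip_flexion * d2r) %*% rot_x(sgn_add * ang$hip_adduction * d2r)
  knee_R <- rot_z(-ang$knee_flexion * d2r)
  ankle_R <- rot_z(ang$ankle_dorsiflexion * d2r)
  thigh_R <- pelvis_pose$rotation %*% hip_R
  hip_w <- pose_apply(pelvis_pose, model$hip_center_local[[side]])
  thigh <- list(rotation = thigh_R, origin = hip_w)
  knee_w <- pose_apply(thigh, c(0, -model$segment_lengths[["thigh"]], 0))
  shank <- list(rotation = thigh_R %*% knee_R, origin = knee_w)
  ankle_w <- pose_apply(shank, c(0, -model$segment_lengths[["shank"]], 0))
  foot <- list(rotation = shank$rotation %*% ankle_R, origin = ankle_w)
  list(thigh = thigh, shank = shank, foot = foot)
}

pelvis_pose_at <- function(tpl, t, cycle_time, speed) {
  if (tpl$static) {
    return(list(rotation = diag(3), origin = c(0, tpl$pelvis_height, 0)))
  }
  phase <- (t / cycle_time) %% 1
  org <- c(speed * t,
           tpl$pelvis_height + 0.015 * sin(4 * pi * phase),
           0.01 * sin(2 * pi * phase))
  R <- rot_y(4 * pi / 180 * sin(2 * pi * phase)) %*%
    rot_x(2 * pi / 180 * sin(2 * pi * phase))
  list(rotation = R, origin = org)
}

all_poses_at <- function(model, tpl, t, cycle_time, speed, lead_in) {
  pel <- pelvis_pose_at(tpl, t, cycle_time, speed)
  ph_r <- if (tpl$static) 0 else ((t - lead_in) / cycle_time) %% 1
  ph_l <- if (tpl$static) 0 else (ph_r + 0.5) %% 1
  right <- limb_poses_at(model, tpl, pel, ph_r, "r")
  left <- limb_poses_at(model, tpl, pel, ph_l, "l")
  list(pelvis = pel, trunk = pel,
       thigh_r = right$thigh, shank_r = right$shank, foot_r = right$foot,
       thigh_l = left$thigh, shank_l = left$shank, foot_l = left$foot)
}

#' Generate one synthetic gait trial
#'
#' Drives the scaled model through the template's joint-angle waveforms
#' (right heel strike at `lead_in` seconds, left offset by half a cycle),
#' samples the 37 markers at `marker_rate` with isotropic Gaussian noise, and
#' writes per-foot force-plate records (plate 1 = right foot, plate 2 = left)
#' at `plate_rate` with the template's double-hump vertical profile,
#' braking/propulsion and mediolateral shear, and a heel-to-toe COP path.
#'
#' @param model A `limb_model` for the subject.
#' @param template A `gait_template`.
#' @param seed Integer seed; identical seeds give bit-identical trials.
#' @param n_cycles Number of full gait cycles to generate.
#' @param marker_rate,plate_rate Sampling rates (Hz).
#' @return List with `markers` (a `marker_set`), `plates` (list of two
#'   `forceplate_record`s), `events_truth` (exact heel-strike/toe-off times
#'   per side) and the generation parameters.
#' @export
generate_trial <- function(model, template, seed = NULL, n_cycles = 2,
                           marker_rate = 100, plate_rate = 1000) {
  stopifnot(inherits(model, "limb_model"), inherits(template, "gait_template"))
  with_seed(seed, {
    tpl <- template
    cycle_time <- 120 / tpl$cadence
    speed <- if (tpl$static) 0 else tpl$stride_length / cycle_time
    lead_in <- 0.25 * cycle_time
    dur <- if (tpl$static) 2 else lead_in + n_cycles * cycle_time + 0.25 * cycle_time
    nf <- floor(dur * marker_rate) + 1
    tm <- (seq_len(nf) - 1) / marker_rate

    mk <- model$marker_local
    mk_by_seg <- split(seq_len(nrow(mk)), mk$segment)
    mk_local <- as.matrix(mk[, c("x", "y", "z")])
    pos <- array(NA_real_, c(nf, nrow(mk), 3))
    min_y <- Inf
    foot_idx <- which(mk$segment %in% c("foot_r", "foot_l"))
    for (f in seq_len(nf)) {
      poses <- all_poses_at(model, tpl, tm[f], cycle_time, speed, lead_in)
      for (s in names(mk_by_seg)) {
        i <- mk_by_seg[[s]]
        pos[f, i, ] <- pose_apply(poses[[s]], mk_local[i, , drop = FALSE])
      }
      min_y <- min(min_y, pos[f, foot_idx, 2])
    }
    if (min_y < -0.03) {
      stop("template is kinematically inconsistent: foot markers penetrate ",
           "the floor by ", signif(-min_y, 3), " m")
    }
    if (tpl$marker_noise_sd > 0) {
      pos <- pos + array(stats::rnorm(length(pos), 0, tpl$marker_noise_sd), dim(pos))
    }
    markers <- marker_set(mk$name, pos, marker_rate)

    bw <- model$body_mass * 9.81
    npf <- floor(dur * plate_rate) + 1
    tp <- (seq_len(npf) - 1) / plate_rate
    grf_shape <- stats::splinefun(tpl$grf_knot_t, tpl$grf_knot_bw,
                                  method = "monoH.FC")
    events <- list(r = list(heel_strike = numeric(0), toe_off = numeric(0)),
                   l = list(heel_strike = numeric(0), toe_off = numeric(0)))
    plates <- list()
    for (side in c("r", "l")) {
      force <- matrix(0, npf, 3)
      moment <- matrix(0, npf, 3)
      cop <- matrix(NA_real_, npf, 3)
      if (tpl$static) {
        force[, 2] <- bw / 2
        poses <- all_poses_at(model, tpl, 0, cycle_time, speed, lead_in)
        under <- pose_apply(poses[[paste0("foot_", side)]], c(0.05, -0.075, 0))
        cop[, 1] <- under[1]; cop[, 2] <- 0; cop[, 3] <- under[3]
        events[[side]]$heel_strike <- 0
      } else {
        offset <- if (side == "r") 0 else 0.5 * cycle_time
        stance_dur <- tpl$stance_fraction * cycle_time
        k <- 0
        repeat {
          hs <- lead_in + offset + k * cycle_time
          if (hs > dur) break
          {
            events[[side]]$heel_strike <- c(events[[side]]$heel_strike, hs)
            if (hs + stance_dur <= dur + 1e-9) {
              events[[side]]$toe_off <- c(events[[side]]$toe_off, hs + stance_dur)
            }
            sel <- which(tp >= hs & tp <= hs + stance_dur)
            sp <- (tp[sel] - hs) / stance_dur
            fy <- bw * grf_shape(sp)
            fx <- -tpl$ap_peak_bw * bw * sin(2 * pi * sp)
            ml_sign <- if (side == "r") -1 else 1   # medially directed shear
            fz <- ml_sign * tpl$ml_peak_bw * bw * sin(pi * sp)
            force[sel, 1] <- force[sel, 1] + fx
            force[sel, 2] <- force[sel, 2] + fy
            force[sel, 3] <- force[sel, 3] + fz
            med_sign <- if (side == "r") -1 else 1
            for (jj in seq_along(sel)) {
              tt <- tp[sel[jj]]
              pel <- pelvis_pose_at(tpl, tt, cycle_time, speed)
              ph <- ((tt - lead_in) / cycle_time + if (side == "l") 0.5 else 0) %% 1
              fp_pose <- limb_poses_at(model, tpl, pel, ph, side)$foot
              pt <- c(-0.04 + 0.18 * sp[jj], -0.075,
                      med_sign * tpl$cop_medial_offset)
              w <- pose_apply(fp_pose, pt)
              cop[sel[jj], ] <- c(w[1], 0, w[3])
            }
          }
          k <- k + 1
        }
      }
      plates[[length(plates) + 1]] <-
        forceplate_record(force, moment, cop, rate = plate_rate,
                          plate_id = if (side == "r") 1L else 2L)
    }
    list(markers = markers, plates = plates, events_truth = events,
         cycle_time = cycle_time, lead_in = lead_in, template = tpl)
  })
}

#' Generate a labeled synthetic cohort
#'
#' Draws per-subject anthropometry and gait variability (body mass, stature
#' scale, cadence, small joint-angle offsets and amplitude scaling) from
#' Gaussian distributions matching the study design this generator emulates
#' (default 10 "normal" and 11 "oa" subjects). OA-mode subjects get the
#' medial load-line offset (`severity`, m) together with the slaved sagittal
#' signatures: knee flexion contracture `150 * severity` degrees and flexion
#' range scaled by `1 - 3.75 * severity`; at `severity = 0` the two groups
#' are drawn from identical distributions.
#'
#' @param n_normal,n_oa Group sizes (>= 2 each).
#' @param severity Medial COP lever offset (m) for the OA group.
#' @param seed Integer seed for the whole cohort.
#' @param n_cycles Gait cycles per trial.
#' @param marker_noise_sd Marker noise SD (m).
#' @return List of subjects, each with `id`, `group`, `model`, `template`,
#'   and a generated `trial`; plus a `manifest` data frame.
#' @export
generate_cohort <- function(n_normal = 10, n_oa = 11, severity = 0.04,
                            seed = 1, n_cycles = 2, marker_noise_sd = 0.001) {
  if (n_normal < 2 || n_oa < 2) stop("at least 2 subjects per group")
  params <- load_model_parameters()
  group_stats <- list(normal = list(mass = c(58.5, 10.5), height = c(1.640, 0.054)),
                      oa = list(mass = c(73.1, 13.4), height = c(1.600, 0.080)))
  ref_height <- 1.70
  subjects <- list()
  labels <- c(rep("normal", n_normal), rep("oa", n_oa))
  with_seed(seed, {
    sub_seeds <- sample.int(2^30, length(labels))
    for (i in seq_along(labels)) {
      grp <- labels[i]
      gs <- group_stats[[grp]]
      mass <- max(40, stats::rnorm(1, gs$mass[1], gs$mass[2]))
      height <- max(1.40, stats::rnorm(1, gs$height[1], gs$height[2]))
      hscale <- height / ref_height
      lengths <- lapply(params$reference$segment_lengths, function(L) L * hscale)
      model <- build_scaled_model(mass, lengths, params = params)
      sev_i <- if (grp == "oa") severity else 0
      tpl <- gait_template(params,
                           cadence = stats::rnorm(1, 110, 5),
                           cop_medial_offset = sev_i,
                           knee_rom_scale = 1 - 3.75 * sev_i,
                           knee_contracture_deg = 150 * sev_i,
                           marker_noise_sd = marker_noise_sd)
      # subject-specific waveform idiosyncrasy: offset + amplitude scaling
      for (nm in names(tpl$angles)) {
        co <- tpl$angles[[nm]]
        co[1] <- co[1] + stats::rnorm(1, 0, 1.5)
        co[-1] <- co[-1] * stats::rnorm(1, 1, 0.05)
        tpl$angles[[nm]] <- co
      }
      tpl$pelvis_height <- params$gait_template$pelvis_height * hscale
      subjects[[i]] <- list(id = sprintf("S%02d", i), group = grp,
                            mass = mass, height = height, model = model,
                            template = tpl, seed = sub_seeds[i])
    }
  })
  for (i in seq_along(subjects)) {
    subjects[[i]]$trial <- generate_trial(subjects[[i]]$model,
                                          subjects[[i]]$template,
                                          seed = subjects[[i]]$seed,
                                          n_cycles = n_cycles)
  }
  manifest <- data.frame(
    id = vapply(subjects, `[[`, character(1), "id"),
    group = vapply(subjects, `[[`, character(1), "group"),
    mass = vapply(subjects, `[[`, numeric(1), "mass"),
    height = vapply(subjects, `[[`, numeric(1), "height"),
    seed = vapply(subjects, `[[`, numeric(1), "seed"))
  list(subjects = subjects, manifest = manifest, severity = severity, seed = seed)
}

#' Construct a known-optimum static-optimization fixture
#'
#' Picks Lagrange multipliers for the moment-balance constraints of one limb
#' at a reference standing pose, builds muscle forces from the KKT
#' stationarity form `F_i = A_i^(3/2) * sqrt(max(s_i, 0) / 3)` with
#' `s = t(Rm) %*% lambda`, and sets the required moments to `Rm %*% F`, so
#' the constructed forces are the unique optimum of the cubed-stress program.
#'
#' @param model A `limb_model`.
#' @param lambda Multiplier vector of length `length(dofs)`, or NULL to draw
#'   one randomly.
#' @param side `"r"` or `"l"`.
#' @param seed Seed for the random draw when `lambda` is NULL.
#' @param dofs Constrained DOF rows ([default_constrained_dofs()] unless
#'   given).
#' @return List with `Rm` (constrained rows of the unit-force moment
#'   matrix), `moments`, `forces_known` (26), `lambda`, `pcsa`, `fmax`, and
#'   muscle names; NULL (rejected) when any constructed force leaves its
#'   bounds.
#' @export
generate_consistency_fixture <- function(model, lambda = NULL, side = "r",
                                         seed = NULL,
                                         dofs = default_constrained_dofs()) {
  tpl <- gait_template(model$params, static = TRUE, marker_noise_sd = 0)
  poses <- all_poses_at(model, tpl, 0, 1, 0, 0)
  geo <- limb_moment_matrix(model, poses, side)
  Rm <- geo$Rm[dofs, , drop = FALSE]
  with_seed(seed, {
    if (is.null(lambda)) lambda <- stats::rnorm(length(dofs), 0, 40)
    stopifnot(length(lambda) == nrow(Rm))
    s <- as.vector(t(Rm) %*% lambda)
    F_known <- geo$pcsa^1.5 * sqrt(pmax(s, 0) / 3)
    if (any(F_known > 0.95 * geo$fmax)) return(NULL)
    list(Rm = Rm, moments = as.vector(Rm %*% F_known),
         forces_known = F_known, lambda = lambda,
         pcsa = geo$pcsa, fmax = geo$fmax, names = geo$names, side = side,
         dofs = dofs)
  })
}
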