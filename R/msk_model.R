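# Subject-scaled rigid-body model of the lower extremity: six limb segments
# (thigh, shank, foot per side) hanging off a pelvis base, three 3-DOF joints
# per limb, and 26 musculotendon units per limb with straight-line paths.

SEGMENT_ORDER <- c(pelvis = 0L, thigh = 1L, shank = 2L, foot = 3L)
JOINTS <- c("hip", "knee", "ankle")
KNEE_EXTENSORS <- c("VINT", "VLAT", "VMED", "RF")
KNEE_FLEXORS <- c("SM", "ST", "BFLH", "BFSH", "GASM", "GASL", "SAR", "GRA")

#' Load and validate the model parameter file
#'
#' Reads the YAML parameter file carrying the anthropometric fractions, hip
#' center regression coefficients, marker placement table, musculotendon table
#' and synthetic gait template, and validates its schema.
#'
#' @param path Path to a parameter YAML; defaults to the table shipped with
#'   the package.
#' @return A named list of validated parameter blocks.
#' @export
load_model_parameters <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "model_parameters.yaml", package = "oagait")
  }
  if (!file.exists(path)) stop("parameter file not found: ", path)
  p <- yaml::read_yaml(path)
  validate_model_parameters(p)
}

#' Validate a model parameter list
#'
#' Schema checks shared by [load_model_parameters()] and
#' [build_scaled_model()]; returns the list with the marker and muscle
#' blocks normalized to data frames.
#'
#' @param p Parameter list.
#' @return The validated parameter list.
#' @export
validate_model_parameters <- function(p) {
  required <- c("reference", "anthropometry", "hip_center_regression",
                "max_stress", "markers", "muscles", "gait_template")
  missing <- setdiff(required, names(p))
  if (length(missing) > 0) {
    stop("parameter file is missing blocks: ", paste(missing, collapse = ", "))
  }
  for (seg in c("pelvis", "thigh", "shank", "foot")) {
    if (is.null(p$reference$segment_lengths[[seg]])) {
      stop("reference segment length missing for: ", seg)
    }
    if (is.null(p$anthropometry[[seg]])) {
      stop("anthropometry row missing for: ", seg)
    }
  }
  mus <- p$muscles
  if (!is.data.frame(mus)) {
    mus <- do.call(rbind, lapply(p$muscles, function(m) {
      for (f in c("via_segment", "vx", "vy", "vz")) if (is.null(m[[f]])) m[[f]] <- NA
      as.data.frame(m, stringsAsFactors = FALSE)
    }))
  }
  if (nrow(mus) != 26) stop("muscle table must have 26 rows, found ", nrow(mus))
  if (anyDuplicated(mus$name)) stop("duplicate muscle names in table")
  if (any(mus$pcsa <= 0)) stop("all PCSA values must be positive")
  ext <- sort(mus$name[mus$group == "knee_extensor"])
  flx <- sort(mus$name[mus$group == "knee_flexor"])
  if (!identical(ext, sort(KNEE_EXTENSORS))) {
    stop("knee extensor group must be exactly: ",
         paste(KNEE_EXTENSORS, collapse = ", "))
  }
  if (!identical(flx, sort(KNEE_FLEXORS))) {
    stop("knee flexor group must be exactly: ",
         paste(KNEE_FLEXORS, collapse = ", "))
  }
  mk <- p$markers
  if (!is.data.frame(mk)) mk <- do.call(rbind, lapply(p$markers, as.data.frame))
  if (anyDuplicated(mk$name)) stop("duplicate marker names in table")
  if (nrow(mk) != 37) stop("marker table must have 37 rows, found ", nrow(mk))
  p$muscles <- mus
  p$markers <- mk
  p
}

mirror_z <- function(v) c(v[1], v[2], -v[3])

resolve_segment <- function(seg, side) {
  if (seg == "pelvis") "pelvis" else paste0(seg, "_", substr(side, 1, 1))
}

#' Build a subject-scaled lower-extremity model
#'
#' Scales the embedded reference model to a subject: segment masses by body
#' mass via Winter-style fractions, all local geometry (COM offsets, radii of
#' gyration, marker placements, muscle attachments, joint centers) linearly by
#' the ratio of subject to reference segment length (the pelvis scales by
#' inter-ASIS width). Maximum isometric muscle forces are `sigma * PCSA` with
#' the configured per-group stress overrides and age factor.
#'
#' @param body_mass Subject body mass (kg), > 0.
#' @param segment_lengths Named list/vector with entries `pelvis` (inter-ASIS
#'   width), `thigh`, `shank`, `foot` in meters. Defaults to the reference
#'   lengths (scale factors of one).
#' @param params Parameter list from [load_model_parameters()], or a path to a
#'   parameter YAML.
#' @param gravity Gravitational acceleration vector (m/s^2), lab frame.
#' @return An object of class `limb_model`: segments with inertial
#'   properties, joints, a 52-row muscle table (26 per side), scaled marker
#'   placements and the scaled hip-center offsets.
#' @export
build_scaled_model <- function(body_mass,
                               segment_lengths = NULL,
                               params = NULL,
                               gravity = c(0, -9.81, 0)) {
  if (!is.numeric(body_mass) || length(body_mass) != 1 || !is.finite(body_mass) ||
      body_mass <= 0) {
    stop("body_mass must be a positive finite scalar (kg)")
  }
  if (is.character(params) || is.null(params)) params <- load_model_parameters(params)
  params <- validate_model_parameters(params)
  ref_len <- unlist(params$reference$segment_lengths)
  if (is.null(segment_lengths)) segment_lengths <- as.list(ref_len)
  segment_lengths <- unlist(segment_lengths)
  for (seg in c("pelvis", "thigh", "shank", "foot")) {
    if (is.na(segment_lengths[seg])) {
      stop("segment length missing for: ", seg)
    }
    if (segment_lengths[seg] <= 0) stop("segment length must be positive for: ", seg)
  }
  scale <- segment_lengths[c("pelvis", "thigh", "shank", "foot")] /
    ref_len[c("pelvis", "thigh", "shank", "foot")]

  build_segment <- function(base, side = NULL) {
    an <- params$anthropometry[[base]]
    L <- unname(segment_lengths[base])
    m <- an$mass_fraction * body_mass
    rg_t <- an$rgyr_transverse * L
    rg_l <- an$rgyr_longitudinal * L
    inertia <- diag(m * c(rg_t^2, rg_l^2, rg_t^2))
    com <- c(0, -an$com_fraction * L, 0)
    name <- if (is.null(side)) base else paste0(base, "_", side)
    prox <- switch(base, pelvis = "root", thigh = "hip", shank = "knee", foot = "ankle")
    dist <- switch(base, pelvis = "hip", thigh = "knee", shank = "ankle", foot = "ground")
    list(name = name, base = base, side = side, mass = m, length = L,
         com_offset = com, inertia = inertia,
         proximal_joint = prox, distal_joint = dist)
  }
  segments <- list(pelvis = build_segment("pelvis"))
  for (side in c("r", "l")) {
    for (base in c("thigh", "shank", "foot")) {
      s <- build_segment(base, side)
      segments[[s$name]] <- s
    }
  }
  total <- sum(vapply(segments, `[[`, numeric(1), "mass"))
  if (abs(total - body_mass) > 1e-9) {
    stop("anthropometric mass fractions do not sum to 1 (total ",
         format(total / body_mass), ")")
  }

  # hip centers in the pelvis frame, Bell-style fractions of inter-ASIS width
  w <- unname(segment_lengths["pelvis"])
  hr <- params$hip_center_regression
  hjc <- list(r = c(hr$hjc_x * w, hr$hjc_y * w, hr$hjc_z * w),
              l = c(hr$hjc_x * w, hr$hjc_y * w, -hr$hjc_z * w))

  # scaled marker placement table (local coordinates)
  mk <- params$markers
  seg_scale_of <- function(segname) {
    base <- sub("_[rl]$", "", segname)
    if (base %in% names(scale)) unname(scale[base]) else unname(scale["pelvis"])
  }
  mk_scale <- vapply(mk$segment, seg_scale_of, numeric(1))
  marker_local <- data.frame(name = mk$name, segment = mk$segment,
                             x = mk$x * mk_scale, y = mk$y * mk_scale,
                             z = mk$z * mk_scale, stringsAsFactors = FALSE)

  # muscle table for both sides, attachments scaled per carrying segment
  sigma_of <- function(group) {
    s <- params$max_stress$default
    ov <- params$max_stress$overrides
    if (!is.null(ov[[group]])) s <- ov[[group]]
    s * params$max_stress$age_factor
  }
  # muscle strength scales with body size: volume ~ body mass, so
  # PCSA ~ mass / muscle length (limb-length scale)
  pcsa_scale <- (body_mass / params$reference$body_mass) /
    mean(scale[c("thigh", "shank")])
  mus <- params$muscles
  rows <- list()
  for (side in c("right", "left")) {
    for (i in seq_len(nrow(mus))) {
      m <- mus[i, ]
      o <- c(m$ox, m$oy, m$oz) * unname(scale[m$origin_segment])
      ins <- c(m$ix, m$iy, m$iz) * unname(scale[m$insertion_segment])
      has_via <- !is.na(m$via_segment)
      v <- if (has_via) c(m$vx, m$vy, m$vz) * unname(scale[m$via_segment]) else c(NA, NA, NA)
      if (side == "left") {
        o <- mirror_z(o); ins <- mirror_z(ins)
        if (has_via) v <- mirror_z(v)
      }
      sg <- sigma_of(m$group)
      rows[[length(rows) + 1]] <- data.frame(
        name = m$name, side = side,
        origin_segment = resolve_segment(m$origin_segment, side),
        ox = o[1], oy = o[2], oz = o[3],
        via_segment = if (has_via) resolve_segment(m$via_segment, side) else NA_character_,
        vx = v[1], vy = v[2], vz = v[3],
        insertion_segment = resolve_segment(m$insertion_segment, side),
        ix = ins[1], iy = ins[2], iz = ins[3],
        pcsa = m$pcsa * pcsa_scale, max_stress = sg,
        fmax = sg * m$pcsa * pcsa_scale,
        group = m$group, stringsAsFactors = FALSE)
    }
  }
  muscles <- do.call(rbind, rows)

  joints <- list()
  for (side in c("r", "l")) {
    joints[[paste0("hip_", side)]] <- list(
      name = paste0("hip_", side), parent = "pelvis",
      child = paste0("thigh_", side),
      center_local = hjc[[side]], center_frame = "pelvis")
    joints[[paste0("knee_", side)]] <- list(
      name = paste0("knee_", side), parent = paste0("thigh_", side),
      child = paste0("shank_", side),
      center_local = c(0, -unname(segment_lengths["thigh"]), 0),
      center_frame = paste0("thigh_", side))
    joints[[paste0("ankle_", side)]] <- list(
      name = paste0("ankle_", side), parent = paste0("shank_", side),
      child = paste0("foot_", side),
      center_local = c(0, -unname(segment_lengths["shank"]), 0),
      center_frame = paste0("shank_", side))
  }

  model <- structure(list(body_mass = body_mass, gravity = gravity,
                          segment_lengths = segment_lengths, scale = scale,
                          segments = segments, joints = joints, muscles = muscles,
                          hip_center_local = hjc, marker_local = marker_local,
                          params = params),
                     class = "limb_model")
  model$cache <- list(r = build_side_cache(model, "r"),
                      l = build_side_cache(model, "l"))
  model
}

#' @export
print.limb_model <- function(x, ...) {
  cat("Lower-extremity model:", length(x$segments), "segments,",
      nrow(x$muscles), "musculotendon units (", nrow(x$muscles) / 2, "per limb )\n")
  cat("  body mass:", x$body_mass, "kg; segment lengths (m):",
      paste(names(x$segment_lengths), round(x$segment_lengths, 3),
            sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Maximum isometric force of a musculotendon unit
#'
#' `sigma * PCSA`, with stress in N/cm^2 and PCSA in cm^2, giving newtons.
#'
#' @param muscle One row of a model's muscle table (or any list with `pcsa`
#'   and `max_stress`).
#' @return Maximum isometric force (N).
#' @export
max_isometric_force <- function(muscle) {
  if (muscle$pcsa <= 0) stop("pcsa must be positive")
  if (muscle$max_stress <= 0) stop("max_stress must be positive")
  muscle$pcsa * muscle$max_stress
}

#' Which muscles cross a given joint
#'
#' A muscle crosses a joint when its origin lies on or proximal to the
#' joint's parent segment and its insertion on or distal to the child, so
#' two-joint muscles (RF, hamstrings, gastrocnemii, SAR, GRA) contribute at
#' every joint their straight-line path spans.
#'
#' @param model A `limb_model`.
#' @param joint Joint label, e.g. `"knee_r"`.
#' @return Logical index into the model's muscle table.
#' @export
muscles_crossing <- function(model, joint) {
  j <- model$joints[[joint]]
  if (is.null(j)) stop("unknown joint: ", joint)
  side <- if (endsWith(joint, "_r")) "right" else "left"
  parent_rank <- SEGMENT_ORDER[[sub("_[rl]$", "", j$parent)]]
  mus <- model$muscles
  o_rank <- SEGMENT_ORDER[sub("_[rl]$", "", mus$origin_segment)]
  i_rank <- SEGMENT_ORDER[sub("_[rl]$", "", mus$insertion_segment)]
  mus$side == side & o_rank <= parent_rank & i_rank >= parent_rank + 1
}

#' World-frame joint centers for a set of segment poses
#'
#' @param model A `limb_model`.
#' @param poses Named list of poses (`rotation`, `origin`) per segment.
#' @return Named list of length-3 world positions, one per model joint.
#' @export
joint_centers_world <- function(model, poses) {
  out <- list()
  for (j in model$joints) {
    pose <- poses[[j$center_frame]]
    if (is.null(pose)) stop("pose missing for segment: ", j$center_frame)
    out[[j$name]] <- pose_apply(pose, j$center_local)
  }
  out
}

#' Muscle lines of action and moment arms about a joint
#'
#' Muscle paths are straight origin-to-insertion lines, except the four
#' quadriceps which route through a patellar via point on the distal thigh.
#' For each muscle crossing `joint`, the path segment spanning that joint
#' determines the geometry: the muscle pulls the segment's distal endpoint
#' toward its proximal endpoint, giving the unit force direction on the
#' distal bone, the position vector of the effective application point
#' relative to the joint center, and the unit-force moment `r x tau`.
#'
#' @param model A `limb_model`.
#' @param poses Named list of segment poses (`rotation`, `origin`).
#' @param joint Joint label, e.g. `"knee_r"`.
#' @return Data frame with one row per crossing muscle: `name`, `tau_*`
#'   (unit direction, lab frame), `r_*` (m), `marm_*` (`r x tau`, m) and
#'   `degenerate` (TRUE when the path endpoints coincide; such rows carry
#'   NA geometry).
#' @export
muscle_line_of_action <- function(model, poses, joint) {
  idx <- which(muscles_crossing(model, joint))
  centers <- joint_centers_world(model, poses)
  jc <- centers[[joint]]
  parent_rank <- SEGMENT_ORDER[[sub("_[rl]$", "", model$joints[[joint]]$parent)]]
  mus <- model$muscles[idx, ]
  n <- nrow(mus)
  out <- data.frame(name = mus$name, side = mus$side,
                    tau_x = NA_real_, tau_y = NA_real_, tau_z = NA_real_,
                    r_x = NA_real_, r_y = NA_real_, r_z = NA_real_,
                    marm_x = NA_real_, marm_y = NA_real_, marm_z = NA_real_,
                    degenerate = FALSE, stringsAsFactors = FALSE)
  for (k in seq_len(n)) {
    m <- mus[k, ]
    # endpoints of the path segment that spans this joint
    pw <- pose_apply(poses[[m$origin_segment]], c(m$ox, m$oy, m$oz))
    dw <- pose_apply(poses[[m$insertion_segment]], c(m$ix, m$iy, m$iz))
    if (!is.na(m$via_segment)) {
      via_rank <- SEGMENT_ORDER[[sub("_[rl]$", "", m$via_segment)]]
      vw <- pose_apply(poses[[m$via_segment]], c(m$vx, m$vy, m$vz))
      if (via_rank <= parent_rank) pw <- vw else dw <- vw
    }
    d <- pw - dw
    len <- sqrt(sum(d^2))
    if (len < 1e-9) {
      out$degenerate[k] <- TRUE
      next
    }
    tau <- d / len
    r <- dw - jc
    marm <- c(r[2] * tau[3] - r[3] * tau[2],
              r[3] * tau[1] - r[1] * tau[3],
              r[1] * tau[2] - r[2] * tau[1])
    out[k, c("tau_x", "tau_y", "tau_z")] <- tau
    out[k, c("r_x", "r_y", "r_z")] <- r
    out[k, c("marm_x", "marm_y", "marm_z")] <- marm
  }
  if (any(out$degenerate)) {
    warning("degenerate (coincident) muscle path for: ",
            paste(out$name[out$degenerate], collapse = ", "))
  }
  out
}

# Precomputed numeric views of one limb's muscle table, used by the
# vectorized per-frame geometry assembly (limb_moment_matrix): attachment
# coordinate matrices, carrying segments, joint-crossing masks and, per
# joint, which polyline segment spans it.
build_side_cache <- function(model, side) {
  side_long <- if (side == "r") "right" else "left"
  mus <- model$muscles[model$muscles$side == side_long, ]
  nm <- nrow(mus)
  rank_of <- function(s) SEGMENT_ORDER[sub("_[rl]$", "", s)]
  o_rank <- rank_of(mus$origin_segment)
  i_rank <- rank_of(mus$insertion_segment)
  has_via <- !is.na(mus$via_segment)
  v_rank <- ifelse(has_via, rank_of(ifelse(has_via, mus$via_segment, "pelvis")), NA)
  joints <- paste0(c("hip", "knee", "ankle"), "_", side)
  per_joint <- lapply(seq_along(joints), function(jk) {
    parent_rank <- jk - 1L   # pelvis 0, thigh 1, shank 2
    crossing <- o_rank <= parent_rank & i_rank >= parent_rank + 1L
    # polyline segment spanning the joint: default origin -> insertion,
    # replaced by the via-split half for routed muscles
    prox_seg <- mus$origin_segment
    prox_pt <- as.matrix(mus[, c("ox", "oy", "oz")])
    dist_seg <- mus$insertion_segment
    dist_pt <- as.matrix(mus[, c("ix", "iy", "iz")])
    use_prox_via <- has_via & !is.na(v_rank) & v_rank <= parent_rank
    use_dist_via <- has_via & !is.na(v_rank) & v_rank > parent_rank
    prox_seg[use_prox_via] <- mus$via_segment[use_prox_via]
    prox_pt[use_prox_via, ] <- as.matrix(mus[use_prox_via, c("vx", "vy", "vz")])
    dist_seg[use_dist_via] <- mus$via_segment[use_dist_via]
    dist_pt[use_dist_via, ] <- as.matrix(mus[use_dist_via, c("vx", "vy", "vz")])
    list(crossing = crossing, prox_seg = prox_seg, prox_pt = prox_pt,
         dist_seg = dist_seg, dist_pt = dist_pt)
  })
  names(per_joint) <- joints
  list(muscles = mus, per_joint = per_joint, pcsa = mus$pcsa,
       fmax = mus$fmax, names = mus$name, group = mus$group)
}

cross_rows <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

# world coordinates of per-muscle local points carried by named segments
world_points <- function(poses, seg_names, pts) {
  out <- matrix(NA_real_, nrow(pts), 3)
  for (s in unique(seg_names)) {
    i <- seg_names == s
    out[i, ] <- pose_apply(poses[[s]], pts[i, , drop = FALSE])
  }
  out
}

#' Musculotendon path length at a pose (polyline through any via point)
#' @keywords internal
muscle_length_world <- function(model, poses, muscle_row) {
  m <- muscle_row
  pts <- list(pose_apply(poses[[m$origin_segment]], c(m$ox, m$oy, m$oz)))
  if (!is.na(m$via_segment)) {
    pts <- c(pts, list(pose_apply(poses[[m$via_segment]], c(m$vx, m$vy, m$vz))))
  }
  pts <- c(pts, list(pose_apply(poses[[m$insertion_segment]], c(m$ix, m$iy, m$iz))))
  sum(vapply(seq_len(length(pts) - 1),
             function(i) sqrt(sum((pts[[i + 1]] - pts[[i]])^2)), numeric(1)))
}
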