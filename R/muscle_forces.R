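# Static optimization of the muscle redundancy problem, per cycle point:
#
#   minimize   sum_i (F_i / A_i)^3
#   subject to sum_i F_i (r_i x tau_i) = M_e   on all 9 rotational DOF
#              0 <= F_i <= sigma_i A_i         for the 26 muscles of the limb
#
# The program is smooth and strictly convex on its feasible set, so the
# KKT system characterizes the unique optimum: with multipliers lambda on
# the moment constraints and s = t(Rm) %*% lambda,
#   F_i(lambda) = clip( A_i^(3/2) * sqrt(max(s_i, 0) / 3), 0, fmax_i ).
# The solver finds lambda with a damped semismooth Newton iteration on the
# constraint residual M_e - Rm F(lambda) (an exponent-2 warm start seeds
# lambda), falling back to BFGS ascent of the concave dual; time points
# whose demanded moment exceeds muscle capacity are flagged and resolved by
# bounded least-squares on the residual instead (bounds are never relaxed).

DOF_NAMES <- c("hip_x", "hip_y", "hip_z", "knee_x", "knee_y", "knee_z",
               "ankle_x", "ankle_y", "ankle_z")

#' Default constrained degrees of freedom
#'
#' All three hip DOF, knee flexion and knee ad/abduction (the frontal-plane
#' constraint that couples the adduction moment into muscle recruitment),
#' and ankle plantar/dorsiflexion. Tibiofemoral and talocrural axial
#' rotation and subtalar inversion are left to passive joint structures: the
#' 26-muscle set contains no evertors or dedicated axial rotators, so those
#' moments are not muscularly actuated in this model.
#'
#' @return Integer indices into the 9 rows (hip x/y/z, knee x/y/z, ankle
#'   x/y/z) of [limb_moment_matrix()].
#' @export
default_constrained_dofs <- function() {
  match(c("hip_x", "hip_y", "hip_z", "knee_x", "knee_z", "ankle_z"), DOF_NAMES)
}

#' Unit-force moment matrix of one limb at a pose
#'
#' Stacks the `r x tau` unit-force moment vectors of all 26 muscles of one
#' limb into a 9 x 26 matrix (rows: hip x/y/z, knee x/y/z, ankle x/y/z; a
#' muscle's column is zero at joints it does not cross).
#'
#' @param model A `limb_model`.
#' @param poses Named list of per-segment poses at one instant.
#' @param side `"r"` or `"l"`.
#' @return List: `Rm` (9 x 26), `tau` per joint (rows aligned with `names`),
#'   `pcsa`, `fmax`, `names`, `group`.
#' @export
limb_moment_matrix <- function(model, poses, side) {
  cache <- model$cache[[side]]
  nm <- length(cache$names)
  Rm <- matrix(0, 9, nm)
  tau <- list()
  centers <- joint_centers_world(model, poses)
  joints <- paste0(c("hip", "knee", "ankle"), "_", side)
  for (jk in seq_along(joints)) {
    pj <- cache$per_joint[[joints[jk]]]
    cr <- pj$crossing
    P <- world_points(poses, pj$prox_seg[cr], pj$prox_pt[cr, , drop = FALSE])
    D <- world_points(poses, pj$dist_seg[cr], pj$dist_pt[cr, , drop = FALSE])
    d <- P - D
    len <- sqrt(rowSums(d^2))
    if (anyNA(len)) {
      stop("segment poses contain missing values at this frame; ",
           "muscle geometry is undefined")
    }
    if (any(len < 1e-9)) {
      warning("degenerate muscle path for: ",
              paste(cache$names[cr][len < 1e-9], collapse = ", "))
      len[len < 1e-9] <- NA_real_
    }
    tu <- d / len
    r <- D - matrix(centers[[joints[jk]]], sum(cr), 3, byrow = TRUE)
    marm <- cross_rows(r, tu)
    marm[is.na(marm)] <- 0
    Rm[3 * (jk - 1) + 1:3, cr] <- t(marm)
    tmat <- matrix(0, nm, 3)
    tmat[cr, ] <- tu
    tmat[is.na(tmat)] <- 0
    tau[[sub("_[rl]$", "", joints[jk])]] <- tmat
  }
  list(Rm = Rm, tau = tau, pcsa = cache$pcsa, fmax = cache$fmax,
       names = cache$names, group = cache$group)
}

forces_from_lambda <- function(lambda, Rm, pcsa, fmax) {
  s <- as.vector(crossprod(Rm, lambda))
  pmin(pcsa^1.5 * sqrt(pmax(s, 0) / 3), fmax)
}

#' Solve the cubed-stress static optimization at one time point
#'
#' @param Rm Unit-force moment matrix (n_dof x n_muscles), e.g. from
#'   [limb_moment_matrix()] (or a 1-row matrix for toy problems).
#' @param moments Required net moments, length `nrow(Rm)` (N m).
#' @param pcsa PCSA per muscle (cm^2).
#' @param fmax Upper force bound per muscle (N), `sigma * pcsa`.
#' @param lambda0 Optional multiplier warm start.
#' @param tol Relative constraint tolerance: converged when
#'   `||Rm F - M|| <= tol * (1 + ||M||)`.
#' @param max_iter Newton iteration cap.
#' @return List: `forces` (N), `activation` (`F / fmax`), `objective`,
#'   `lambda`, `residual` (norm of the moment-balance defect),
#'   `stationarity` (max KKT stationarity defect over interior muscles) and
#'   `status` (`"converged"` or `"infeasible"`).
#' @export
solve_static_optimization <- function(Rm, moments, pcsa, fmax,
                                      lambda0 = NULL, tol = 1e-8,
                                      max_iter = 200) {
  Rm <- as.matrix(Rm)
  nd <- nrow(Rm); nm <- ncol(Rm)
  stopifnot(length(moments) == nd, length(pcsa) == nm, length(fmax) == nm)
  Mn <- sqrt(sum(moments^2))
  target <- function(lam) {
    FF <- forces_from_lambda(lam, Rm, pcsa, fmax)
    moments - as.vector(Rm %*% FF)
  }
  # exponent-2 warm start: F = s * A^2 / 2 gives a linear system for lambda
  if (is.null(lambda0)) {
    A2 <- pcsa^2 / 2
    G <- Rm %*% (t(Rm) * A2)
    lambda0 <- tryCatch(solve(G + diag(1e-9 * max(diag(G), 1), nd), moments),
                        error = function(e) rep(0, nd))
  }
  lam <- lambda0
  phi <- target(lam)
  best <- list(lambda = lam, norm = sqrt(sum(phi^2)))
  mu <- 1e-8
  for (it in seq_len(max_iter)) {
    if (best$norm <= tol * (1 + Mn)) break
    s <- as.vector(crossprod(Rm, lam))
    Fi <- pcsa^1.5 * sqrt(pmax(s, 0) / 3)
    interior <- s > 1e-14 & Fi < fmax
    d <- numeric(nm)
    d[interior] <- pcsa[interior]^1.5 / (2 * sqrt(3 * s[interior]))
    J <- Rm %*% (t(Rm) * d)
    step <- tryCatch(solve(J + diag(mu + 1e-12, nd), phi),
                     error = function(e) NULL)
    if (is.null(step)) { mu <- max(mu * 10, 1e-6); next }
    improved <- FALSE
    alpha <- 1
    for (ls in 1:30) {
      lam_try <- lam + alpha * step
      phi_try <- target(lam_try)
      if (sqrt(sum(phi_try^2)) < best$norm * (1 - 1e-4 * alpha)) {
        lam <- lam_try; phi <- phi_try
        best <- list(lambda = lam, norm = sqrt(sum(phi^2)))
        mu <- max(mu / 5, 1e-12)
        improved <- TRUE
        break
      }
      alpha <- alpha / 2
    }
    if (!improved) {
      mu <- mu * 10
      if (mu > 1e4) break
    }
  }
  if (best$norm > tol * (1 + Mn)) {
    # fall back to BFGS ascent of the concave dual
    dual <- function(lam) {
      FF <- forces_from_lambda(lam, Rm, pcsa, fmax)
      -(sum((FF / pcsa)^3) + sum(lam * (moments - as.vector(Rm %*% FF))))
    }
    dual_grad <- function(lam) {
      FF <- forces_from_lambda(lam, Rm, pcsa, fmax)
      -(moments - as.vector(Rm %*% FF))
    }
    opt <- stats::optim(best$lambda, dual, dual_grad, method = "BFGS",
                        control = list(maxit = 500, reltol = 1e-15))
    phi_o <- target(opt$par)
    if (sqrt(sum(phi_o^2)) < best$norm) {
      best <- list(lambda = opt$par, norm = sqrt(sum(phi_o^2)))
    }
  }
  lam <- best$lambda
  FF <- forces_from_lambda(lam, Rm, pcsa, fmax)
  status <- if (best$norm <= tol * (1 + Mn)) "converged" else "infeasible"
  if (status == "infeasible") {
    # demanded moment beyond capacity: minimize the moment defect over the
    # box instead (never relax the bounds), keep the flag
    ls_obj <- function(f) { r <- as.vector(Rm %*% f) - moments; sum(r^2) }
    ls_grad <- function(f) as.vector(2 * crossprod(Rm, as.vector(Rm %*% f) - moments))
    opt <- stats::optim(FF, ls_obj, ls_grad, method = "L-BFGS-B",
                        lower = rep(0, nm), upper = fmax,
                        control = list(maxit = 500, factr = 1e4))
    FF <- opt$par
  }
  s <- as.vector(crossprod(Rm, lam))
  interior <- FF > 1e-9 & FF < fmax - 1e-9
  stat_res <- if (any(interior)) {
    max(abs(3 * FF[interior]^2 / pcsa[interior]^3 - s[interior]))
  } else 0
  list(forces = FF, activation = FF / fmax,
       objective = sum((FF / pcsa)^3), lambda = lam,
       residual = sqrt(sum((as.vector(Rm %*% FF) - moments)^2)),
       stationarity = stat_res, status = status)
}

#' Solve the muscle redundancy problem over a normalized cycle
#'
#' Runs [solve_static_optimization()] at each cycle point of one limb,
#' assembling the 9-DOF moment constraints from the per-point geometry and
#' net joint moments, warm-starting each point from the previous multiplier.
#'
#' @param geometry List of per-point outputs of [limb_moment_matrix()].
#' @param moments Matrix n_points x 9 of net joint moments (hip, knee, ankle
#'   x/y/z, lab frame, N m).
#' @param tol Constraint tolerance, as in [solve_static_optimization()].
#' @param dofs Indices of the constrained DOF rows
#'   ([default_constrained_dofs()] unless given).
#' @return Object of class `muscle_solution`: `forces` and `activation`
#'   (n_points x 26), `residual`, `status`, `objective` per point, muscle
#'   `names` and `group`, and the per-point `geometry` (full 9-row moment
#'   matrices) for downstream metrics.
#' @export
solve_cycle <- function(geometry, moments, tol = 1e-8,
                        dofs = default_constrained_dofs()) {
  np <- length(geometry)
  stopifnot(nrow(moments) == np, ncol(moments) == 9)
  nm <- length(geometry[[1]]$names)
  forces <- matrix(NA_real_, np, nm)
  activation <- matrix(NA_real_, np, nm)
  residual <- numeric(np); objective <- numeric(np)
  status <- character(np)
  lam <- NULL
  for (p in seq_len(np)) {
    geo <- geometry[[p]]
    Rm <- geo$Rm[dofs, , drop = FALSE]
    sol <- solve_static_optimization(Rm, moments[p, dofs], geo$pcsa, geo$fmax,
                                     lambda0 = lam, tol = tol)
    if (sol$status != "converged") {
      # retry from a cold start before accepting the flag
      sol2 <- solve_static_optimization(Rm, moments[p, dofs], geo$pcsa,
                                        geo$fmax, lambda0 = NULL, tol = tol)
      if (sol2$residual < sol$residual) sol <- sol2
    }
    forces[p, ] <- sol$forces
    activation[p, ] <- sol$activation
    residual[p] <- sol$residual
    objective[p] <- sol$objective
    status[p] <- sol$status
    lam <- if (sol$status == "converged") sol$lambda else NULL
  }
  colnames(forces) <- geometry[[1]]$names
  colnames(activation) <- geometry[[1]]$names
  structure(list(forces = forces, activation = activation,
                 residual = residual, objective = objective, status = status,
                 names = geometry[[1]]$names, group = geometry[[1]]$group,
                 geometry = geometry, dofs = dofs),
            class = "muscle_solution")
}

#' Knee joint contact force and its anatomical components
#'
#' Applies the joint force balance: the contact (bone-on-bone) force is the
#' net intersegmental force minus the summed muscle force vectors of the
#' muscles crossing the knee, `F_j = F_e - sum_i F_i tau_i`. Components are
#' reported in the shank anatomical frame with the conventions: axial
#' component positive = tensile (stance values are negative, compressive);
#' mediolateral positive = medial; anteroposterior positive = posterior.
#'
#' @param net_F Matrix n_points x 3, net knee force, lab frame (N).
#' @param solution A `muscle_solution` for the limb.
#' @param shank_rot Array n_points x 3 x 3 of shank rotations.
#' @param side `"r"` or `"l"`.
#' @param body_weight Body weight (N) for the BW-normalized view.
#' @return Object of class `joint_contact_force`: `F_lab` (n x 3),
#'   `components` (n x 3: `compressive`, `ml`, `ap`), and `components_bw`.
#' @export
joint_contact_force <- function(net_F, solution, shank_rot, side,
                                body_weight) {
  np <- nrow(net_F)
  Fj <- matrix(NA_real_, np, 3)
  comp <- matrix(NA_real_, np, 3)
  colnames(comp) <- c("compressive", "ml", "ap")
  ml_sign <- if (side == "r") -1 else 1   # +Z is the subject's right
  for (p in seq_len(np)) {
    tau <- solution$geometry[[p]]$tau$knee
    msum <- as.vector(t(tau) %*% solution$forces[p, ])
    Fj[p, ] <- net_F[p, ] - msum
    R <- matrix(shank_rot[p, , ], 3, 3)
    fl <- as.vector(t(R) %*% Fj[p, ])
    comp[p, ] <- c(fl[2], ml_sign * fl[3], -fl[1])
  }
  structure(list(F_lab = Fj, components = comp,
                 components_bw = comp / body_weight,
                 body_weight = body_weight, side = side),
            class = "joint_contact_force")
}

#' Peak contact-force components over the cycle
#'
#' The compressive peak is the largest compressive magnitude (positive
#' number, in body weights, as customarily tabulated); the mediolateral and
#' anteroposterior peaks are the signed extrema of largest magnitude
#' (medial/posterior positive).
#'
#' @param jcf A `joint_contact_force`.
#' @return Named numeric: `compressive`, `ml`, `ap`, in BW.
#' @export
peak_components <- function(jcf) {
  x <- jcf$components_bw
  signed_extremum <- function(v) v[which.max(abs(v))]
  c(compressive = max(pmax(-x[, "compressive"], 0)),
    ml = signed_extremum(x[, "ml"]),
    ap = signed_extremum(x[, "ap"]))
}
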