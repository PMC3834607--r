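# Cocontraction metrics (EFAR/EFTR), normalized muscle force summaries, and
# the two-sample statistics used for group comparison.

#' Knee extensor/flexor cocontraction metrics
#'
#' Per cycle point, sums activations over the four knee extensors (VINT,
#' VLAT, VMED, RF) and the eight knee flexors (SM, ST, BFLH, BFSH, GASM,
#' GASL, SAR, GRA), and sums the magnitudes of each muscle's knee
#' flexion-axis torque contribution `F_i * (marm_i . z_knee)`. EFAR and EFTR
#' are the extensor/flexor ratios of these sums. Pointwise ratios are
#' flagged undefined when the denominator falls below `floor`; the cycle
#' summary is the ratio of cycle means, which stays finite through near-zero
#' flexor phases.
#'
#' @param solution A `muscle_solution` for one limb over a cycle.
#' @param knee_axis n_points x 3 matrix, the knee flexion axis (shank frame Z
#'   in lab coordinates) per point.
#' @param floor Smallest denominator for a defined pointwise ratio.
#' @return Object of class `cocontraction_metrics`: per-point sums `A_e`,
#'   `A_f`, `T_e`, `T_f` (torques in N m), pointwise `efar`/`eftr` series
#'   (NA where undefined), and scalar summaries `efar`, `eftr` (ratios of
#'   cycle means).
#' @export
cocontraction_ratios <- function(solution, knee_axis, floor = 1e-6) {
  ext <- solution$group == "knee_extensor"
  flx <- solution$group == "knee_flexor"
  if (sum(ext) != 4 || sum(flx) != 8) {
    stop("expected 4 knee extensors and 8 knee flexors in the solution")
  }
  np <- nrow(solution$activation)
  A_e <- rowSums(solution$activation[, ext, drop = FALSE])
  A_f <- rowSums(solution$activation[, flx, drop = FALSE])
  T_e <- numeric(np); T_f <- numeric(np)
  for (p in seq_len(np)) {
    marm_knee <- solution$geometry[[p]]$Rm[4:6, ]       # knee rows of r x tau
    t_flex <- abs(as.vector(knee_axis[p, ] %*% marm_knee)) * solution$forces[p, ]
    T_e[p] <- sum(t_flex[ext]); T_f[p] <- sum(t_flex[flx])
  }
  ratio_series <- function(num, den) ifelse(den >= floor, num / den, NA_real_)
  structure(list(A_e = A_e, A_f = A_f, T_e = T_e, T_f = T_f,
                 efar_series = ratio_series(A_e, A_f),
                 eftr_series = ratio_series(T_e, T_f),
                 efar = mean(A_e) / max(mean(A_f), floor),
                 eftr = mean(T_e) / max(mean(T_f), floor)),
            class = "cocontraction_metrics")
}

#' Cycle-mean normalized muscle force
#'
#' Mean over the normalized cycle of `F / (sigma * PCSA)`, the muscle force
#' scaled to its maximum isometric force (the "activation" tabulated per
#' muscle).
#'
#' @param solution A `muscle_solution`.
#' @param muscle Muscle name (one of the 26 abbreviations).
#' @return Dimensionless mean in `[0, 1]`.
#' @export
mean_normalized_muscle_force <- function(solution, muscle) {
  i <- match(muscle, solution$names)
  if (is.na(i)) stop("unknown muscle: ", muscle)
  mean(solution$activation[, i])
}

#' Two-sample t test between groups
#'
#' Welch's unequal-variance test by default (pooled-variance optional).
#' Degenerate input with zero variance in both groups and equal means
#' returns `t = 0, P = 1` by convention.
#'
#' @param a,b Numeric vectors, length >= 2 each.
#' @param var_equal Use the pooled-variance test.
#' @return List: `t`, `p`, `df`, `mean_a`, `mean_b`.
#' @export
independent_t_test <- function(a, b, var_equal = FALSE) {
  if (length(a) < 2 || length(b) < 2) stop("need at least 2 values per group")
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    if (mean(a) == mean(b)) {
      message("degenerate t test: both groups constant and equal; P = 1")
      return(list(t = 0, p = 1, df = length(a) + length(b) - 2,
                  mean_a = mean(a), mean_b = mean(b)))
    }
    return(list(t = Inf * sign(mean(a) - mean(b)), p = 0,
                df = length(a) + length(b) - 2,
                mean_a = mean(a), mean_b = mean(b)))
  }
  ht <- stats::t.test(a, b, var.equal = var_equal)
  list(t = unname(ht$statistic), p = ht$p.value,
       df = unname(ht$parameter), mean_a = mean(a), mean_b = mean(b))
}

#' Pearson correlation with two-sided P value
#'
#' @param x,y Numeric series of equal length >= 3.
#' @return List: `r`, `p`, `n`; zero-variance input yields `r = NA` with a
#'   warning.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("series must have equal length")
  if (length(x) < 3) stop("need at least 3 points")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("zero variance: correlation undefined")
    return(list(r = NA_real_, p = NA_real_, n = length(x)))
  }
  ht <- stats::cor.test(x, y)
  list(r = unname(ht$estimate), p = ht$p.value, n = length(x))
}
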