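#' Default force-length relation
#'
#' Piecewise-linear tent reflecting actin-myosin filament overlap: zero below
#' the ascending-limb limit, a plateau of 1 around the optimal stretch, and a
#' linear descending limb reaching zero where overlap is lost. Because overlap
#' counts available cross-bridges, this curve scales the active stress and is
#' not a hyperelastic stress-stretch relation.
#'
#' @param lambda_f fiber stretch (dimensionless), vectorized.
#' @param lambda_opt optimal stretch (plateau center), default 1.
#' @param plateau_halfwidth half-width of the unit plateau, default 0.055.
#' @param lambda_min stretch below which overlap (and force) is zero.
#' @param lambda_max stretch above which overlap is zero.
#' @return values in `[0, 1]`; exactly 1 on the plateau.
#' @export
default_force_length <- function(lambda_f, lambda_opt = 1,
                                 plateau_halfwidth = 0.055,
                                 lambda_min = 0.5, lambda_max = 1.8) {
  lo <- lambda_opt - plateau_halfwidth
  hi <- lambda_opt + plateau_halfwidth
  f <- ifelse(lambda_f <= lambda_min | lambda_f >= lambda_max, 0,
       ifelse(lambda_f < lo, (lambda_f - lambda_min) / (lo - lambda_min),
       ifelse(lambda_f <= hi, 1,
              (lambda_max - lambda_f) / (lambda_max - hi))))
  pmax(f, 0)
}

#' Default force-velocity relation
#'
#' Hill hyperbola on the shortening side, normalized so the isometric value is
#' `f_v(0) = 1` and force vanishes at the maximal shortening rate; a saturating
#' eccentric branch rising towards `f_ecc` for lengthening. The rate convention
#' is `rate = d(lambda_f)/dt`: negative while shortening.
#'
#' @param rate fiber stretch rate (1/s), vectorized; negative = shortening.
#' @param v_max maximal shortening rate (1/s), default 10.
#' @param curvature Hill curvature parameter `a/P0`, default 0.25.
#' @param f_ecc eccentric force plateau (>= 1), default 1.4.
#' @return non-negative values with `f_v(0) = 1`.
#' @export
default_force_velocity <- function(rate, v_max = 10, curvature = 0.25,
                                   f_ecc = 1.4) {
  conc <- pmax(1 + rate / v_max, 0) / (1 - rate / (curvature * v_max))
  ecc <- (1 + f_ecc * rate / (curvature * v_max)) /
    (1 + rate / (curvature * v_max))
  ifelse(rate <= 0, conc, ecc)
}

#' Phenomenological active state
#'
#' The Hill-type active state: maximum isometric nominal stress `P_max`, a
#' lumped activation `alpha` in `[0, 1]`, and dimensionless force-length and
#' force-velocity curves.
#'
#' @param P_max maximum isometric nominal stress in Pa (default 25 N cm^-2).
#' @param alpha activation level in `[0, 1]`.
#' @param fl_curve function of fiber stretch, `fl_curve(lambda_opt) = 1`.
#' @param fv_curve function of fiber stretch rate, `fv_curve(0) = 1`.
#' @return object of class `phen_active_state`.
#' @export
phen_active_state <- function(P_max = 25e4, alpha = 1,
                              fl_curve = default_force_length,
                              fv_curve = default_force_velocity) {
  alpha <- as.numeric(alpha)
  if (!is.finite(alpha) || alpha < 0 || alpha > 1)
    stop("alpha must lie in [0, 1]", call. = FALSE)
  if (P_max < 0) stop("P_max must be non-negative", call. = FALSE)
  stopifnot(is.function(fl_curve), is.function(fv_curve))
  structure(list(P_max = as.numeric(P_max), alpha = alpha,
                 fl_curve = fl_curve, fv_curve = fv_curve),
            class = "phen_active_state")
}

#' Scalar active stress of the phenomenological law
#'
#' `P_a = P_max * f_l(lambda_f) * f_v(rate) * alpha`.
#'
#' @param state a [phen_active_state()].
#' @param lambda_f fiber stretch.
#' @param lambda_f_rate fiber stretch rate (1/s).
#' @return scalar nominal stress in Pa, non-negative for the default curves.
#' @export
active_scalar <- function(state, lambda_f, lambda_f_rate = 0) {
  stopifnot(inherits(state, "phen_active_state"))
  state$P_max * state$fl_curve(lambda_f) * state$fv_curve(lambda_f_rate) *
    state$alpha
}

#' Phenomenological active-stress tensor
#'
#' Maps the scalar active stress onto the deformed fiber direction:
#' `P_a = active_scalar * F %*% (a0f %o% a0f)`. The result has rank at most
#' one and acts along the push-forward of the fiber axis.
#'
#' @param F 3x3 deformation gradient.
#' @param arch a [fiber_architecture()].
#' @param state a [phen_active_state()].
#' @param lambda_f_rate fiber stretch rate passed to the force-velocity curve.
#' @return 3x3 first Piola-Kirchhoff active-stress tensor (Pa).
#' @export
active_stress_phenomenological <- function(F, arch, state, lambda_f_rate = 0) {
  check_deformation_gradient(F)
  s <- active_scalar(state, fiber_stretch(F, arch), lambda_f_rate)
  s * (F %*% structural_tensor(arch))
}

#' Cross-bridge population
#'
#' A population of attached cross-bridges, each a linear molecular spring of
#' stiffness `k_xb` with elongation `x[i]`, together with the geometry that
#' homogenizes their forces over a half-sarcomere unit cell of the hexagonal
#' filament lattice: the force-transmission angle `phi` (measured from the
#' fiber axis), the fiber-normal cross-sectional area `A_f_ref` of the
#' reference volume, and `A_xf_ref`, one sixth of its mantle surface.
#'
#' @param k_xb cross-bridge stiffness (N/m), positive.
#' @param x numeric vector of elongations (m); may be empty; signed values
#'   are allowed (post-powerstroke compression).
#' @param phi transmission angle in radians, in `(0, pi/2)`.
#' @param A_f_ref fiber-normal reference area (m^2), positive.
#' @param A_xf_ref one sixth of the reference-volume mantle surface (m^2).
#' @return object of class `crossbridge_population`.
#' @export
crossbridge_population <- function(k_xb, x, phi, A_f_ref, A_xf_ref) {
  if (k_xb <= 0) stop("k_xb must be positive", call. = FALSE)
  if (A_f_ref <= 0 || A_xf_ref <= 0)
    stop("reference areas must be positive", call. = FALSE)
  if (phi <= 0 || phi >= pi / 2)
    stop("phi must lie in (0, pi/2)", call. = FALSE)
  x <- as.numeric(x)
  if (length(x) && !all(is.finite(x)))
    stop("elongations must be finite", call. = FALSE)
  structure(list(k_xb = as.numeric(k_xb), x = x, phi = as.numeric(phi),
                 A_f_ref = as.numeric(A_f_ref),
                 A_xf_ref = as.numeric(A_xf_ref)),
            class = "crossbridge_population")
}

#' @export
print.crossbridge_population <- function(x, ...) {
  cat("crossbridge_population:", length(x$x), "attached bridges\n")
  cat("  k_xb =", format(x$k_xb), "N/m; phi =",
      format(x$phi * 180 / pi, digits = 4), "deg\n")
  cat("  A_f_ref =", format(x$A_f_ref), "m^2; A_xf_ref =",
      format(x$A_xf_ref), "m^2\n")
  if (length(x$x))
    cat("  sum(k x) =", format(x$k_xb * sum(x$x)), "N\n")
  invisible(x)
}

#' Read cross-bridge elongations from CSV
#'
#' One-column CSV (header `x`, values in meters) as produced by
#' [generate_population()] exports.
#'
#' @param path CSV file path.
#' @return numeric vector of elongations (m).
#' @export
read_elongations_csv <- function(path) {
  df <- utils::read.csv(path, comment.char = "#")
  if (!"x" %in% names(df))
    stop("elongation CSV must have a column named 'x'", call. = FALSE)
  as.numeric(df$x)
}

#' Total elastic energy stored in the cross-bridge population
#'
#' `sum_i k_xb x_i^2 / 2` over all attached bridges (Joules).
#'
#' @param pop a [crossbridge_population()].
#' @return scalar energy, >= 0; zero for an empty population.
#' @export
xb_energy <- function(pop) {
  stopifnot(inherits(pop, "crossbridge_population"))
  if (!length(pop$x)) return(0)
  sum(0.5 * pop$k_xb * pop$x^2)
}

#' Force of a single cross-bridge
#'
#' The linear-spring force `k_xb * x_i` (signed, Newtons); the partial
#' derivative of the population energy with respect to the elongation.
#'
#' @param k_xb spring stiffness (N/m).
#' @param x_i elongation (m), vectorized.
#' @return force(s) in N.
#' @export
xb_force <- function(k_xb, x_i) k_xb * x_i

# net population spring force along the bridge axis (N)
xb_population_force <- function(pop) {
  if (!length(pop$x)) return(0)
  pop$k_xb * sum(pop$x)
}

#' Homogenized fiber-direction active stress
#'
#' `P_a^f = cos(phi)/A_f_ref * sum(k_xb x_i) * F %*% (a0f %o% a0f)`:
#' the fiber-axis component of all cross-bridge spring forces divided by the
#' fiber-normal reference area, mapped along the deformed fiber direction.
#'
#' @param pop a [crossbridge_population()].
#' @param F 3x3 deformation gradient.
#' @param arch a [fiber_architecture()].
#' @return 3x3 nominal stress tensor (Pa).
#' @export
fiber_active_stress <- function(pop, F, arch) {
  check_deformation_gradient(F)
  s <- cos(pop$phi) / pop$A_f_ref * xb_population_force(pop)
  s * (F %*% structural_tensor(arch))
}

#' Hexagonal lattice transmission directions
#'
#' The six transverse unit vectors of the hexagonal filament lattice,
#' `t_n = cos(phi_lattice + (n-1) pi/3) e2 + sin(phi_lattice + (n-1) pi/3) e3`,
#' pointing from the central myosin filament towards its six surrounding actin
#' filaments. They satisfy `sum_n t_n %o% t_n = 3 (I - a0f %o% a0f)` for any
#' lattice angle.
#'
#' @param arch a [fiber_architecture()] (uses `e2`, `e3`, `phi_lattice`).
#' @return 3x6 matrix; column `n` is `t_n`.
#' @export
crossfiber_directions <- function(arch) {
  stopifnot(inherits(arch, "fiber_architecture"))
  ang <- arch$phi_lattice + (0:5) * pi / 3
  outer(arch$e2, cos(ang)) + outer(arch$e3, sin(ang))
}

#' Homogenized cross-fiber active stress
#'
#' The sum of the six per-actin-filament stress tensors
#' `(1/6) sin(phi)/A_xf_ref * sum(k_xb x_i) * F %*% (t_n %o% t_n)` collapses,
#' via the lattice identity `sum_n t_n %o% t_n = 3 (I - a0f %o% a0f)`, to the
#' closed form `sin(phi)/(2 A_xf_ref) * sum(k_xb x_i) * F %*% (I - a0f %o%
#' a0f)`. The closed form is returned; set `by_direction = TRUE` for the
#' explicit six-term sum (used as an independent oracle in the tests).
#'
#' @inheritParams fiber_active_stress
#' @param by_direction if `TRUE`, evaluate the six per-direction tensors and
#'   sum them instead of using the collapsed closed form.
#' @return 3x3 nominal stress tensor (Pa).
#' @export
crossfiber_active_stress <- function(pop, F, arch, by_direction = FALSE) {
  check_deformation_gradient(F)
  fsum <- xb_population_force(pop)
  if (by_direction) {
    tn <- crossfiber_directions(arch)
    acc <- matrix(0, 3L, 3L)
    for (n in 1:6)
      acc <- acc + sin(pop$phi) / (6 * pop$A_xf_ref) * fsum *
        (F %*% tcrossprod(tn[, n]))
    acc
  } else {
    sin(pop$phi) / (2 * pop$A_xf_ref) * fsum *
      (F %*% (diag(3) - structural_tensor(arch)))
  }
}

#' Total homogenized active-stress tensor
#'
#' Fiber plus cross-fiber homogenized contributions.
#'
#' @inheritParams fiber_active_stress
#' @return 3x3 nominal stress tensor (Pa).
#' @export
total_active_stress <- function(pop, F, arch) {
  fiber_active_stress(pop, F, arch) + crossfiber_active_stress(pop, F, arch)
}

#' Additive-split total stress (active-stress approach)
#'
#' `P = P_passive + P_active - p J F^-T`: the linear superposition of the
#' passive hyperelastic stress, an active-stress tensor, and the
#' incompressibility pressure term. The active source is either a
#' [phen_active_state()] or a [crossbridge_population()].
#'
#' @param F 3x3 deformation gradient with `det(F) = 1`.
#' @param p pressure (Pa).
#' @param arch a [fiber_architecture()].
#' @param passive_model a [passive_model()].
#' @param active_source a [phen_active_state()], a
#'   [crossbridge_population()], or `NULL` for a purely passive response.
#' @param lambda_f_rate fiber stretch rate for the force-velocity curve.
#' @param tol_J incompressibility tolerance.
#' @return a [stress_result()].
#' @export
additive_total_stress <- function(F, p, arch, passive_model,
                                  active_source = NULL, lambda_f_rate = 0,
                                  tol_J = 1e-9) {
  check_deformation_gradient(F)
  check_incompressible(F, tol_J)
  Pa <- active_part(active_source, F, arch, lambda_f_rate)
  P <- passive_dWdF(F, arch, passive_model) + Pa - p * det(F) * t(solve(F))
  stress_result(P, p, F)
}

# dispatch on the two active-source flavours (or NULL)
active_part <- function(active_source, F, arch, lambda_f_rate = 0) {
  if (is.null(active_source)) return(matrix(0, 3L, 3L))
  if (inherits(active_source, "phen_active_state"))
    return(active_stress_phenomenological(F, arch, active_source,
                                          lambda_f_rate))
  if (inherits(active_source, "crossbridge_population"))
    return(total_active_stress(active_source, F, arch))
  stop("active_source must be a phen_active_state or crossbridge_population",
       call. = FALSE)
}
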