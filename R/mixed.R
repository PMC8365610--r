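#' Mixed active-stress--active-strain model configuration
#'
#' Composes the three rheological branches of the mixed model: a parallel
#' spring `W1(F)`, a serial spring `W2(F_e)` behind an active element
#' (multiplicative split), and an additive active-stress tensor. Branch
#' weights scale the underlying stiffnesses (`W1`/`W2` parameters, `P_max` or
#' `k_xb`), never the computed stresses, so every weighted branch remains a
#' valid constitutive model in its own right.
#'
#' @param W1_model parallel-spring [passive_model()] or `NULL` for none.
#' @param W2_model serial-spring [passive_model()] or `NULL` for none.
#' @param active_source a [phen_active_state()], [crossbridge_population()]
#'   or `NULL`.
#' @param Fa_rule an activation closure from [make_Fa_rule()]; defaults to
#'   the identity rule (no internal configuration change).
#' @param w1,w2,wa non-negative branch weights applied to the stiffness
#'   parameters of `W1`, `W2` and the active source respectively.
#' @return object of class `mixed_model_config`.
#' @export
mixed_model_config <- function(W1_model = NULL, W2_model = NULL,
                               active_source = NULL,
                               Fa_rule = make_Fa_rule("identity"),
                               w1 = 1, w2 = 1, wa = 1) {
  if (any(c(w1, w2, wa) < 0))
    stop("branch weights must be non-negative", call. = FALSE)
  structure(list(
    W1_model = scale_branch(if (is.null(W1_model)) zero_passive_model()
                            else W1_model, w1),
    W2_model = scale_branch(if (is.null(W2_model)) zero_passive_model()
                            else W2_model, w2),
    active_source = scale_branch(active_source, wa),
    Fa_rule = Fa_rule),
    class = "mixed_model_config")
}

# weight a branch by scaling its stiffness-like parameters
scale_branch <- function(obj, w) {
  if (is.null(obj) || w == 1) return(obj)
  if (inherits(obj, "passive_model")) {
    if (obj$form == "fiber-reinforced")
      obj$parameters[c("mu", "c1")] <-
        lapply(obj$parameters[c("mu", "c1")], `*`, w)
    else
      obj$parameters <- lapply(obj$parameters, `*`, w)
    return(obj)
  }
  if (inherits(obj, "phen_active_state")) {
    obj$P_max <- obj$P_max * w
    return(obj)
  }
  if (inherits(obj, "crossbridge_population")) {
    obj$k_xb <- obj$k_xb * w
    return(obj)
  }
  stop("cannot weight object of class ", class(obj)[1L], call. = FALSE)
}

#' Mixed-model first Piola-Kirchhoff stress
#'
#' `P = dW1/dF + dW2/dF_e %*% t(solve(Fa)) + P_a - p J F^-T`. One activation
#' `alpha` drives both the additive active-stress branch and the internal
#' active deformation `Fa`; the limits `W2 = 0, Fa = I` and
#' `active_source = NULL, W1 = 0` recover the pure active-stress and pure
#' (generalized) active-strain models exactly.
#'
#' @param F 3x3 deformation gradient with `det(F) = 1`.
#' @param p pressure (Pa).
#' @param arch a [fiber_architecture()].
#' @param config a [mixed_model_config()].
#' @param alpha activation in `[0, 1]` broadcast to all branches. For a
#'   cross-bridge active source, `alpha` scales the population spring force
#'   (the attached fraction is proportional to activation).
#' @param lambda_f_rate fiber stretch rate for the force-velocity curve.
#' @param tol_J incompressibility tolerance.
#' @return a [stress_result()].
#' @export
mixed_stress <- function(F, p, arch, config, alpha = 0, lambda_f_rate = 0,
                         tol_J = 1e-9) {
  br <- branch_report(F, p, arch, config, alpha, lambda_f_rate, tol_J)
  stress_result(br$parallel + br$serial + br$active + br$pressure, p, F)
}

#' Per-branch stress decomposition of the mixed model
#'
#' Returns the four first Piola-Kirchhoff contributions separately:
#' parallel spring, serial (active-strain) branch, additive active stress,
#' and the pressure term. Their sum equals [mixed_stress()]`$P` exactly.
#'
#' @inheritParams mixed_stress
#' @return list with 3x3 matrices `parallel`, `serial`, `active`,
#'   `pressure`, plus `Fa` (the internal active deformation used).
#' @export
branch_report <- function(F, p, arch, config, alpha = 0, lambda_f_rate = 0,
                          tol_J = 1e-9) {
  stopifnot(inherits(config, "mixed_model_config"))
  check_deformation_gradient(F)
  check_incompressible(F, tol_J)
  if (alpha < 0 || alpha > 1) stop("alpha must lie in [0, 1]", call. = FALSE)

  Fa <- config$Fa_rule(alpha, arch)
  Fe <- elastic_part(F, Fa)

  active <- active_part(apply_activation(config$active_source, alpha),
                        F, arch, lambda_f_rate)

  list(parallel = passive_dWdF(F, arch, config$W1_model),
       serial = passive_dWdF(Fe, arch, config$W2_model) %*% t(solve(Fa)),
       active = active,
       pressure = -p * det(F) * t(solve(F)),
       Fa = Fa)
}
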