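#' Active deformation gradient: volume-preserving fiber contraction
#'
#' `F_a = lambda_a (a0f %o% a0f) + 1/sqrt(lambda_a) (I - a0f %o% a0f)`:
#' contraction by `lambda_a < 1` along the fiber axis, compensated by an equal
#' transverse expansion so that `det(F_a) = 1` exactly for every
#' `lambda_a > 0`. Models a fiber in series with connective tissue that must
#' stretch elastically to preserve compatibility.
#'
#' @param lambda_a internal active stretch, > 0 (1 = no activation).
#' @param arch a [fiber_architecture()].
#' @return 3x3 unimodular active deformation gradient.
#' @export
build_Fa_fiber_contraction <- function(lambda_a, arch) {
  if (!is.finite(lambda_a) || lambda_a <= 0)
    stop("lambda_a must be positive", call. = FALSE)
  M <- structural_tensor(arch)
  lambda_a * M + (1 / sqrt(lambda_a)) * (diag(3) - M)
}

#' Active deformation gradient: activation-induced shear along the fiber
#'
#' `F_a = I + gamma_a (a0f %o% e_i)` with `e_i` a transverse unit vector:
#' a simple shear of the intermediate configuration along the fiber axis, as
#' produced by relative sliding of a non-spanning fiber against thin sheets of
#' extracellular connective tissue. `det(F_a) = 1` for any shear because
#' `a0f` and `e_i` are orthogonal.
#'
#' @param gamma_a internal active shear (dimensionless, signed).
#' @param arch a [fiber_architecture()].
#' @param direction_index 2 or 3: which transverse basis vector (`e2`/`e3`)
#'   receives the shear.
#' @return 3x3 unimodular active deformation gradient.
#' @export
build_Fa_shear <- function(gamma_a, arch, direction_index = 2L) {
  if (!is.finite(gamma_a)) stop("gamma_a must be finite", call. = FALSE)
  if (!direction_index %in% c(2L, 3L))
    stop("direction_index must be 2 or 3", call. = FALSE)
  ei <- if (direction_index == 2L) arch$e2 else arch$e3
  if (abs(sum(ei * arch$a0f)) > 1e-10)
    stop("shear direction must be orthogonal to the fiber axis",
         call. = FALSE)
  diag(3) + gamma_a * outer(arch$a0f, ei)
}

#' Elastic part of the multiplicative split
#'
#' `F_e = F %*% solve(F_a)`: the deformation of the serial elastic element,
#' mapping the (incompatible, stress-free) intermediate configuration to the
#' actual one.
#'
#' @param F 3x3 deformation gradient.
#' @param Fa 3x3 active deformation gradient (invertible).
#' @return 3x3 elastic deformation gradient with `F_e %*% F_a = F`.
#' @export
elastic_part <- function(F, Fa) {
  d <- det(Fa)
  if (!is.finite(d) || abs(d) < 1e-14)
    stop("Fa is singular", call. = FALSE)
  F %*% solve(Fa)
}

#' Active-strain first Piola-Kirchhoff stress
#'
#' The serial (multiplicative-split) stress: the energy is evaluated on the
#' elastic part `F_e = F %*% solve(Fa)` only, and the resulting two-point
#' tensor is pulled back to referential coordinates,
#' `P = dW/dF_e %*% t(solve(Fa)) - p J F^-T`. With `Fa = I` this reduces
#' exactly to the passive incompressible stress.
#'
#' @param F 3x3 deformation gradient with `det(F) = 1`.
#' @param p pressure (Pa).
#' @param arch a [fiber_architecture()].
#' @param passive_model a [passive_model()] acting on `F_e`.
#' @param Fa 3x3 active deformation gradient.
#' @param tol_J incompressibility tolerance.
#' @return a [stress_result()].
#' @export
active_strain_stress <- function(F, p, arch, passive_model, Fa,
                                 tol_J = 1e-9) {
  check_deformation_gradient(F)
  check_incompressible(F, tol_J)
  Fe <- elastic_part(F, Fa)
  Pe <- passive_dWdF(Fe, arch, passive_model) %*% t(solve(Fa))
  stress_result(Pe - p * det(F) * t(solve(F)), p, F)
}

#' Generalized active-strain stress (parallel + serial spring)
#'
#' Adds a parallel elastic spring `W1(F)` to the serial active-strain branch
#' `W2(F_e)`: `P = dW1/dF + dW2/dF_e %*% t(solve(Fa)) - p J F^-T`. With
#' `W2 = 0` this is the passive model `W1`; with `W1 = 0` it is the pure
#' active-strain stress; with `Fa = I` it is the passive stress of `W1 + W2`.
#'
#' @inheritParams active_strain_stress
#' @param W1_model parallel-spring [passive_model()] (function of `F`).
#' @param W2_model serial-spring [passive_model()] (function of `F_e`).
#' @return a [stress_result()].
#' @export
generalized_active_strain_stress <- function(F, p, arch, W1_model, W2_model,
                                             Fa, tol_J = 1e-9) {
  check_deformation_gradient(F)
  check_incompressible(F, tol_J)
  Fe <- elastic_part(F, Fa)
  P <- passive_dWdF(F, arch, W1_model) +
    passive_dWdF(Fe, arch, W2_model) %*% t(solve(Fa)) -
    p * det(F) * t(solve(F))
  stress_result(P, p, F)
}

#' Activation closures for the internal active variables
#'
#' The internal variables of the multiplicative split are not observable and
#' their constitutive law is a modeling choice. The packaged closures map a
#' lumped activation `alpha` in `[0, 1]` to:
#' \describe{
#'   \item{fiber contraction}{`lambda_a = 1 - alpha (1 - lambda_a_min)`,
#'     linear interpolation from 1 (passive) to `lambda_a_min` at full
#'     activation; default `lambda_a_min = 0.7`.}
#'   \item{fiber shear}{`gamma_a = alpha * gamma_a_max`; default
#'     `gamma_a_max = 0.3`.}
#' }
#' Both are swappable: [make_Fa_rule()] accepts any closure
#' `function(alpha) -> scalar`.
#'
#' @param form `"fiber-contraction"`, `"fiber-shear"` or `"identity"`.
#' @param lambda_a_min active stretch at full activation (fiber-contraction).
#' @param gamma_a_max active shear at full activation (fiber-shear).
#' @param direction_index transverse basis index for the shear form.
#' @param closure optional replacement closure `function(alpha) -> scalar`
#'   giving `lambda_a` or `gamma_a`.
#' @return a function `(alpha, arch) -> 3x3 Fa matrix` with attribute `form`.
#' @export
make_Fa_rule <- function(form = c("fiber-contraction", "fiber-shear",
                                  "identity"),
                         lambda_a_min = 0.7, gamma_a_max = 0.3,
                         direction_index = 2L, closure = NULL) {
  form <- match.arg(form)
  rule <- switch(form,
    "identity" = function(alpha, arch) diag(3),
    "fiber-contraction" = {
      cl <- if (is.null(closure))
        function(alpha) 1 - alpha * (1 - lambda_a_min) else closure
      function(alpha, arch) build_Fa_fiber_contraction(cl(alpha), arch)
    },
    "fiber-shear" = {
      cl <- if (is.null(closure))
        function(alpha) alpha * gamma_a_max else closure
      function(alpha, arch) build_Fa_shear(cl(alpha), arch, direction_index)
    })
  attr(rule, "form") <- form
  rule
}
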