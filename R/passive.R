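#' Passive hyperelastic strain-energy model
#'
#' Constructs one of the packaged strain-energy families for the passive
#' tissue response. All forms are energy-free at the reference state
#' (`W(I) = 0`) and frame indifferent; the transversely isotropic form is
#' additionally invariant under rotations about the fiber axis.
#'
#' Packaged forms:
#' \describe{
#'   \item{`"neo-hookean"`}{`W = mu/2 (I1 - 3)`, parameter `mu` (Pa).}
#'   \item{`"mooney-rivlin"`}{`W = c10 (I1 - 3) + c01 (I2 - 3)`,
#'     parameters `c10`, `c01` (Pa).}
#'   \item{`"fiber-reinforced"`}{`W = mu/2 (I1 - 3) +
#'     c1/(2 c2) (exp(c2 (I4 - 1)^2) - 1)` with `I4 = lambda_f^2`;
#'     parameters `mu`, `c1` (Pa) and dimensionless `c2 > 0`. By default the
#'     exponential fiber term engages only in fiber extension (`I4 > 1`);
#'     set `tension_only = FALSE` for a bilateral fiber response.}
#' }
#'
#' Invariants are of the right Cauchy-Green tensor `C = t(F) %*% F`:
#' `I1 = tr(C)`, `I2 = (I1^2 - tr(C %*% C))/2`, `I4 = a0f . C a0f`.
#'
#' @param form one of `"neo-hookean"`, `"mooney-rivlin"`, `"fiber-reinforced"`.
#' @param ... named scalar parameters for the chosen form (see Details).
#' @param tension_only logical; fiber term active only for `I4 > 1`
#'   (fiber-reinforced form only).
#' @return object of class `passive_model`.
#' @examples
#' nh <- passive_model("neo-hookean", mu = 1e4)
#' passive_energy(diag(3), fiber_architecture(c(1, 0, 0)), nh)
#' @export
passive_model <- function(form = c("neo-hookean", "mooney-rivlin",
                                   "fiber-reinforced"),
                          ..., tension_only = TRUE) {
  form <- match.arg(form)
  pars <- list(...)
  required <- switch(form,
    "neo-hookean" = "mu",
    "mooney-rivlin" = c("c10", "c01"),
    "fiber-reinforced" = c("mu", "c1", "c2"))
  missing <- setdiff(required, names(pars))
  if (length(missing))
    stop(sprintf("passive form '%s' needs parameter(s): %s", form,
                 paste(missing, collapse = ", ")), call. = FALSE)
  extra <- setdiff(names(pars), required)
  if (length(extra))
    stop(sprintf("unknown parameter(s) for form '%s': %s", form,
                 paste(extra, collapse = ", ")), call. = FALSE)
  pars <- lapply(pars[required], as.numeric)
  if (any(unlist(pars) < 0))
    stop("stiffness parameters must be non-negative", call. = FALSE)
  if (form == "fiber-reinforced" && pars$c2 <= 0)
    stop("c2 must be positive", call. = FALSE)
  structure(list(form = form, parameters = pars,
                 symmetry = if (form == "fiber-reinforced")
                   "transversely-isotropic" else "isotropic",
                 tension_only = isTRUE(tension_only)),
            class = "passive_model")
}

#' @export
print.passive_model <- function(x, ...) {
  cat("passive_model:", x$form, sprintf("(%s)\n", x$symmetry))
  for (nm in names(x$parameters))
    cat(" ", nm, "=", format(x$parameters[[nm]]), "\n")
  invisible(x)
}

# a model that contributes nothing; used for branch limits of the mixed model
zero_passive_model <- function() {
  structure(list(form = "zero", parameters = list(), symmetry = "isotropic",
                 tension_only = TRUE), class = "passive_model")
}

#' Passive strain energy
#'
#' Evaluates the volume-specific strain energy `W(F)` of a packaged
#' [passive_model()] (units: Pa, i.e. J/m^3).
#'
#' @param F 3x3 deformation gradient, `det(F) > 0`.
#' @param arch a [fiber_architecture()].
#' @param model a [passive_model()].
#' @return scalar energy density in Pa.
#' @export
passive_energy <- function(F, arch, model) {
  check_deformation_gradient(F)
  stopifnot(inherits(model, "passive_model"))
  C <- crossprod(F)
  I1 <- sum(diag(C))
  p <- model$parameters
  switch(model$form,
    "zero" = 0,
    "neo-hookean" = p$mu / 2 * (I1 - 3),
    "mooney-rivlin" = {
      I2 <- (I1^2 - sum(C * C)) / 2
      p$c10 * (I1 - 3) + p$c01 * (I2 - 3)
    },
    "fiber-reinforced" = {
      a <- arch$a0f
      I4 <- as.numeric(a %*% C %*% a)
      Wf <- if (model$tension_only && I4 <= 1) 0 else
        p$c1 / (2 * p$c2) * (exp(p$c2 * (I4 - 1)^2) - 1)
      p$mu / 2 * (I1 - 3) + Wf
    },
    stop("unknown passive form: ", model$form, call. = FALSE))
}

# analytic dW/dF for the packaged forms (first Piola-Kirchhoff, no pressure)
passive_dWdF <- function(F, arch, model) {
  p <- model$parameters
  switch(model$form,
    "zero" = matrix(0, 3L, 3L),
    "neo-hookean" = p$mu * F,
    "mooney-rivlin" = {
      C <- crossprod(F)
      I1 <- sum(diag(C))
      2 * p$c10 * F + 2 * p$c01 * (I1 * F - F %*% C)
    },
    "fiber-reinforced" = {
      C <- crossprod(F)
      a <- arch$a0f
      I4 <- as.numeric(a %*% C %*% a)
      M <- tcrossprod(a)
      fib <- if (model$tension_only && I4 <= 1) matrix(0, 3L, 3L) else
        2 * p$c1 * (I4 - 1) * exp(p$c2 * (I4 - 1)^2) * (F %*% M)
      p$mu * F + fib
    },
    stop("unknown passive form: ", model$form, call. = FALSE))
}

#' Assemble a stress result
#'
#' Container for a first Piola-Kirchhoff tensor `P`, the incompressibility
#' pressure `p`, and the Cauchy stress `P %*% t(F)` (valid under `J = 1`).
#' Stresses are stored in Pa; 1 N cm^-2 = 1e4 Pa.
#'
#' @param P 3x3 first Piola-Kirchhoff tensor (Pa).
#' @param p scalar pressure (Pa).
#' @param F the deformation gradient used to push `P` forward.
#' @return object of class `stress_result` with fields `P`, `p`, `cauchy`.
#' @export
stress_result <- function(P, p, F) {
  structure(list(P = P, p = as.numeric(p), cauchy = P %*% t(F) / det(F)),
            class = "stress_result")
}

#' @export
print.stress_result <- function(x, ...) {
  cat("stress_result (Pa); p =", format(x$p, digits = 6), "\n")
  cat("P:\n"); print(signif(x$P, 6))
  invisible(x)
}

#' Incompressible first Piola-Kirchhoff stress
#'
#' Analytic stress `P = dW/dF - p J F^-T` for a packaged passive model under
#' the incompressibility constraint `det(F) = 1`, with the Lagrange-multiplier
#' pressure `p` supplied by the caller (see [solve_pressure()]).
#'
#' @inheritParams passive_energy
#' @param p scalar pressure (Pa).
#' @param tol_J tolerance on `|det(F) - 1|`.
#' @return a [stress_result()].
#' @export
pk1_incompressible <- function(F, p, arch, model, tol_J = 1e-9) {
  check_deformation_gradient(F)
  check_incompressible(F, tol_J)
  J <- det(F)
  P <- passive_dWdF(F, arch, model) - p * J * t(solve(F))
  stress_result(P, p, F)
}

#' Finite-difference stress oracle
#'
#' Independent check of the analytic stress: component-wise second-order
#' central difference of the strain energy with respect to `F`, plus the
#' `- p J F^-T` pressure term. Used by the test-suite to validate every
#' analytic derivative; it shares no code path with [pk1_incompressible()].
#'
#' @inheritParams pk1_incompressible
#' @param h finite-difference step (default 1e-6).
#' @param energy_fn energy function `(F, arch, model) -> scalar`; defaults to
#'   [passive_energy()].
#' @return 3x3 matrix approximating the first Piola-Kirchhoff stress.
#' @export
fd_stress_oracle <- function(F, p, arch, model, h = 1e-6,
                             energy_fn = passive_energy) {
  stopifnot(h > 0)
  P <- matrix(0, 3L, 3L)
  for (i in 1:3) for (j in 1:3) {
    Fp <- F; Fp[i, j] <- Fp[i, j] + h
    Fm <- F; Fm[i, j] <- Fm[i, j] - h
    P[i, j] <- (energy_fn(Fp, arch, model) - energy_fn(Fm, arch, model)) /
      (2 * h)
  }
  P - p * det(F) * t(solve(F))
}
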