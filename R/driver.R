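#' Apply an activation level to an active source
#'
#' For the phenomenological law, sets the lumped activation `alpha`. For a
#' cross-bridge population, detaches bridges so that the attached count is
#' `round(alpha * N)` — the attached fraction is proportional to activation,
#' mirroring the linear relation between isometric tension and the fraction
#' of activated fibers.
#'
#' @param active_source a [phen_active_state()], [crossbridge_population()]
#'   or `NULL`.
#' @param alpha activation in `[0, 1]`.
#' @return the activated source (same class), or `NULL`.
#' @export
apply_activation <- function(active_source, alpha) {
  if (alpha < 0 || alpha > 1) stop("alpha must lie in [0, 1]", call. = FALSE)
  if (is.null(active_source)) return(NULL)
  if (inherits(active_source, "phen_active_state")) {
    active_source$alpha <- alpha
    return(active_source)
  }
  if (inherits(active_source, "crossbridge_population")) {
    n <- round(alpha * length(active_source$x))
    active_source$x <- active_source$x[seq_len(n)]
    return(active_source)
  }
  stop("unknown active source class: ", class(active_source)[1L],
       call. = FALSE)
}

#' Constitutive model wrapper
#'
#' Bundles one of the four constitutive frameworks with its ingredient
#' models so the material-point driver can evaluate any of them through a
#' single interface ([evaluate_stress()]).
#'
#' @param framework `"active-stress"`, `"active-strain"`,
#'   `"generalized-active-strain"` or `"mixed"`.
#' @param passive [passive_model()] for the single-spring frameworks.
#' @param W1,W2 parallel/serial [passive_model()]s (generalized active
#'   strain and mixed frameworks).
#' @param active_source a [phen_active_state()] or
#'   [crossbridge_population()] (active-stress and mixed frameworks).
#' @param Fa_rule activation closure from [make_Fa_rule()] (active-strain
#'   and mixed frameworks).
#' @return object of class `muscle_model`.
#' @export
muscle_model <- function(framework = c("active-stress", "active-strain",
                                       "generalized-active-strain", "mixed"),
                         passive = NULL, W1 = NULL, W2 = NULL,
                         active_source = NULL, Fa_rule = NULL) {
  framework <- match.arg(framework)
  if (framework %in% c("active-stress", "active-strain") &&
      is.null(passive))
    stop(framework, " framework needs a 'passive' model", call. = FALSE)
  if (framework %in% c("active-strain", "generalized-active-strain") &&
      is.null(Fa_rule))
    stop(framework, " framework needs an Fa_rule", call. = FALSE)
  if (is.null(Fa_rule)) Fa_rule <- make_Fa_rule("identity")
  structure(list(framework = framework, passive = passive,
                 W1 = W1, W2 = W2, active_source = active_source,
                 Fa_rule = Fa_rule),
            class = "muscle_model")
}

#' Evaluate the first Piola-Kirchhoff stress of any framework
#'
#' Dispatches to the framework-specific stress function with a shared
#' signature, applying the activation to the active source and the internal
#' active deformation rule.
#'
#' @param model a [muscle_model()].
#' @param F 3x3 deformation gradient with `det(F) = 1`.
#' @param p pressure (Pa).
#' @param arch a [fiber_architecture()].
#' @param alpha activation in `[0, 1]`.
#' @param lambda_f_rate fiber stretch rate (1/s).
#' @param tol_J incompressibility tolerance.
#' @return a [stress_result()].
#' @export
evaluate_stress <- function(model, F, p, arch, alpha = 0, lambda_f_rate = 0,
                            tol_J = 1e-9) {
  stopifnot(inherits(model, "muscle_model"))
  switch(model$framework,
    "active-stress" = additive_total_stress(
      F, p, arch, model$passive,
      apply_activation(model$active_source, alpha), lambda_f_rate, tol_J),
    "active-strain" = active_strain_stress(
      F, p, arch, model$passive, model$Fa_rule(alpha, arch), tol_J),
    "generalized-active-strain" = generalized_active_strain_stress(
      F, p, arch,
      if (is.null(model$W1)) zero_passive_model() else model$W1,
      if (is.null(model$W2)) zero_passive_model() else model$W2,
      model$Fa_rule(alpha, arch), tol_J),
    "mixed" = mixed_stress(
      F, p, arch,
      mixed_model_config(model$W1, model$W2, model$active_source,
                         model$Fa_rule),
      alpha, lambda_f_rate, tol_J))
}

#' Loading protocol for homogeneous material-point experiments
#'
#' Defines a path of prescribed deformations and activations:
#' \describe{
#'   \item{`"uniaxial-fiber"`}{fiber-direction stretch ramp, transverse
#'     stretches `lambda^(-1/2)` by incompressibility and transverse
#'     isotropy.}
#'   \item{`"uniaxial-cross-fiber"`}{stretch ramp along `e2`; the fiber and
#'     `e3` stretches are found by the driver (Newton) so both lateral
#'     normal Cauchy stresses vanish.}
#'   \item{`"simple-shear"`}{`F = I + gamma a0f %o% e2`; pressure gauged by
#'     `sigma_33 = 0`.}
#'   \item{`"isometric-activation"`}{`F = I` throughout while the activation
#'     ramps over the schedule.}
#'   \item{`"custom-F-path"`}{explicit list of deformation gradients.}
#' }
#'
#' @param kind protocol kind (see Details).
#' @param lambda_range length-2 stretch range (uniaxial kinds), values > 0.
#' @param gamma_range length-2 shear range (simple shear).
#' @param n_steps number of steps (>= 1).
#' @param alpha_schedule constant in `[0, 1]` or function of the step
#'   fraction `s` in `[0, 1]` returning the activation.
#' @param lambda_f_rate fiber stretch rate handed to the force-velocity
#'   curve (constant or function of step fraction).
#' @param F_path list of 3x3 matrices (custom kind only), each `det = 1`.
#' @return object of class `loading_protocol`.
#' @export
loading_protocol <- function(kind = c("uniaxial-fiber",
                                      "uniaxial-cross-fiber",
                                      "simple-shear",
                                      "isometric-activation",
                                      "custom-F-path"),
                             lambda_range = c(1, 1.2),
                             gamma_range = c(0, 0.4),
                             n_steps = 11L,
                             alpha_schedule = 0,
                             lambda_f_rate = 0,
                             F_path = NULL) {
  kind <- match.arg(kind)
  n_steps <- as.integer(n_steps)
  if (n_steps < 1L) stop("n_steps must be >= 1", call. = FALSE)
  if (any(lambda_range <= 0))
    stop("stretch values must be positive", call. = FALSE)
  if (kind == "custom-F-path") {
    if (is.null(F_path) || !length(F_path))
      stop("custom-F-path needs a non-empty F_path list", call. = FALSE)
    for (F in F_path) {
      check_deformation_gradient(F)
      check_incompressible(F)
    }
    n_steps <- length(F_path)
  }
  structure(list(kind = kind, lambda_range = lambda_range,
                 gamma_range = gamma_range, n_steps = n_steps,
                 alpha_schedule = alpha_schedule,
                 lambda_f_rate = lambda_f_rate, F_path = F_path),
            class = "loading_protocol")
}

protocol_alpha <- function(protocol, s) {
  a <- protocol$alpha_schedule
  if (is.function(a)) a(s) else as.numeric(a)
}

protocol_rate <- function(protocol, s) {
  r <- protocol$lambda_f_rate
  if (is.function(r)) r(s) else as.numeric(r)
}

step_fraction <- function(protocol, step) {
  if (protocol$n_steps == 1L) 1 else (step - 1) / (protocol$n_steps - 1)
}

#' Deformation gradient at a protocol step
#'
#' Builds the prescribed isochoric deformation for step `step` (1-based) in
#' the fiber-architecture frame. For the cross-fiber kind this is the
#' symmetric initial guess; [run_protocol()] refines the free stretches.
#'
#' @param protocol a [loading_protocol()].
#' @param step step index in `1:n_steps`.
#' @param arch a [fiber_architecture()].
#' @return a [deformation_state()].
#' @export
build_deformation <- function(protocol, step, arch) {
  stopifnot(inherits(protocol, "loading_protocol"))
  if (step < 1L || step > protocol$n_steps)
    stop("step out of range", call. = FALSE)
  s <- step_fraction(protocol, step)
  M <- structural_tensor(arch)
  F <- switch(protocol$kind,
    "uniaxial-fiber" = {
      lam <- interp_range(protocol$lambda_range, s)
      lam * M + lam^(-0.5) * (diag(3) - M)
    },
    "uniaxial-cross-fiber" = {
      lam <- interp_range(protocol$lambda_range, s)
      M2 <- tcrossprod(arch$e2)
      lam * M2 + lam^(-0.5) * (diag(3) - M2)
    },
    "simple-shear" = {
      gam <- interp_range(protocol$gamma_range, s)
      diag(3) + gam * outer(arch$a0f, arch$e2)
    },
    "isometric-activation" = diag(3),
    "custom-F-path" = protocol$F_path[[step]])
  deformation_state(F, arch, protocol_rate(protocol, s))
}

interp_range <- function(range, s) range[1L] + s * (range[2L] - range[1L])

#' Solve the incompressibility pressure from a traction condition
#'
#' The pressure enters the Cauchy stress as `-p I` (since
#' `(p J F^-T) t(F) / J = p I` under any `F`), so a zero-normal-traction
#' condition on a direction `d` is solved in one step:
#' `p = d . sigma(p = 0) d`. The residual is verified against
#' `1e-8 * max(|sigma|, 1)`.
#'
#' @param F 3x3 deformation gradient.
#' @param arch a [fiber_architecture()].
#' @param model_callable function `(F, p) -> stress_result`, affine in `p`.
#' @param direction unit 3-vector whose normal Cauchy traction is driven to
#'   zero; default `arch$e3`.
#' @return scalar pressure `p` (Pa).
#' @export
solve_pressure <- function(F, arch, model_callable, direction = NULL) {
  if (is.null(direction)) direction <- arch$e3
  d <- direction / sqrt(sum(direction^2))
  s0 <- model_callable(F, 0)$cauchy
  p <- as.numeric(d %*% s0 %*% d)
  res <- abs(as.numeric(d %*% model_callable(F, p)$cauchy %*% d))
  scale <- max(abs(s0), 1)
  if (res > 1e-8 * scale)
    stop(sprintf("pressure solve failed: residual %.3e", res), call. = FALSE)
  p
}

#' Run a loading protocol against a constitutive model
#'
#' Steps through the protocol, solving the incompressibility pressure from
#' the protocol's traction gauge at every step (and, for cross-fiber
#' loading, the free transverse-stretch ratio by Newton iteration with
#' analytic pressure elimination inside each iterate; tolerance 1e-10, at
#' most 50 iterations). Deterministic: the same inputs give bit-identical
#' tables.
#'
#' @param protocol a [loading_protocol()].
#' @param model a [muscle_model()].
#' @param arch a [fiber_architecture()].
#' @return `data.frame` with one row per step: `step`, `control` (stretch or
#'   shear), `alpha`, `lambda_f`, `lambda_f_rate`, `p`, the nine `P_ij` and
#'   nine `sigma_ij` components (Pa), and for the mixed framework the
#'   fiber-direction component of each branch
#'   (`branch_parallel_11`, `branch_serial_11`, `branch_active_11`).
#' @export
run_protocol <- function(protocol, model, arch) {
  stopifnot(inherits(protocol, "loading_protocol"),
            inherits(model, "muscle_model"),
            inherits(arch, "fiber_architecture"))
  rows <- vector("list", protocol$n_steps)
  for (step in seq_len(protocol$n_steps)) {
    s <- step_fraction(protocol, step)
    alpha <- protocol_alpha(protocol, s)
    rate <- protocol_rate(protocol, s)
    st <- build_deformation(protocol, step, arch)
    F <- st$F

    callable <- function(F, p)
      evaluate_stress(model, F, p, arch, alpha, rate)

    gauge_dir <- switch(protocol$kind,
      "uniaxial-fiber" = arch$e2,
      "uniaxial-cross-fiber" = arch$e3,
      "simple-shear" = arch$e3,
      "isometric-activation" = arch$e2,
      "custom-F-path" = arch$e3)

    if (protocol$kind == "uniaxial-cross-fiber") {
      sol <- solve_crossfiber_step(protocol, s, model, arch, alpha, rate)
      F <- sol$F
      p <- sol$p
    } else {
      p <- solve_pressure(F, arch, callable, gauge_dir)
    }

    res <- callable(F, p)
    control <- switch(protocol$kind,
      "uniaxial-fiber" = interp_range(protocol$lambda_range, s),
      "uniaxial-cross-fiber" = interp_range(protocol$lambda_range, s),
      "simple-shear" = interp_range(protocol$gamma_range, s),
      "isometric-activation" = 1,
      "custom-F-path" = NA_real_)

    row <- c(step = step, control = control, alpha = alpha,
             lambda_f = fiber_stretch(F, arch), lambda_f_rate = rate, p = p,
             flatten_tensor(res$P, "P"), flatten_tensor(res$cauchy, "sigma"))
    if (model$framework == "mixed") {
      br <- branch_report(F, p, arch,
                          mixed_model_config(model$W1, model$W2,
                                             model$active_source,
                                             model$Fa_rule),
                          alpha, rate)
      a <- arch$a0f
      row <- c(row,
               branch_parallel_11 = as.numeric(a %*% br$parallel %*% a),
               branch_serial_11 = as.numeric(a %*% br$serial %*% a),
               branch_active_11 = as.numeric(a %*% br$active %*% a))
    }
    rows[[step]] <- row
  }
  as.data.frame(do.call(rbind, rows))
}

flatten_tensor <- function(T, prefix) {
  v <- as.numeric(t(T))  # row-major: T11 T12 T13 T21 ...
  names(v) <- paste0(prefix, "_", rep(1:3, each = 3), rep(1:3, 3))
  v
}

# Cross-fiber uniaxial step: stretch lam prescribed along e2; unknown ratio s
# distributes the remaining 1/lam between the fiber axis (stretch u = s) and
# e3 (stretch 1/(lam*s)). Pressure eliminated analytically via sigma_33 = 0;
# Newton drives the fiber-direction normal Cauchy stress to zero.
solve_crossfiber_step <- function(protocol, sfrac, model, arch, alpha, rate,
                                  tol = 1e-10, max_iter = 50L) {
  lam <- interp_range(protocol$lambda_range, sfrac)
  M <- structural_tensor(arch)
  M2 <- tcrossprod(arch$e2)
  M3 <- tcrossprod(arch$e3)
  build_F <- function(u) lam * M2 + u * M + 1 / (lam * u) * M3

  resid <- function(u) {
    F <- build_F(u)
    cal <- function(F, p) evaluate_stress(model, F, p, arch, alpha, rate)
    p <- solve_pressure(F, arch, cal, arch$e3)
    sig <- cal(F, p)$cauchy
    list(g = as.numeric(arch$a0f %*% sig %*% arch$a0f), p = p, F = F)
  }

  u <- lam^(-0.5)
  scale <- NULL
  for (iter in seq_len(max_iter)) {
    r <- resid(u)
    if (is.null(scale)) scale <- max(abs(r$g), 1)
    if (abs(r$g) <= tol * scale) return(list(F = r$F, p = r$p, stretch = u))
    h <- max(1e-7, 1e-7 * abs(u))
    dg <- (resid(u + h)$g - resid(u - h)$g) / (2 * h)
    if (!is.finite(dg) || abs(dg) < 1e-300)
      stop("singular Newton step in cross-fiber solve", call. = FALSE)
    du <- -r$g / dg
    # damp to keep the stretch positive
    while (u + du <= 0) du <- du / 2
    u <- u + du
  }
  stop("cross-fiber Newton did not converge in ", max_iter, " iterations",
       call. = FALSE)
}
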