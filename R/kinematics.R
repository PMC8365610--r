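#' Fiber architecture of a transversely isotropic muscle sample
#'
#' Bundles the referential unit fiber direction `a0f`, two transverse unit
#' vectors `e2`, `e3` completing a right-handed orthonormal laboratory frame
#' with `e1 = a0f`, and the in-plane lattice angle `phi_lattice` that fixes the
#' orientation of the hexagonal filament lattice within the transverse plane.
#'
#' If `e2`/`e3` are omitted they are constructed deterministically from `a0f`
#' (a stable Gram-Schmidt complement).
#'
#' @param a0f numeric length-3 vector, referential fiber direction (normalized
#'   internally; must be nonzero).
#' @param e2,e3 optional unit vectors orthogonal to `a0f` and each other.
#' @param phi_lattice lattice orientation angle in radians, in `[0, 2*pi)`.
#' @return An object of class `fiber_architecture` with fields `a0f`, `e2`,
#'   `e3`, `phi_lattice`.
#' @examples
#' arch <- fiber_architecture(c(1, 0, 0))
#' structural_tensor(arch)
#' @export
fiber_architecture <- function(a0f, e2 = NULL, e3 = NULL, phi_lattice = 0) {
  a0f <- as.numeric(a0f)
  if (length(a0f) != 3L || !all(is.finite(a0f)))
    stop("a0f must be a finite length-3 numeric vector", call. = FALSE)
  na <- sqrt(sum(a0f^2))
  if (na < 1e-12) stop("a0f must be nonzero", call. = FALSE)
  a0f <- a0f / na

  if (is.null(e2)) {
    # pick the lab axis least aligned with a0f, orthogonalize
    seed_axis <- diag(3)[, which.min(abs(a0f))]
    e2 <- seed_axis - sum(seed_axis * a0f) * a0f
    e2 <- e2 / sqrt(sum(e2^2))
  } else {
    e2 <- as.numeric(e2)
    e2 <- e2 / sqrt(sum(e2^2))
    if (abs(sum(e2 * a0f)) > 1e-10)
      stop("e2 must be orthogonal to a0f", call. = FALSE)
  }
  if (is.null(e3)) {
    e3 <- cross3(a0f, e2)
  } else {
    e3 <- as.numeric(e3)
    e3 <- e3 / sqrt(sum(e3^2))
    if (abs(sum(e3 * a0f)) > 1e-10 || abs(sum(e3 * e2)) > 1e-10)
      stop("e3 must be orthogonal to a0f and e2", call. = FALSE)
    if (sum(cross3(a0f, e2) * e3) < 0)
      stop("{a0f, e2, e3} must be right-handed", call. = FALSE)
  }
  phi_lattice <- as.numeric(phi_lattice) %% (2 * pi)
  structure(list(a0f = a0f, e2 = e2, e3 = e3, phi_lattice = phi_lattice),
            class = "fiber_architecture")
}

cross3 <- function(u, v) {
  c(u[2L] * v[3L] - u[3L] * v[2L],
    u[3L] * v[1L] - u[1L] * v[3L],
    u[1L] * v[2L] - u[2L] * v[1L])
}

#' @export
print.fiber_architecture <- function(x, ...) {
  cat("fiber_architecture\n")
  cat("  a0f:", format(x$a0f, digits = 4), "\n")
  cat("  phi_lattice:", format(x$phi_lattice, digits = 4), "rad\n")
  invisible(x)
}

#' Structural tensor of the fiber direction
#'
#' Returns the rank-one projector `a0f %o% a0f` encoding transverse isotropy
#' about the fiber axis. It is symmetric, idempotent and has unit trace.
#'
#' @param arch a [fiber_architecture()].
#' @return 3x3 numeric matrix.
#' @export
structural_tensor <- function(arch) {
  stopifnot(inherits(arch, "fiber_architecture"))
  tcrossprod(arch$a0f)
}

#' Fiber stretch from a deformation gradient
#'
#' Computes `lambda_f = sqrt((F a0f) . (F a0f))`, the stretch of a line
#' element along the referential fiber direction.
#'
#' @param F 3x3 deformation gradient with `det(F) > 0`.
#' @param arch a [fiber_architecture()].
#' @return scalar fiber stretch, strictly positive.
#' @export
fiber_stretch <- function(F, arch) {
  check_deformation_gradient(F)
  v <- F %*% arch$a0f
  sqrt(sum(v * v))
}

check_deformation_gradient <- function(F) {
  if (!is.matrix(F) || !identical(dim(F), c(3L, 3L)) || !all(is.finite(F)))
    stop("F must be a finite 3x3 matrix", call. = FALSE)
  if (det(F) <= 0)
    stop("invalid deformation: det(F) must be positive", call. = FALSE)
  invisible(F)
}

#' Deformation state at a material point
#'
#' Wraps a deformation gradient `F` with its derived kinematic quantities:
#' `J = det(F)`, the fiber stretch `lambda_f` (always recomputed from `F` and
#' the architecture, never user-supplied), and an optional fiber stretch rate
#' supplied by the loading protocol.
#'
#' @param F 3x3 deformation gradient, `det(F) > 0`.
#' @param arch a [fiber_architecture()].
#' @param lambda_f_rate scalar fiber stretch rate (1/s); default 0.
#' @return object of class `deformation_state` with fields `F`, `J`,
#'   `lambda_f`, `lambda_f_rate`.
#' @export
deformation_state <- function(F, arch, lambda_f_rate = 0) {
  check_deformation_gradient(F)
  structure(list(F = F, J = det(F),
                 lambda_f = fiber_stretch(F, arch),
                 lambda_f_rate = as.numeric(lambda_f_rate)),
            class = "deformation_state")
}

# incompressibility gate shared by the stress evaluators
check_incompressible <- function(F, tol_J = 1e-9) {
  J <- det(F)
  if (abs(J - 1) > tol_J)
    stop(sprintf("deformation is not isochoric: |det(F) - 1| = %.3e > %.1e",
                 abs(J - 1), tol_J), call. = FALSE)
  invisible(J)
}

#' Uniformly distributed random rotation
#'
#' Draws a rotation matrix uniformly (Haar measure) on SO(3) via a normalized
#' quaternion of four iid standard normals. The draw is reproducible per seed
#' and leaves the global RNG stream untouched.
#'
#' @param seed integer seed.
#' @return 3x3 proper orthogonal matrix.
#' @export
random_rotation <- function(seed) {
  q <- with_local_seed(seed, stats::rnorm(4L))
  q <- q / sqrt(sum(q^2))
  w <- q[1L]; x <- q[2L]; y <- q[3L]; z <- q[4L]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
           2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
           2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)),
         nrow = 3L)
}

# run expr under a temporary RNG state; restores the caller's stream
with_local_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  expr
}

#' Rotation about the fiber axis
#'
#' Proper rotation by `angle` about `a0f` (Rodrigues formula); such rotations
#' generate the material symmetry group of a transversely isotropic tissue.
#'
#' @param arch a [fiber_architecture()].
#' @param angle rotation angle in radians.
#' @return 3x3 rotation matrix `Q` with `Q %*% a0f == a0f`.
#' @export
rotation_about_fiber <- function(arch, angle) {
  stopifnot(inherits(arch, "fiber_architecture"))
  a <- arch$a0f
  K <- matrix(c(0, a[3L], -a[2L],
                -a[3L], 0, a[1L],
                a[2L], -a[1L], 0), nrow = 3L)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}
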