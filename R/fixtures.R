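# Default cross-bridge parameter set for a half-sarcomere unit cell of the
# hexagonal filament lattice. Geometry: myosin center-to-center spacing
# 45 nm gives a hexagonal Wigner-Seitz cell of area sqrt(3)/2 * d^2 and side
# d/sqrt(3); the reference-volume length 0.72 um is the cross-bridge-bearing
# overlap zone of one half A-band. The post-powerstroke elongation x0 is
# calibrated (scripts/calibrate_crossbridge.R) so that 97 attached bridges of
# stiffness 2e-3 N/m transmitting at 60 deg yield a nominal fiber stress of
# exactly 25 N cm^-2 at F = I.
default_xb_parameters <- function() {
  d <- 45e-9
  L <- 0.72e-6
  list(
    k_xb = 2e-3,                    # N/m (~2 pN/nm molecular spring)
    N_xb = 97L,                     # attached bridges per unit cell
    x0 = 4.51984907902960743e-09,   # m, calibrated post-powerstroke elongation
    phi = pi / 3,                   # transmission angle from the fiber axis
    A_f_ref = sqrt(3) / 2 * d^2,    # m^2, hexagonal cell cross-section
    A_xf_ref = d / sqrt(3) * L      # m^2, one sixth of the mantle surface
  )
}

#' Cross-bridge population specification
#'
#' Describes how to draw a synthetic population of attached cross-bridges:
#' the nominal count `N_xb`, the attached fraction (proportional to
#' activation), the elongation distribution, and the RNG seed. Distributions:
#' \describe{
#'   \item{`"point-mass"`}{every bridge at `x0`.}
#'   \item{`"uniform"`}{iid uniform on `[x_lo, x_hi]`.}
#'   \item{`"two-point"`}{mixture of pre-powerstroke bridges at `x_pre`
#'     (default 0) and post-powerstroke bridges at `x_post`, with
#'     `post_fraction` drawn per bridge (default 0.7).}
#' }
#'
#' @param N_xb nominal cross-bridge count (>= 0).
#' @param attachment_fraction fraction attached, in `[0, 1]`.
#' @param x_distribution `"point-mass"`, `"uniform"` or `"two-point"`.
#' @param x0 point-mass elongation (m).
#' @param x_lo,x_hi uniform bounds (m), `x_lo <= x_hi`.
#' @param x_pre,x_post two-point elongations (m).
#' @param post_fraction probability a bridge is post-powerstroke.
#' @param seed integer RNG seed.
#' @return object of class `population_spec`.
#' @export
population_spec <- function(N_xb, attachment_fraction = 1,
                            x_distribution = c("point-mass", "uniform",
                                               "two-point"),
                            x0 = default_xb_parameters()$x0,
                            x_lo = 0, x_hi = 8e-9,
                            x_pre = 0, x_post = default_xb_parameters()$x0,
                            post_fraction = 0.7, seed = 1L) {
  x_distribution <- match.arg(x_distribution)
  if (N_xb < 0) stop("N_xb must be non-negative", call. = FALSE)
  if (attachment_fraction < 0 || attachment_fraction > 1)
    stop("attachment_fraction must lie in [0, 1]", call. = FALSE)
  if (x_distribution == "uniform" && x_lo > x_hi)
    stop("x_lo must not exceed x_hi", call. = FALSE)
  if (x_distribution == "two-point" &&
      (post_fraction < 0 || post_fraction > 1))
    stop("post_fraction must lie in [0, 1]", call. = FALSE)
  structure(list(N_xb = as.integer(N_xb),
                 attachment_fraction = as.numeric(attachment_fraction),
                 x_distribution = x_distribution,
                 x0 = x0, x_lo = x_lo, x_hi = x_hi,
                 x_pre = x_pre, x_post = x_post,
                 post_fraction = post_fraction,
                 seed = as.integer(seed)),
            class = "population_spec")
}

#' Generate a synthetic cross-bridge population
#'
#' Draws `round(N_xb * attachment_fraction)` elongations according to the
#' spec's distribution, reproducibly per seed (base R Mersenne-Twister via a
#' local RNG stream), and attaches the default unit-cell geometry unless
#' overridden.
#'
#' @param spec a [population_spec()].
#' @param k_xb,phi,A_f_ref,A_xf_ref geometry/stiffness overrides; defaults
#'   are the packaged unit-cell parameter set.
#' @return a [crossbridge_population()].
#' @export
generate_population <- function(spec,
                                k_xb = default_xb_parameters()$k_xb,
                                phi = default_xb_parameters()$phi,
                                A_f_ref = default_xb_parameters()$A_f_ref,
                                A_xf_ref = default_xb_parameters()$A_xf_ref) {
  stopifnot(inherits(spec, "population_spec"))
  n <- round(spec$N_xb * spec$attachment_fraction)
  x <- if (n == 0) numeric(0) else switch(spec$x_distribution,
    "point-mass" = rep(spec$x0, n),
    "uniform" = with_local_seed(spec$seed,
                                stats::runif(n, spec$x_lo, spec$x_hi)),
    "two-point" = with_local_seed(spec$seed, {
      post <- stats::runif(n) < spec$post_fraction
      ifelse(post, spec$x_post, spec$x_pre)
    }))
  crossbridge_population(k_xb = k_xb, x = x, phi = phi,
                         A_f_ref = A_f_ref, A_xf_ref = A_xf_ref)
}

#' Packaged default cross-bridge population
#'
#' The deterministic reference population at optimal muscle length: all
#' attached bridges post-powerstroke at the calibrated elongation, with the
#' packaged unit-cell geometry. At `F = I` and full activation it produces a
#' nominal fiber-direction active stress of 25 N cm^-2 and a cross-fiber to
#' fiber stress ratio of about 8 percent.
#'
#' @param attachment_fraction fraction of the bridges attached (scales the
#'   population size; proportional to activation).
#' @return a [crossbridge_population()].
#' @examples
#' pop <- default_crossbridge_population()
#' arch <- fiber_architecture(c(1, 0, 0))
#' fiber_active_stress(pop, diag(3), arch)[1, 1] / 1e4  # N cm^-2
#' @export
default_crossbridge_population <- function(attachment_fraction = 1) {
  pars <- default_xb_parameters()
  spec <- population_spec(pars$N_xb, attachment_fraction,
                          x_distribution = "point-mass", x0 = pars$x0)
  generate_population(spec)
}

#' Export a population's elongations to CSV
#'
#' Writes the one-column (`x`, meters) CSV consumed by
#' [read_elongations_csv()].
#'
#' @param pop a [crossbridge_population()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_elongations_csv <- function(pop, path) {
  stopifnot(inherits(pop, "crossbridge_population"))
  utils::write.csv(data.frame(x = pop$x), path, row.names = FALSE)
  invisible(path)
}

#' Random admissible isochoric deformation gradient
#'
#' Test-support generator: a random 3x3 matrix near the identity with
#' positive determinant, rescaled to `det(F) = 1` exactly (within floating
#' point). Reproducible per seed.
#'
#' @param seed integer seed.
#' @param spread entrywise perturbation scale (default 0.2).
#' @return 3x3 matrix with `det = 1`.
#' @export
random_isochoric_F <- function(seed, spread = 0.2) {
  F <- with_local_seed(seed, {
    repeat {
      cand <- diag(3) + matrix(stats::runif(9, -spread, spread), 3L, 3L)
      if (det(cand) > 0.1) break
    }
    cand
  })
  F / det(F)^(1 / 3)
}
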