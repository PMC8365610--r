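test_that("scalar Hill-type law multiplies its four factors", {
  st <- phen_active_state(P_max = 25e4, alpha = 0)
  expect_equal(active_scalar(st, 1, 0), 0)
  st <- phen_active_state(P_max = 25e4, alpha = 1,
                          fl_curve = function(l) 1,
                          fv_curve = function(v) 1)
  expect_equal(active_scalar(st, 1.3, 5), 25e4)
  st$alpha <- 0.5
  st$fl_curve <- function(l) 0.8
  expect_equal(active_scalar(st, 1, 0), 10e4)
  expect_error(phen_active_state(alpha = 1.2), "alpha")
})

test_that("default activation curves are normalized and windowed", {
  expect_equal(default_force_length(1), 1)
  expect_equal(default_force_velocity(0), 1)
  expect_equal(default_force_length(2.2), 0)
  expect_equal(default_force_length(0.3), 0)
  lam <- seq(0.4, 2.0, by = 0.01)
  expect_true(all(default_force_length(lam) >= 0 &
                  default_force_length(lam) <= 1))
  v <- seq(-12, 12, by = 0.25)
  expect_true(all(default_force_velocity(v) >= 0))
  # shortening reduces, lengthening enhances force
  expect_lt(default_force_velocity(-2), 1)
  expect_gt(default_force_velocity(2), 1)
})

test_that("phenomenological tensor maps along the deformed fiber", {
  st <- phen_active_state(P_max = 3e4, alpha = 1,
                          fl_curve = function(l) 1,
                          fv_curve = function(v) 1)
  expect_equal(active_stress_phenomenological(diag(3), arch_x, st),
               3e4 * diag(c(1, 0, 0)))
  off <- phen_active_state(P_max = 3e4, alpha = 0)
  expect_equal(active_stress_phenomenological(random_isochoric_F(3), arch_x,
                                              off),
               matrix(0, 3, 3))
  lam <- 1.02  # on the force-length plateau
  F <- uniaxial_F(lam)
  P <- active_stress_phenomenological(F, arch_x, st)
  expect_equal(P[1, 1], lam * 3e4, tolerance = 1e-12)
  expect_equal(P[, 2], c(0, 0, 0))
  expect_equal(P[, 3], c(0, 0, 0))
})

test_that("cross-bridge energy and force obey the linear-spring relations", {
  pars <- default_xb_parameters()
  empty <- crossbridge_population(pars$k_xb, numeric(0), pars$phi,
                                  pars$A_f_ref, pars$A_xf_ref)
  expect_equal(xb_energy(empty), 0)
  one <- crossbridge_population(2e-3, 4e-9, pars$phi, pars$A_f_ref,
                                pars$A_xf_ref)
  expect_equal(xb_energy(one), 1.6e-20, tolerance = 1e-12)
  two <- one; two$x <- 2 * one$x
  expect_equal(xb_energy(two), 4 * xb_energy(one), tolerance = 1e-12)
  expect_equal(xb_force(2e-3, 0), 0)
  expect_equal(xb_force(2e-3, 4e-9), 8e-12, tolerance = 1e-15)
  # force is the elongation-derivative of the energy
  h <- 1e-12
  num <- (0.5 * 2e-3 * (4e-9 + h)^2 - 0.5 * 2e-3 * (4e-9 - h)^2) / (2 * h)
  expect_equal(xb_force(2e-3, 4e-9), num, tolerance = 1e-6)
})

test_that("packaged population reproduces the isometric stress anchors", {
  pop <- default_crossbridge_population()
  Pf <- fiber_active_stress(pop, diag(3), arch_x)
  expect_equal(Pf[1, 1] / 1e4, 25, tolerance = 0.01)  # N cm^-2
  ratio <- crossfiber_active_stress(pop, diag(3), arch_x)[2, 2] / Pf[1, 1]
  expect_gt(100 * ratio, 5)
  expect_lt(100 * ratio, 10)
})

test_that("active stresses are linear in the attached population", {
  pop <- default_crossbridge_population()
  half <- pop; half$x <- pop$x[seq_len(length(pop$x) %/% 2)]
  F <- random_isochoric_F(11)
  arch <- rotated_arch(4)
  expect_equal(total_active_stress(half, F, arch) * length(pop$x) /
                 length(half$x),
               total_active_stress(pop, F, arch), tolerance = 1e-12)
  empty <- pop; empty$x <- numeric(0)
  expect_equal(total_active_stress(empty, F, arch), matrix(0, 3, 3))
})

test_that("hexagonal directions satisfy the lattice identity", {
  tn <- crossfiber_directions(arch_x)
  expect_equal(tn[, 1], arch_x$e2)  # phi_lattice = 0 starts at e2
  for (s in 1:50) {
    arch <- rotated_arch(s)
    tn <- crossfiber_directions(arch)
    expect_lt(max(abs(t(tn) %*% arch$a0f)), 1e-12)
    expect_equal(colSums(tn^2), rep(1, 6), tolerance = 1e-12)
    expect_lt(max(abs(tcrossprod(tn) -
                      3 * (diag(3) - structural_tensor(arch)))), 1e-12)
  }
})

test_that("six-term cross-fiber sum equals the collapsed closed form", {
  pop <- default_crossbridge_population()
  for (s in 1:10) {
    arch <- rotated_arch(s + 20)
    F <- random_isochoric_F(s + 40)
    expect_lt(rel_diff(crossfiber_active_stress(pop, F, arch,
                                                by_direction = TRUE),
                       crossfiber_active_stress(pop, F, arch)), 1e-12)
  }
})

test_that("homogenized cross-fiber stress is independent of the lattice angle", {
  pop <- default_crossbridge_population()
  F <- random_isochoric_F(5)
  base <- fiber_architecture(c(1, 0, 0), phi_lattice = 0)
  ref <- crossfiber_active_stress(pop, F, base, by_direction = TRUE)
  for (phl in c(0.3, 1.1, 2.9, 5.5)) {
    arch <- fiber_architecture(c(1, 0, 0), phi_lattice = phl)
    expect_lt(rel_diff(crossfiber_active_stress(pop, F, arch,
                                                by_direction = TRUE), ref),
              1e-12)
  }
})

test_that("active tensors are objective: P(QF) = Q P(F)", {
  pop <- default_crossbridge_population()
  st <- phen_active_state(P_max = 2e5, alpha = 0.8)
  for (s in 1:10) {
    F <- random_isochoric_F(s)
    Q <- random_rotation(s + 77)
    arch <- rotated_arch(s + 10)
    expect_lt(rel_diff(total_active_stress(pop, Q %*% F, arch),
                       Q %*% total_active_stress(pop, F, arch)), 1e-12)
    expect_lt(rel_diff(active_stress_phenomenological(Q %*% F, arch, st),
                       Q %*% active_stress_phenomenological(F, arch, st)),
              1e-12)
  }
})

test_that("additive split reduces and decomposes correctly", {
  F <- random_isochoric_F(9)
  p <- 3e3
  # zero activation: identical to the passive incompressible stress
  expect_equal(additive_total_stress(F, p, arch_x, nh_model, NULL)$P,
               pk1_incompressible(F, p, arch_x, nh_model)$P,
               tolerance = 1e-14)
  # components verified separately sum to the total
  pop <- default_crossbridge_population()
  total <- additive_total_stress(F, p, arch_x, fr_model, pop)$P
  parts <- pk1_incompressible(F, 0, arch_x, fr_model)$P +
    total_active_stress(pop, F, arch_x) - p * det(F) * t(solve(F))
  expect_lt(rel_diff(total, parts), 1e-14)
  # zero passive stiffness: active tensor minus pressure term
  mute <- passive_model("neo-hookean", mu = 0)
  expect_equal(additive_total_stress(F, p, arch_x, mute, pop)$P,
               total_active_stress(pop, F, arch_x) -
                 p * det(F) * t(solve(F)),
               tolerance = 1e-12)
})

test_that("population constructor validates its geometry", {
  expect_error(crossbridge_population(0, 1e-9, 1, 1e-15, 1e-14), "k_xb")
  expect_error(crossbridge_population(1e-3, 1e-9, 2, 1e-15, 1e-14), "phi")
  expect_error(crossbridge_population(1e-3, 1e-9, 1, -1, 1e-14), "areas")
})
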