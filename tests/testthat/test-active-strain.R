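test_that("both active deformation forms are unimodular on parameter grids", {
  for (s in 1:5) {
    arch <- rotated_arch(s)
    for (la in c(0.5, 0.7, 0.8, 1, 1.3, 1.6))
      expect_equal(det(build_Fa_fiber_contraction(la, arch)), 1,
                   tolerance = 1e-12)
    for (ga in seq(-0.6, 0.6, by = 0.15))
      for (di in c(2L, 3L))
        expect_equal(det(build_Fa_shear(ga, arch, di)), 1,
                     tolerance = 1e-12)
  }
  expect_error(build_Fa_fiber_contraction(0, arch_x), "positive")
  expect_error(build_Fa_fiber_contraction(-0.2, arch_x), "positive")
})

test_that("fiber-contraction form has the expected spectral structure", {
  expect_equal(build_Fa_fiber_contraction(1, arch_x), diag(3))
  expect_equal(build_Fa_fiber_contraction(0.8, arch_x),
               diag(c(0.8, 1 / sqrt(0.8), 1 / sqrt(0.8))),
               tolerance = 1e-14)
})

test_that("shear form is a rank-one unimodular update", {
  expect_equal(build_Fa_shear(0, arch_x), diag(3))
  Fa <- build_Fa_shear(0.2, arch_x, 2L)
  expected <- diag(3); expected[1, 2] <- 0.2
  expect_equal(Fa, expected, tolerance = 1e-14)
})

test_that("elastic part reconstructs the total deformation", {
  expect_equal(elastic_part(uniaxial_F(1.2), diag(3)), uniaxial_F(1.2))
  Fa <- build_Fa_fiber_contraction(0.85, arch_x)
  expect_equal(elastic_part(Fa, Fa), diag(3), tolerance = 1e-13)
  for (s in 1:10) {
    F <- random_isochoric_F(s)
    Fa <- build_Fa_fiber_contraction(0.6 + 0.05 * s, rotated_arch(s))
    Fe <- elastic_part(F, Fa)
    expect_lt(rel_diff(Fe %*% Fa, F), 1e-12)
  }
  expect_error(elastic_part(diag(3), matrix(0, 3, 3)), "singular")
})

test_that("active-strain stress reduces to the passive stress at Fa = I", {
  for (s in 1:10) {
    F <- random_isochoric_F(s)
    expect_equal(active_strain_stress(F, 2e3, arch_x, fr_model, diag(3))$P,
                 pk1_incompressible(F, 2e3, arch_x, fr_model)$P,
                 tolerance = 1e-14)
  }
})

test_that("activation alone with free boundaries produces no stress", {
  # F = Fa means the serial spring is unloaded (Fe = I); with the solved
  # pressure the sample contracts stress-free
  Fa <- build_Fa_fiber_contraction(0.8, arch_x)
  cal <- function(F, p) active_strain_stress(F, p, arch_x, nh_model, Fa)
  p <- solve_pressure(Fa, arch_x, cal, arch_x$e2)
  expect_lt(max(abs(cal(Fa, p)$P)), 1e-8)
})

test_that("pulled-back stress matches the chain-rule oracle", {
  for (s in 1:20) {
    F <- random_isochoric_F(s)
    arch <- rotated_arch(s + 5)
    Fa <- if (s %% 2) build_Fa_fiber_contraction(0.75 + 0.01 * s, arch)
          else build_Fa_shear(0.02 * s, arch)
    for (model in packaged_models) {
      analytic <- active_strain_stress(F, 1.5e3, arch, model, Fa)$P
      composed <- function(F, arch, model)
        passive_energy(elastic_part(F, Fa), arch, model)
      fd <- fd_stress_oracle(F, 1.5e3, arch, model, energy_fn = composed)
      expect_lt(rel_diff(analytic, fd), 1e-5)
    }
  }
})

test_that("pulled-back stress is objective", {
  Fa <- build_Fa_fiber_contraction(0.8, arch_x)
  for (s in 1:10) {
    F <- random_isochoric_F(s)
    Q <- random_rotation(s + 200)
    expect_lt(rel_diff(active_strain_stress(Q %*% F, 1e3, arch_x, fr_model,
                                            Fa)$P,
                       Q %*% active_strain_stress(F, 1e3, arch_x, fr_model,
                                                  Fa)$P), 1e-12)
  }
})

test_that("shrinking the internal stretch below 1 raises fiber tension", {
  sig11 <- vapply(c(1, 0.95, 0.9, 0.85, 0.8), function(la) {
    Fa <- build_Fa_fiber_contraction(la, arch_x)
    cal <- function(F, p) active_strain_stress(F, p, arch_x, fr_model, Fa)
    p <- solve_pressure(diag(3), arch_x, cal, arch_x$e2)
    cal(diag(3), p)$cauchy[1, 1]
  }, numeric(1))
  expect_true(all(diff(sig11) > 0))
  expect_equal(sig11[1], 0, tolerance = 1e-8)
})

test_that("generalized form recovers its three limits", {
  F <- random_isochoric_F(13)
  Fa <- build_Fa_fiber_contraction(0.85, arch_x)
  p <- 1e3
  zero <- passive_model("neo-hookean", mu = 0)
  # W2 -> 0: parallel spring only
  expect_equal(generalized_active_strain_stress(F, p, arch_x, nh_model,
                                                zero, Fa)$P,
               pk1_incompressible(F, p, arch_x, nh_model)$P,
               tolerance = 1e-12)
  # W1 -> 0: pure active-strain
  expect_equal(generalized_active_strain_stress(F, p, arch_x, zero,
                                                fr_model, Fa)$P,
               active_strain_stress(F, p, arch_x, fr_model, Fa)$P,
               tolerance = 1e-12)
  # Fa = I: passive with W1 + W2
  expect_equal(generalized_active_strain_stress(F, p, arch_x, nh_model,
                                                fr_model, diag(3))$P,
               pk1_incompressible(F, 0, arch_x, nh_model)$P +
                 pk1_incompressible(F, p, arch_x, fr_model)$P,
               tolerance = 1e-12)
})

test_that("packaged activation closures interpolate as documented", {
  rule <- make_Fa_rule("fiber-contraction", lambda_a_min = 0.7)
  expect_equal(rule(0, arch_x), diag(3))
  expect_equal(rule(1, arch_x), build_Fa_fiber_contraction(0.7, arch_x))
  expect_equal(rule(0.5, arch_x), build_Fa_fiber_contraction(0.85, arch_x))
  rule <- make_Fa_rule("fiber-shear", gamma_a_max = 0.3)
  expect_equal(rule(1, arch_x), build_Fa_shear(0.3, arch_x))
  custom <- make_Fa_rule("fiber-contraction",
                         closure = function(alpha) 1 - 0.1 * alpha^2)
  expect_equal(custom(1, arch_x), build_Fa_fiber_contraction(0.9, arch_x))
})
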