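# shared fixtures: architectures, models, and admissible deformations

arch_x <- fiber_architecture(c(1, 0, 0))

rotated_arch <- function(seed) {
  Q <- random_rotation(seed)
  fiber_architecture(Q %*% c(1, 0, 0), phi_lattice = (seed * 0.37) %% (2 * pi))
}

nh_model <- passive_model("neo-hookean", mu = 1e4)
mr_model <- passive_model("mooney-rivlin", c10 = 4e3, c01 = 1e3)
fr_model <- passive_model("fiber-reinforced", mu = 5e3, c1 = 2e3, c2 = 1.5)
packaged_models <- list("neo-hookean" = nh_model,
                        "mooney-rivlin" = mr_model,
                        "fiber-reinforced" = fr_model)

# relative Frobenius difference with a floor so zero tensors compare cleanly
rel_diff <- function(A, B, floor = 1) {
  max(abs(A - B)) / max(max(abs(A)), max(abs(B)), floor)
}

uniaxial_F <- function(lambda, arch = arch_x) {
  M <- structural_tensor(arch)
  lambda * M + lambda^(-0.5) * (diag(3) - M)
}
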