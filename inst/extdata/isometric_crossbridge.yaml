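# Isometric activation of the cross-bridge homogenization model at optimal
# length: F = I while activation ramps 0 -> 1. The branch_active_11 column
# of the final row shows the packaged unit-cell prediction of ~25 N cm^-2
# nominal fiber stress; sigma_11 is lower because the laterally-free
# pressure gauge subtracts the cross-fiber active stress.
model:
  framework: mixed
  W1:
    form: fiber-reinforced
    mu: 1.0e4
    c1: 2.0e3
    c2: 1.5
  active:
    type: crossbridge
    population:
      source: default
architecture:
  a0f: [1.0, 0.0, 0.0]
  phi_lattice: 0.0
protocol:
  kind: isometric-activation
  n_steps: 11
  alpha_ramp: [0.0, 1.0]
output:
  units: N/cm^2
  path: isometric_crossbridge.csv
seed: 1
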