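# Passive uniaxial fiber-direction stretch of an incompressible neo-Hookean
# sample; the driver table matches P11 = mu (lambda - lambda^-2).
model:
  framework: active-stress
  passive:
    form: neo-hookean
    mu: 1.0e4
  active:
    type: none
architecture:
  a0f: [1.0, 0.0, 0.0]
protocol:
  kind: uniaxial-fiber
  lambda_range: [0.7, 1.5]
  n_steps: 17
output:
  units: Pa
  path: uniaxial_passive.csv
seed: 1
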