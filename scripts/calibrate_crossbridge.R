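#!/usr/bin/env Rscript
# Calibration of the packaged cross-bridge unit-cell parameter set.
#
# Geometry and stiffness are standard sarcomere-physiology values:
#   - hexagonal myosin lattice, center-to-center spacing d = 45 nm
#     -> Wigner-Seitz cell area A_f = sqrt(3)/2 d^2, side s = d/sqrt(3)
#   - reference-volume length L = 0.72 um (cross-bridge-bearing overlap zone
#     of one half A-band) -> A_xf = mantle/6 = s * L
#   - cross-bridge stiffness k_xb = 2e-3 N/m (~2 pN/nm)
#   - transmission angle phi = 60 deg from the fiber axis
#   - N = 97 attached bridges per unit cell at full activation
#
# The one remaining free parameter, the post-powerstroke elongation x0, is
# solved from the isometric anchor: nominal fiber stress at F = I equal to
# 25 N cm^-2 (2.5e5 Pa). The printed value is frozen into
# default_xb_parameters() in R/fixtures.R.

target_Pa <- 2.5e5
d <- 45e-9
L <- 0.72e-6
k_xb <- 2e-3
phi <- pi / 3
N <- 97L

A_f <- sqrt(3) / 2 * d^2
A_xf <- d / sqrt(3) * L

x0 <- target_Pa * A_f / (cos(phi) * k_xb * N)

cat(sprintf("A_f_ref  = %.17e m^2\n", A_f))
cat(sprintf("A_xf_ref = %.17e m^2\n", A_xf))
cat(sprintf("x0       = %.17e m  (calibrated)\n", x0))
cat(sprintf("check: fiber stress = %.6f N cm^-2\n",
            cos(phi) / A_f * N * k_xb * x0 / 1e4))
cat(sprintf("check: cross-fiber/fiber ratio = %.4f %%\n",
            100 * (sin(phi) / (2 * A_xf)) / (cos(phi) / A_f)))
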