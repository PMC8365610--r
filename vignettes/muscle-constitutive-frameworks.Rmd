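---
title: "Active-stress, active-strain, and mixed constitutive frameworks for skeletal muscle"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Active-stress, active-strain, and mixed constitutive frameworks for skeletal muscle}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(musclemech)
```

## The modelling problem

Skeletal muscle is, mechanically, a fiber-reinforced incompressible soft
tissue that can generate stress on demand. On the cellular scale the sliding
filament and cross-bridge picture explains force generation: bound myosin
heads (cross-bridges) act as molecular springs between the thick and thin
filaments of the sarcomere lattice. On the tissue scale, the generated
stresses must be carried to the tendon either directly through the
actin–myosin skeleton or indirectly through shear of the extracellular
connective tissue — and a macroscopic constitutive model implicitly commits
to one of these transmission pictures.

`musclemech` implements the three standard commitments as separate, mutually
reducible stress evaluators on a common kinematic core:

* **additive (active-stress) split** — active and passive stresses are
  carried by independent parallel structures:
  $\mathbf{P} = \partial W/\partial\mathbf{F} + \mathbf{P}_a
  - p J \mathbf{F}^{-T}$;
* **multiplicative (active-strain) split** — activation changes the
  stress-free configuration of the tissue,
  $\mathbf{F} = \mathbf{F}_e \mathbf{F}_a$, and only the elastic remainder
  is loaded: $\mathbf{P} = (\partial W/\partial\mathbf{F}_e)\,
  \mathbf{F}_a^{-T} - p J \mathbf{F}^{-T}$;
* **mixed model** — a parallel spring $W_1(\mathbf{F})$, a serial spring
  $W_2(\mathbf{F}_e)$ behind the active element, and an additive active
  stress $\mathbf{P}_a$ together, so that each pure framework is an exact
  limit (`W2 = 0, Fa = I` gives the additive model; no active source and
  `W1 = 0` gives the multiplicative one). The test suite asserts these
  reductions at machine precision; they are the central structural
  correctness property of the package.

All evaluators treat the tissue as transversely isotropic about a referential
fiber direction $\mathbf{a}_0^f$ (structural tensor
$\mathbf{a}_0^f \otimes \mathbf{a}_0^f$) and strictly incompressible, with
the hydrostatic pressure $p$ a Lagrange multiplier fixed by boundary
conditions, never by the constitutive law.

## Passive energies

The framework does not prescribe a particular passive energy, so the package
ships the minimal standard representative of each symmetry class:
neo-Hookean $W = \tfrac{\mu}{2}(I_1 - 3)$, Mooney–Rivlin
$W = c_{10}(I_1-3) + c_{01}(I_2-3)$, and a fiber-reinforced form
$W = \tfrac{\mu}{2}(I_1-3) + \tfrac{c_1}{2c_2}
\bigl(e^{c_2 (I_4-1)^2} - 1\bigr)$ with $I_4 = \lambda_f^2$. The exponential
fiber term engages only in fiber extension by default (`tension_only`),
the usual convention for wavy collagenous reinforcement; the switch is
exposed because muscle titin plausibly also resists compression. Parameters
are stored in Pa; the conventional muscle-physiology unit is available on
output (1 N cm⁻² = 10⁴ Pa). No fitting to experimental passive data is
attempted — the package is about comparing frameworks, not calibrating any
one muscle.

Every analytic stress is validated against `fd_stress_oracle()`, a
component-wise second-order central difference of the energy that shares no
code with the analytic derivatives. For the multiplicative split the oracle
differentiates the *composed* energy $W(\mathbf{F}\mathbf{F}_a^{-1})$ with
respect to $\mathbf{F}$, which checks the pull-back
$\mathbf{F}_a^{-T}$ — the one genuinely error-prone piece of tensor calculus
in the package.

## The cross-bridge homogenization and its parameter set

The microstructural active-stress source sums the forces of $N_{xb}$
attached cross-bridges, each a linear spring $F_i = k_{xb} x_i$, over a
half-sarcomere unit cell of the hexagonal filament lattice, splitting each
bridge force by the transmission angle $\varphi$ into a fiber component
(divided by the cell cross-section $A_f^{ref}$) and a transverse component
(divided by $A_{xf}^{ref}$, one sixth of the cell's mantle surface). The six
transverse directions $\mathbf{t}_n$ point from the central myosin filament
to its six actin neighbours; their dyads satisfy
$\sum_n \mathbf{t}_n \otimes \mathbf{t}_n =
3(\mathbf{I} - \mathbf{a}_0^f \otimes \mathbf{a}_0^f)$ for any in-plane
lattice angle, which is why the homogenized cross-fiber stress is
transversely isotropic and collapses to a closed form. The package evaluates
the closed form but keeps the explicit six-term sum as an independent oracle
(`by_direction = TRUE`).

The packaged unit-cell parameters are standard sarcomere physiology:

| parameter | value | rationale |
|---|---|---|
| myosin lattice spacing $d$ | 45 nm | hexagonal lattice of vertebrate muscle |
| $A_f^{ref} = \tfrac{\sqrt3}{2} d^2$ | 1.754·10⁻¹⁵ m² | Wigner–Seitz cell |
| cell length $L$ | 0.72 µm | cross-bridge-bearing overlap zone of a half A-band |
| $A_{xf}^{ref} = d L/\sqrt3$ | 1.871·10⁻¹⁴ m² | one sixth of the hexagonal mantle |
| $k_{xb}$ | 2·10⁻³ N/m | ≈ 2 pN/nm molecular spring stiffness |
| $\varphi$ | 60° | oblique S1/S2 geometry bridging the interfilament gap |
| $N_{xb}$ | 97 | attached bridges per half-filament at full activation |

One parameter remains free: the post-powerstroke elongation $x_0$. It is
anchored (see `scripts/calibrate_crossbridge.R`) so that the nominal fiber
stress at $\mathbf{F} = \mathbf{I}$, optimal length and full activation
equals 25 N cm⁻², the specific tension of skeletal muscle; the calibrated
value, $x_0 = 4.52$ nm, is itself a physiologically sensible sustained
spring elongation (per-bridge force ≈ 9 pN). With the anchor fixed, the
cross-fiber to fiber stress ratio is *not* tuned — it follows from the
geometry as $\tan\varphi \cdot A_f^{ref} / (2 A_{xf}^{ref}) \approx 8.1\%$,
inside the 5–10 % band expected for lattice-mediated transverse stress.
The population sum $\sum k_{xb} x_i$ is allowed to be negative (bridges
compressed past the powerstroke); stresses are signed accordingly.

The state of the population is externally prescribed — there are no
attachment/detachment kinetics, no calcium dynamics, and no motor-unit
recruitment in the package. Activation enters only by detaching bridges:
`apply_activation()` keeps `round(alpha * N)` of them, mirroring the linear
relation between isometric tension and the fraction of active fibers.

## Hill-type scalar law

The phenomenological active source is
$P_a = P_{max}\, f_l(\lambda_f)\, f_v(\dot\lambda_f)\, \alpha$ mapped along
the deformed fiber direction. The packaged $f_l$ is a piecewise-linear tent
(zero below stretch 0.5, unit plateau at 0.945–1.055, zero above 1.8)
standing in for the filament-overlap curve; $f_v$ is a Hill hyperbola
normalized to $f_v(0)=1$ with maximal shortening rate 10 s⁻¹, curvature
0.25 and an eccentric plateau of 1.4. These shapes are deliberately simple
defaults — both curves are plain R functions and can be replaced, including
by tabulated data. The stretch rate is supplied by the loading protocol,
not finite-differenced inside the constitutive call, because the
force-velocity factor is a function of a prescribed velocity, not of the
deformation history.

## Internal variables of the multiplicative split

The active deformation $\mathbf{F}_a$ is an internal, non-observable
variable and its constitutive law is genuinely open; the package therefore
ships transparent closures rather than pretending to a physiological law:
$\lambda_a = 1 - \alpha(1 - \lambda_a^{min})$ with default
$\lambda_a^{min} = 0.7$ (a 30 % internal fiber shortening at full
activation, the order of sarcomere shortening against compliant series
tissue), and $\gamma_a = \alpha\,\gamma_a^{max}$ with default
$\gamma_a^{max} = 0.3$ (shear of thin endomysial sheets needs only modest
relative fiber motion). Both closures are swappable via `make_Fa_rule()`.
Only quasi-static schedules are supported — no rate equations for the
internal variable, consistent with neglecting viscous effects throughout.
The intermediate configuration is never materialized; it is incompatible,
and only the tensors $\mathbf{F}_a$, $\mathbf{F}_e$ exist in code.

Both packaged forms are unimodular by construction
($\det \mathbf{F}_a = 1$), so activation alone never changes volume; with a
fiber-reinforced serial spring, lowering $\lambda_a$ below 1 at fixed
$\mathbf{F} = \mathbf{I}$ monotonically raises the fiber elastic stretch
$1/\lambda_a$ and hence the isometric tension — the serial-pathway analogue
of turning activation up.

## The material-point driver and numerical choices

`run_protocol()` evaluates any framework along homogeneous deformation
paths. Numerical decisions, all of which are configurable:

* **Pressure solve.** The pressure contributes exactly $-p\mathbf{I}$ to the
  Cauchy stress under any deformation, so a zero-normal-traction gauge is
  solved in a single affine step, $p = \mathbf{d}\cdot\boldsymbol\sigma(0)
  \mathbf{d}$, and verified to a residual below $10^{-8}$ of the stress
  scale. Gauges: zero lateral stress for uniaxial loading, $\sigma_{33}=0$
  for simple shear (a gauge must be chosen; this is the conventional one).
* **Transverse-isotropy shortcut.** For fiber-aligned uniaxial loading the
  transverse stretches are set to $\lambda^{-1/2}$ by symmetry. For
  cross-fiber loading the symmetry is broken, so the free stretch ratio is
  found by Newton iteration (tolerance $10^{-10}$, at most 50 iterations,
  numeric derivative, damped to keep stretches positive) with the pressure
  eliminated analytically inside every iterate.
* **Incompressibility gate.** Stress evaluators reject deformations with
  $|\det\mathbf{F} - 1| > 10^{-9}$ (`tol_J`, configurable). The tolerance is
  a numerical guard, not a physical parameter.
* **Determinism.** Protocols contain no randomness; rerunning one yields a
  bit-identical table. All randomness in the package (rotation sampling,
  population draws, admissible-deformation fixtures) flows through explicit
  integer seeds and restores the caller's RNG stream.
* **Tie-breaks and degenerate inputs.** The tension-only fiber term makes
  the energy $C^1$ (not $C^2$) at $I_4 = 1$; the stress is continuous there
  and the finite-difference oracle remains within its stated $10^{-5}$
  agreement. Singular $\mathbf{F}$ or $\mathbf{F}_a$, activations outside
  $[0,1]$, non-orthogonal shear directions and unknown config keys all fail
  fast with informative errors rather than producing numbers.

## What the synthetic populations do and do not emulate

`generate_population()` draws elongation samples from a point mass, a
uniform window, or a two-point pre/post-powerstroke mixture (default post
fraction 0.7 — most attached bridges force-bearing under full activation,
the simplest population consistent with the working-stroke picture). The
deterministic packaged default used by the headline predictions is the
point-mass population at the calibrated $x_0$. These generators reproduce
the *mechanical* state of a population at one instant; they do not emulate
cross-bridge cycling, elongation correlations, filament compliance, or
length-dependent attachment. Tests passing on these populations therefore
validate the homogenization algebra and its geometric predictions — not
kinetic muscle behaviour.

Likewise, the material-point driver exercises homogeneous deformations
only. Nothing here discretizes a boundary-value problem: there is no
momentum balance, no spatial heterogeneity, no viscoelasticity, and no
titin-specific force enhancement. Problem sizes in the tests are small by
design (tens of protocol steps, 100 random deformations per oracle check,
10⁵-sample population moments) — every quantitative claim in the package is
desk-scale and recomputable in seconds.

## Known limitations

* The choice of passive energy for a given muscle, and the weighting
  between the active-stress and active-strain pathways of the mixed model,
  are modeller's assumptions; the package makes them explicit and testable
  but cannot decide them from macroscopic data.
* The transmission angle is held constant during deformation; in reality it
  co-varies with lattice spacing.
* The force-length curve always takes the total fiber stretch, also inside
  the mixed model. This is a deliberate design choice: the overlap argument
  concerns the visible sarcomere length, and letting the additive branch see
  the serial-branch elastic stretch instead would couple it to a
  non-observable internal variable. An elastic-stretch variant is easy to
  compose from the exported pieces but is not a packaged option.
* `alpha`-scaling of a cross-bridge population detaches whole bridges, so
  activation sweeps are stepwise linear for small populations.
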