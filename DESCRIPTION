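Package: musclemech
Title: Constitutive Frameworks for Active Skeletal-Muscle Tissue Mechanics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Transversely isotropic, incompressible hyperelastic constitutive
    models for skeletal muscle tissue with three alternative treatments of the
    active behaviour: an additive active-stress split (phenomenological
    Hill-type scalar law and a microstructural cross-bridge homogenization over
    the hexagonal actin-myosin filament lattice), a multiplicative active-strain
    split of the deformation gradient with volume-preserving fiber contraction
    and activation-induced shear forms, and a mixed model combining a parallel
    spring, a serial spring on the elastic part of the deformation, and an
    additive active-stress tensor. Includes a material-point driver for
    homogeneous deformation protocols (uniaxial, simple shear, isometric
    activation) with the incompressibility pressure solved from traction
    conditions, deterministic synthetic cross-bridge population generators, a
    finite-difference stress oracle, and YAML-configured command-line tools.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
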