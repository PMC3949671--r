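Package: cedsim
Title: Voxelized Porous-Media Simulation of Convection-Enhanced Delivery
    in Solid Tumors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Image-based finite-volume modelling of convection-enhanced
    delivery (CED) of macromolecular tracers into heterogeneous solid
    tumors. Per-voxel vascular leakiness (Ktrans) and porosity maps are
    estimated from dynamic contrast-enhanced (DCE) concentration curves
    with a two-compartment (Tofts) model, converted to heterogeneous
    hydraulic conductivity and effective diffusivity through
    porosity-dependent constitutive laws, and fed to coupled solvers for
    the steady interstitial pressure/velocity field (Darcy flow with
    Starling filtration and lymphatic drainage) and transient
    advection-diffusion tracer transport.  Includes a synthetic leg/tumor
    phantom generator, closed-form verification oracles, distribution
    volume analysis, and a flow-rate/catheter-site/conductivity parameter
    study driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    RNifti,
    jsonlite,
    minpack.lm,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests:
    deSolve,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
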