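Package: ionbz
Title: Conservative Electrodiffusion Modelling of Ischemic Border-Zone Ion
    Gradients in Myocardium
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the spatial and temporal evolution of ion concentrations
    across a myocardial ischemic border zone with a two-domain (intracellular /
    extracellular) electrodiffusion model that conserves every ionic species.
    Nernst-Planck transport of Na+, K+, Cl-, Ca2+, H+, HCO3-, lactate and CO2 in
    both domains is coupled to a passive (diastolic) cell-membrane model through
    an algebraic membrane potential, with rapid buffering, CO2 hydration, an
    equilibrium sarcoplasmic-reticulum calcium subsystem and pH-dependent
    gap-junction coupling. Transporter and channel densities are derived
    automatically from a zero-net-flux calibration at a referenced resting state,
    ischemia is imposed as sodium-potassium pump inhibition, background potassium
    channel activation and respiratory plus metabolic acidosis, and analysis
    tools quantify per-ion border-zone widths, drift/diffusion/transmembrane
    flux decompositions, clamped-potential counterfactuals and a qualitative
    validation grid of the membrane model. The fully implicit backward-Euler
    discretization is solved with a line-search Newton method on a sparse
    finite-difference Jacobian.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
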