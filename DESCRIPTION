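Package: kinforge
Title: Generative Adversarial Synthesis of Biologically Relevant Kinetic Metabolic Models
Version: 0.9.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for building populations of kinetic models of metabolism
    with prescribed dynamic properties. Provides a convenience-kinetics ODE
    core for stoichiometric networks with a thermodynamically consistent
    reference steady state; Monte Carlo sampling of enzyme saturations with
    back-calculation of Michaelis constants and maximal velocities so that
    every sampled model reproduces the reference fluxes; labelling of
    parameter sets as biologically relevant from the eigenvalues of the
    Jacobian at the reference state; a conditional generative adversarial
    network that learns the labelled parameter distribution and emits
    relevant parameter sets at high incidence; transfer learning of trained
    generators across flux-direction physiologies in the low-data regime;
    and validation via Kullback-Leibler divergence, Spearman correlation,
    perturbation-return analysis, trajectory PCA and parameter ranking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    graphics,
    tools,
    deSolve,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
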