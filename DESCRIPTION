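Package: pathdyn
Title: Transition Pathways and Enhanced Sampling on Model Energy Landscapes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Toolkit for computing conformational transition pathways and free
    energy profiles on analytic model potentials and synthetic bead-chain
    systems. Implements the zero-temperature string method for minimum energy
    paths, the finite-temperature string method in collective variables with
    mean-force estimation and potential-of-mean-force integration,
    well-tempered multiple-walker metadynamics over contact-map collective
    variables, diameter-bounded agglomerative clustering of conformational
    ensembles with cluster networks and geometric state classification,
    root-mean-square fluctuation analysis under flat-bottom restraints, and
    reaction-coordinate driving by successive restrained minimizations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    bio3d,
    yaml,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
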