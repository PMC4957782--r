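Package: nephronet
Title: Probability-Based Renal Arterial Trees and Coupled Nephron Dynamics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generates rat renal arterial networks as probability-based
    asymmetric bifurcating trees obeying Murray's law, either with afferent
    arterioles only at the terminal branch points (ABT) or with exponentially
    spaced arterioles branching off any vessel (kidney-specific KSABT).
    Couples the generated trees to a Poiseuille pressure network with
    diameter-dependent blood viscosity, an electrotonic gap-junction model of
    endothelial signal conduction, and a six-variable tubuloglomerular
    feedback nephron model, and provides simulation experiments for
    autoregulation, operating ranges and nephron-nephron synchronization.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    deSolve,
    Matrix,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
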