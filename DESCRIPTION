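Package: AntioxDesign
Title: Computer-Aided Design and Radical-Scavenging Kinetics of Antioxidant Candidates
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
                  role = c("aut", "cre"))
Description: A desk-scale workflow for computer-aided antioxidant design built
    around a caffeic-acid scaffold: combinatorial enumeration of derivatives
    with drug-likeness descriptors and rule filters (Lipinski, Ghose, Veber),
    desirability-based selection and elimination scoring against a reference
    compound set, fitted-parameter pKa estimation and polyprotic acid-base
    speciation, assembly of radical-scavenging rate constants from
    quantum-chemistry-derived free energies (transition state theory with
    Wigner or Eckart zero-curvature tunneling, Marcus theory for electron
    transfer, Collins-Kimball/Smoluchowski diffusion corrections, pH-weighted
    global rate coefficients), electron/hydrogen donating-ability maps, and
    reaction-force analysis of intrinsic-reaction-coordinate energy profiles.
    Includes a synthetic-data generator that emulates the quantum-chemistry
    stage so every step is testable without electronic-structure software.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports: methods, stats, utils, ChemmineOB, jsonlite, yaml
Suggests: testthat (>= 3.0.0), deSolve, knitr, rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
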