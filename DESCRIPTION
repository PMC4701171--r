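Package: denitpop
Title: Subpopulation Dynamics of Denitrification Kinetics in Batch Culture
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Simulates growth and respiration of Paracoccus denitrificans in
    gas-tight batch vials, where stochastic initiation of nar and nirS
    transcription divides the culture into four subpopulations whose coupled
    respiration explains transient nitrite accumulation, the gradually rising
    nitrous oxide trace, and dinitrogen production. Provides a hybrid
    ODE/discrete-event simulator (Michaelis-Menten electron competition,
    Henry's-law headspace-liquid gas transfer, headspace sampling
    perturbations), closed-form recruited-fraction summaries, least-squares
    calibration of recruitment probabilities, and a synthetic-observation
    generator emulating robotised incubation measurements.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports: deSolve, jsonlite, stats, tools, utils, yaml
Suggests: testthat (>= 3.0.0), withr, optparse
Config/testthat/edition: 3
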