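Package: frontostriatal
Title: Frontostriatal Circuit Model of Striatal Dopamine and D2 Receptor
    Occupancy in Schizophrenia
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A system-level model of the frontostriatal circuit (prefrontal
    cortex, striatum, midbrain dopamine nuclei) coupled to single-site D2
    receptor binding theory.  Provides the linearized equilibrium analysis of
    striatal activity and dopamine release under presynaptic D2 hetero- and
    autoreceptor modulation, calibration of patient and control receptor
    parameters from dopamine-depletion (AMPT) imaging occupancies, the
    net-binding criterion for the optimum antipsychotic D2 occupancy under
    competitive binding, and the transformation linking depletion-induced
    binding-potential increases to prefrontal activity and symptom change.
    Includes synthetic-data generators for parameter-recovery testing and a
    command-line front end that regenerates the model's tables and curves.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
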