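Package: chronoclock
Title: In Silico Genetics of the Mammalian Circadian Clock with the
    CHRONO Repressor
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Mechanistic modelling of the mammalian circadian
    transcription-translation feedback loop with two independent
    stoichiometric repression channels acting on the BMAL1-CLOCK
    activator: PER-CRY sequestration and a CRY-independent CHRONO
    channel. Provides a rule-based constructor for CHRONO-containing
    protein complexes, an in-silico genetics engine (knockout,
    fractional knockdown, constitutive overexpression), stiff ODE
    integration with limit-cycle detection and period calibration, and
    the rhythm-analysis stack used for behavioural and bioluminescence
    recordings: chi-squared periodogram, running-mean detrending,
    damped-cosine fitting, and phase/amplitude summaries. Includes
    seeded generators for synthetic locomotor actograms,
    bioluminescence traces and qPCR time courses.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    deSolve,
    minpack.lm,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'chronoclock-package.R'
    'AllClasses.R'
    'params.R'
    'species.R'
    'model-build.R'
    'perturbation.R'
    'integrate.R'
    'cycle.R'
    'periodogram.R'
    'detrend.R'
    'damped-fit.R'
    'phase.R'
    'synthetic.R'
    'io.R'
    'scenarios.R'
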