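Package: camnet
Title: Equilibrium Binding-Network Models of Calcium/Calmodulin/MLCK and
    Model Discrimination
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Equilibrium reaction-network models of Ca2+ and myosin light
    chain kinase (MLCK) binding to calmodulin (CaM): the fully random
    (Model 1), partially ordered (Model 2) and fully ordered (Model 3)
    mechanisms, for wild-type CaM and EF-hand knockout mutants. Computes
    closed-form fraction-bound titration curves at clamped free Ca2+,
    qualitative binding/no-binding prediction tables, and the
    model-falsification logic used to discriminate between mechanisms.
    Includes a synthetic plate-reader FRET and on-bead densitometry data
    generator, rank-test and area-under-curve comparisons, four-parameter
    Hill dose-response fitting, and Monte-Carlo parameter-sensitivity
    sweeps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    minpack.lm,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    pracma
Config/testthat/edition: 3
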