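Package: dualTS
Title: Dual Tight-Binding Inhibition Kinetics and Synergy Analysis for
    Thymidylate Synthase
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantitative analysis of the simultaneous inhibition of human
    thymidylate synthase (hTS) by a nucleotide-site inhibitor (FdUMP, the
    active metabolite of 5-fluorouracil) and a folate-site inhibitor
    (raltitrexed). Implements a rapid-equilibrium partition-function rate
    law for the seven-species binding scheme with two substrates and two
    inhibitors sharing one catalytic cavity, Morrison-type tight-binding
    analysis of single-inhibitor dose-response data with inhibitor
    depletion, Dixon-plot tangent and combination-index (Loewe
    isobologram) synergy statistics at the enzyme level, synergism
    quotients for cell-growth inhibition data, and geometric contact
    analysis (hydrogen bonds, ring stacking, superposition RMSD) of
    ternary-complex coordinates. Includes seeded synthetic-data
    generators for progress curves, dose-response plates, cell plates
    and toy coordinate files so that every stage of the pipeline can be
    exercised without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    minpack.lm,
    pracma,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
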