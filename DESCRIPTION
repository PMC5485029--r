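Package: hypothermAb
Title: Kinetic Modelling of CHO Fed-Batch Culture, Antibody Synthesis and
    Fc N-Glycosylation Under Mild Hypothermia
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Coupled kinetic model of fed-batch Chinese hamster ovary (CHO)
    cell culture with a mid-culture temperature shift to mild hypothermia.
    Combines Monod-type cell growth and metabolism, a structured
    heavy-chain/light-chain antibody synthesis and secretion model, de novo
    nucleotide and nucleotide-sugar-donor (NSD) metabolism, and a Golgi
    plug-flow-reactor model of Fc N-linked glycan processing. Provides
    event-aware stiff ODE simulation of bolus-fed bioreactor runs with
    regime switching at the shift time, maximum-likelihood parameter
    estimation with multistart local optimization and normal-approximation
    confidence intervals, two-temperature parameter comparison, and a
    synthetic fed-batch data generator for testing parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    deSolve,
    lhs,
    pracma,
    yaml,
    jsonlite
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
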