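Package: ciflow
Title: Cytoplasmic Incompatibility Dynamics and Coupling with Host
    Reproductive Isolation Barriers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies whether a cytoplasmic-incompatibility (CI) inducing
    endosymbiont such as Wolbachia would introgress between hybridizing host
    populations. Estimates individual reproductive-isolation barriers from
    raw assay tables (allochronic isolation from adult eclosion phenology,
    sexual isolation from no-choice mating trials, CI strength from egg-hatch
    reductions in hybrid crosses), couples them into a probability of gene
    flow, and compares that probability against closed-form critical
    migration rates for unidirectional and bidirectional CI. A deterministic
    discrete-generation simulator of endosymbiont frequency dynamics in one
    and two host populations verifies the closed forms by locating invasion
    thresholds with bisection. Includes seeded generators that emulate the
    statistical structure of the underlying assays so the full pipeline is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
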