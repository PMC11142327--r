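Package: antsembly
Title: Parse, Translate and Simulate Human-Readable Reaction-Network Models
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A compiler and execution engine for a concise, human-readable
    text language for biochemical reaction networks in the Antimony style.
    Model text is tokenized and parsed into an abstract syntax tree, resolved
    into a validated semantic model (species, parameters, reactions, rules,
    events, metadata, uncertainty annotations and flux-balance constraints),
    and translated to and from SBML Level 3 Version 2 XML, including the
    Distributions and Flux Balance Constraints (version 1) packages. A
    deterministic ODE compiler with event localisation gives the language's
    constructs (kinetic laws, assignment and rate rules, rateOf, seeded
    probability-distribution draws, discrete events) verifiable numerical
    semantics.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    xml2,
    deSolve,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
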