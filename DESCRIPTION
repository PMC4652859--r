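Package: aim
Title: Allosteric Ising Models for Coarse-Grained Two-State Biomolecular
    Systems
Version: 1.0.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Exact statistical-mechanical analysis of small networks of
    two-state structural components ("Allosteric Ising Models").  Systems are
    declared as components with conformational energies and pairwise
    couplings, solved exactly by full state enumeration, and interrogated for
    allosteric efficacies, effective interaction energies, conditional and
    indirect channel contributions, closed-form single- and multi-channel
    expressions, mutual information and symmetric uncertainty.  Includes
    random-ensemble experiments that test the Ising-derived estimators on
    general (non-Ising) two-state systems, and a worked coarse-grained model
    of the asymmetric dopamine D2 receptor homodimer signaling complex.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
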