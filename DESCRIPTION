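Package: subsite
Title: Peptidase Substrate Specificity Profiling and Cleavage-Site Conservation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for curating peptidase substrate-cleavage collections in
    Schechter-Berger P4-P4' subsite nomenclature: per-pocket specificity
    count matrices with decile shading, sequence-logo weights, a pairwise
    reliability score for substrate diversity, rule-based calling of pocket
    preferences and negative preferences, derivation of processing-event
    cleavages from UniProt flat-file annotations, and an "analyse substrates"
    service that scores conservation of cleavage sites across orthologue
    alignments by counting replacements never observed in the peptidase's
    binding pockets. Includes seeded generators for synthetic collections
    and alignments, and a command-line interface.
License: MIT
Encoding: UTF-8
Imports:
    Biostrings,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
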