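Package: nucassign
Title: Nucleic Acid Sequence Assignment, Identification and Validation for
    Cryo-EM and Crystallographic Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for interpreting nucleic-acid components of atomic models
    built into cryo-EM or crystallographic density maps. Provides a
    density-based purine/pyrimidine classifier operating on fixed-geometry
    residue descriptors, sequence-independent base-pair detection by
    superposition of short backbone fragments of known secondary structure,
    probabilistic assignment of continuous polynucleotide fragments to target
    sequences with extreme-value p-values, covariance-model and profile-HMM
    sequence-database queries, base-pair restraint generation for popular
    refinement programs, and a synthetic-data generator (idealized duplexes
    and simulated maps) used throughout the test suite.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    Biostrings,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
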