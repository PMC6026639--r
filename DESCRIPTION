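Package: amylscan
Title: Aggregation-Propensity Scanning and De Novo Design of Amylin Variants
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Per-residue aggregation-propensity scoring of peptides with an
    AGGRESCAN-style windowed scale (a3v/a4v profiles, hot-spot detection and
    the length-normalised Na4vSS summary score), sequence-level
    physicochemical profiling (Kyte-Doolittle hydropathy, Henderson-Hasselbalch
    net charge and isoelectric point, Eisenberg hydrophobic moment), cross-species
    variant cataloguing from aligned sequence panels, and exhaustive single and
    multi-residue substitution scanning that ranks candidate islet amyloid
    polypeptide (IAPP/amylin) analogues against a reference sequence. Includes
    a seeded generator of synthetic cross-species sequence panels and a small
    command-line front-end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    seqinr,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
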