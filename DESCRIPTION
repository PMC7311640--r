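Package: bifhyd
Title: Discriminating Electron-Bifurcating from Non-Bifurcating
    NADH-Dependent Hydrogenase Beta Subunits
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Sequence-analysis toolkit for classifying the flavin-binding
    beta subunits (HydB/NuoF/Nqo1 homologs) of multimeric [FeFe]-hydrogenases
    and formate dehydrogenases as electron-bifurcating or non-bifurcating
    NADH-dependent enzymes. Implements reference-anchored residue
    fingerprints read off pairwise global alignments to a reference scaffold
    (T. maritima HydB numbering), cysteine-spacing motif scanning for
    iron-sulfur cluster domains with predicted iron stoichiometry,
    distance-based (neighbor-joining) phylogeny with a monophyly check,
    Nernst-equilibrium thermodynamics linking NADH/NAD+ ratios to hydrogen
    partial pressures relevant to syntrophic hydrogen transfer, routine
    protein biochemistry calculations (mass, isoelectric point, specific
    activity, purification statistics), and a seeded generator of
    beta-subunit-like synthetic sequences with planted fingerprints for
    validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    ape,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
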