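Package: pamkit
Title: PAM Depletion Screen Analysis and Quantitative Assay Fitting for
    CRISPR Helicase Characterization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for protospacer adjacent motif (PAM)
    depletion screens of CRISPR immune systems, from raw sequencing reads
    to an IUPAC consensus and a Krona PAM wheel: target-anchored 5-nt PAM
    extraction, counting over the 1024-PAM space, replicate pooling,
    depletion-score computation, position-wise base preferences, and
    consensus calling with anti-targeting detection. Companion fitting
    tools for the quantitative biochemistry of helicase characterization:
    malachite-green phosphate standard curves and initial velocities,
    Michaelis-Menten ATPase kinetics, Beer-Lambert quantitation,
    single-site fluorescence-anisotropy binding fits, helicase
    percent-unwound time courses, circular-dichroism unit conversion, and
    plasmid-clearance colony-forming-unit ratios. A seeded synthetic-data
    generator emulates every raw input with full ground-truth bookkeeping
    for parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    minpack.lm,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
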