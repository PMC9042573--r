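Package: supscreen
Title: Analysis of Site-Directed Saturation-Mutagenesis Suppressor Screens
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the quantitative analysis of site-directed
    saturation-mutagenesis suppressor screens on protein domains, built
    around the cohesin Psm3 head-coiled-coil junction / Rad21 N-terminal
    domain system. Provides parsing and validation of suppressor
    substitution tables, position-by-amino-acid substitution matrices,
    per-position substitution counts and mean relative molecular-weight
    and Kyte-Doolittle hydropathy profiles, Shannon-entropy conservation
    scoring from multiple sequence alignments, structure-based annotation
    of interface contacts and hydrophobic-core residues, Kabsch rigid-body
    superposition with a coiled-coil segment rotation measurement, and a
    seeded simulator of NNN-codon mutagenesis screens so the entire
    pipeline runs on synthetic data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    bio3d,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
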