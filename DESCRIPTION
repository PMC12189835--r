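Package: gdtr
Title: Gamma-Delta T Cell Receptor Complex Modeling and Interface Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying gamma-delta T cell receptor (TRG_TRD)
    complexes with CD1D and beta-2-microglobulin in species with highly
    diversified delta-chain repertoires such as the dromedary camel.
    Implements IMGT unique numbering for V domains (including the 111/112
    CDR3 insertion scheme) and for MH-like G domains (letter insertions),
    CDR3-IMGT junction delimitation and D-segment attribution of rearranged
    V-(D)-J cDNA clones, alignment-guided template threading with Kabsch
    superposition, geometric classification of protein-protein interface
    interactions (ionic, hydrogen bond, aromatic, cation-pi, hydrophobic),
    and a transparent unfold-and-subtract interface energy with per-term and
    per-residue decomposition. Ships synthetic fixture generators with full
    ground-truth records for every planted feature.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    bio3d,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
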