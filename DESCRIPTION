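Package: retromark
Title: Retroposon Presence/Absence Markers for Phylogenetics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for retrophylogenomic analysis with short interspersed
    element (SINE) and other retroposon insertion markers. Calls per-taxon
    presence/absence states from per-locus multiple sequence alignments under
    strict validity criteria (orthologous insertion point, orientation,
    subtype, target site duplication), maps markers onto a rooted species tree
    with Dollo-consistency checking and conflict detection, tests branch
    support against a hard-polytomy null, characterizes chimeric tRNA-head /
    CR1-tail SINE families (majority-rule consensus, head/tail partition,
    diagnostic sites, terminal microsatellite), computes CpG-excluded Kimura
    2-parameter divergence landscapes, and concatenates element-stripped
    flanking sequences into a supermatrix. A simulation module generates
    synthetic marker loci with full truth tables so every stage can be
    validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
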