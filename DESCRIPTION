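Package: conformap
Title: Conformational Classification of Nanobody CDR-H3 Loops and Camelid
    Immune Repertoire Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to classify the CDR-H3 loop conformation of single-domain
    camelid antibodies (VHH / nanobodies) from Chothia-numbered structures using
    the alpha101 pseudo-dihedral and tau101 pseudo-bond angles over C-alpha stem
    atoms, to map framework-2 / CDR-H3 residue contacts with C-terminally
    anchored insert numbering, to quantify solvent accessibility and per-region
    paratope buried area by a Shrake-Rupley implementation, and to analyse
    UMI-tagged B-cell receptor repertoire sequencing reads from paired FASTQ
    through consensus building, V(D)J germline assignment, junction trimming
    metrics and isotype calls. Includes seed-deterministic synthetic generators
    for VHH backbones with prescribed stem angles, toy antigen complexes, and
    V(D)J recombination read simulation with ground-truth tables, so every
    analysis step is testable without external data.
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
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
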