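Package: pepassembly
Title: Hydrogen-Bond Pattern Analysis of Self-Assembling Pentapeptides
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to characterise the early self-assembly of the
    tumor-homing pentapeptide CREKA and its backbone N-methylated variant
    CRE(NMe)KA from all-atom structural snapshots. Detects hydrogen bonds
    and salt bridges with geometric criteria, partitions chains into
    aggregates, classifies every hydrogen bond into seven pattern
    categories stratified by aggregate size, assigns parallel or
    antiparallel orientation to beta-sheet strand pairs, computes
    pH-dependent dominant-state net charges and counterion requirements,
    generates synthetic all-atom test systems (ideal strands, sheets,
    turns, salt-bridged dimers and minimum-bias multi-chain boxes), and
    includes a lattice simulator of the two-step diffusion-limited
    dendrite-formation mechanism with box-counting fractal-dimension
    estimation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    igraph,
    jsonlite,
    Rcpp,
    stats,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    bio3d,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
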