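Package: pikkmap
Title: Conservation and Structural Mapping of Cancer-Associated Mutations
    in PIKK-Family Kinases
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of cancer-associated missense mutations in the
    DNA-damage-response kinases ATM and ATR and their budding-yeast
    orthologs Mec1 and Tel1. Ingests cBioPortal-style mutation export
    tables, classifies protein-level consequences and computes per-gene
    mutation frequencies and per-cancer-type mutated-residue sets; maps
    residue positions across species via affine-gap global alignment and
    calls evolutionarily conserved residues; parses PDB coordinate models,
    computes Shrake-Rupley solvent-accessible surface area with
    surface/buried classification, inter-residue distances and
    single-linkage spatial clusters; performs binomial and hypergeometric
    domain-enrichment and residue-set overlap statistics; and generates
    fully synthetic cohorts, ortholog families and toy structures with
    known ground truth so the entire pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    bio3d,
    Biostrings,
    igraph,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
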