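Package: ligtrans
Title: Ligand Transference Across Protein-Chemical Complex Structures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts new protein-chemical interactions from the network of
    solved protein-ligand complex structures. For triplets of complexes in
    which two proteins share a common ligand and one of them binds a second
    ligand, the package composes a protein-based and a ligand-based rigid
    superposition to transfer the second ligand into the other protein's
    binding site, then judges the structural viability of the putative
    complex with a seven-descriptor empirical score (clash volume, contacts,
    hydrogen bonds, van der Waals contacts, unsatisfied and solvent-exposed
    polar atoms, uncontacted carbons) normalised against a decoy reference
    of randomly swapped ligands, and reports an empirical p-value. Includes
    structure parsing (PDB and mmCIF), bipartite protein-chemical network
    construction and candidate filtering, a deterministic synthetic-fixture
    generator, and a pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    bio3d,
    Biostrings,
    igraph,
    Rcpp,
    jsonlite,
    tibble,
    dplyr,
    tidyr,
    purrr,
    ggplot2,
    rlang,
    generics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    ChemmineR
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
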