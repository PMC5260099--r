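Package: mutclust3d
Title: Detection of Significantly Mutated 3D Clusters in Protein Structures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Identifies clusters of somatic missense mutations that are close
    together in protein three-dimensional space more often than expected by
    chance. Residue contact maps are computed from PDB structures at a 5
    Angstrom any-atom cutoff, one candidate cluster is formed per residue
    (the residue plus its contact neighbors), and each cluster is scored by
    the number of mutated tumor samples it contains. Significance is
    assessed with a permutation test that shuffles per-residue mutation
    counts over the aligned region of the structure, caps decoy counts at
    the largest count inside the assessed cluster so that dominant
    single-residue hotspots elsewhere in the gene do not mask modest
    clusters, and compares the observed score against the maximum cluster
    score in each decoy. Includes germline and expression mutation filters,
    sequence-to-structure alignment handling, catalog assembly with residue
    categorization, an exact enumeration oracle for small problems, and a
    synthetic fixture generator so the whole pipeline is testable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    Matrix,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
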