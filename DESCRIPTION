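Package: chaindyn
Title: Conformational Dynamics of Coarse-Grained Protein Chains
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Post-processing toolkit for alpha-carbon protein trajectories
    treated as polymer chains. Computes end-to-end statistics and the
    Flory-De Gennes size exponent, RMSD series, backbone planar and
    dihedral angles along the C-alpha trace, Ramachandran-histogram
    conformational entropy, Fisher's exact g-test for hidden periodicity
    in entropy time series, Kruskal-Wallis and Conover-Iman rank
    comparisons across temperature ensembles, and Kullback-Leibler
    divergence between histogram distributions. Includes a seeded
    synthetic-trajectory generator (freely jointed, confined and
    noisy-helix chain models) so the full analysis pipeline runs without
    external molecular-dynamics data, plus multi-model PDB input/output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
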