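Package: rcugdyn
Title: Coarse-Grained Elastic Network and Ensemble Dynamics of CUG-Repeat RNA
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Comparative dynamics analysis of RNA CUG trinucleotide repeats:
    anisotropic network models (ANM) with a distance-dependent force constant,
    principal component analysis of aligned structural ensembles, essential
    dynamics on trajectory snapshots, mode-comparison metrics (overlap,
    cumulative overlap, essential subspace overlap, collectivity), ANM-driven
    conformer generation, and geometric classification of non-canonical U-U
    base pairs (types I-VI) including average-linkage clustering of their
    conformations. Includes an idealized A-form (CUG)n duplex builder and
    low-rank Gaussian ensemble generators so every stage runs without external
    structure files.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
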