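Package: protfid
Title: Distributional Evaluation of Protein Structure Ensembles with the
    Frechet Distance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Compares a set of generated protein backbones against a
    reference ensemble with a Frechet distance between Gaussian fits of
    structure embeddings (a protein FID), together with the companion
    validation machinery: an optimal-transport distance built on
    symmetrized TM-score costs, cluster-aware diversity races, per-sample
    influence gradients of a softmax-weighted FID, controlled coordinate
    perturbations, secondary-structure-aware contact-order statistics and
    greedy motif-cover analyses. Includes a deterministic geometric
    featurizer and synthetic backbone and embedding generators so the whole
    pipeline runs without pretrained network weights or downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
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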