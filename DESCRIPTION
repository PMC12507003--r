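Package: burrowtrack
Title: RFID Colony Tracking, Behavioral Phenotyping and Social Network
    Inference for Group-Housed Burrowing Rodents
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for reconstructing grid-cell locations of group-housed
    burrowing rodents (such as naked mole-rats) from raw RFID detection
    logs, segmenting and classifying stay events (Rest, Nest, Toilet,
    Garbage, Other), extracting daily behavioral parameter vectors and
    clustering them into behavioral phenotypes via UMAP embedding and
    watershed segmentation of a smoothed density map, quantifying
    within-individual phenotype consistency with an entropy-based index
    and Monte-Carlo nulls, computing dyadic activity-rhythm synchrony,
    spatial proximity and directional follow indices against
    cyclic-permutation surrogate distributions, and building
    significance-thresholded weighted social networks with strength
    centrality. An agent-based synthetic colony simulator with planted
    rhythm coupling, co-location preference and follower-followee
    relationships provides ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    uwot,
    EBImage,
    car,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
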