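Package: CoFracNet
Title: Co-Fractionation Mass Spectrometry Complex Discovery
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Toolkit for inferring protein complexes from co-fractionation
    mass spectrometry (CF-MS) experiments. Takes per-fraction protein
    quantitation profiles (MS2 spectral counts and MS1 intensities),
    derives four pairwise co-elution scores per experiment (Pearson
    correlation with added Poisson noise, weighted cross-correlation,
    co-apex score, and an MS1 Euclidean-profile similarity), harmonizes
    multi-species score tables into a reference namespace via ortholog
    maps, trains a probabilistic co-complex classifier with
    complex-held-out cross-validation, thresholds the scored network at a
    target precision, clusters it into putative (possibly overlapping)
    complexes by cohesiveness growth, and projects the network to other
    species by orthology. A built-in simulator generates multi-species
    fractionation worlds with known complexes so every stage is testable
    end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    yaml,
    ranger
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
biocViews: Proteomics, MassSpectrometry, NetworkInference, Clustering
RoxygenNote: 7.3.3
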