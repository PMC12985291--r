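Package: wildtrace
Title: Screening Pipeline for Concealed-Wildlife Detection and pXRF Dosimetry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computational spine of an end-to-end wildlife-trafficking screening
    workflow. Provides a synthetic-phantom generator for 3D X-ray parcel volumes,
    two concealed-animal detection pipelines over reconstructed radiodensity
    volumes (a random-forest blob classifier and a maximum-intensity-projection
    embedding pipeline with a five-layer dense head), an analytic X-ray tube
    spectrum and Beer-Lambert dosimetry model for portable-XRF exposure of
    lizards through a keratin scale layer, and the trial-level statistical
    analyses (detection-rate aggregation, pooled one-tailed two-proportion
    z-test, provenance abstention rule and seizure tallies).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    igraph,
    randomForest,
    RNifti,
    EBImage,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'accessors.R'
    'utils.R'
    'synth.R'
    'detect-segment.R'
    'detect-features.R'
    'detect-at2.R'
    'detect-embed.R'
    'detect-at3.R'
    'detect-parcel.R'
    'detect-benchmark.R'
    'dose-data.R'
    'dose-spectrum.R'
    'dose-dosimetry.R'
    'stats.R'
    'io-volume.R'
    'fixtures.R'
    'pipeline.R'
    'zzz.R'
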