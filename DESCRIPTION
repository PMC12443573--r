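Package: spadGWAS
Title: UAV Multispectral Chlorophyll Inversion and Mixed-Model GWAS for Wheat
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: End-to-end analysis of drone-based multispectral phenotyping of
    wheat chlorophyll (SPAD) under irrigation and drought: radiometric
    calibration of digital-number imagery against a reference whiteboard,
    zonal extraction of per-plot band reflectance, computation of eighteen
    vegetation indices, random-forest plus correlation based index selection,
    a backpropagation neural-network SPAD inversion model, descriptive trait
    statistics with ANOVA broad-sense heritability, and a Q+K mixed linear
    model genome scan with LD-decay based locus merging and measured-versus
    -predicted locus comparison. A seeded synthetic-data module generates
    genotypes with population structure, replicated SPAD trials with planted
    QTLs, and five-band plot scenes so the whole pipeline is testable without
    field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    tiff,
    randomForest,
    S4Vectors,
    IRanges,
    GenomicRanges,
    rtracklayer
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
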