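Package: quadfoot
Title: Footprinting, Splicing and Binding Readouts of G-Quadruplex Ligand
    Action on pre-mRNA
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative pipeline for mapping where a G-quadruplex (G4)
    ligand remodels a pre-mRNA and how that shifts alternative 5' splice-site
    choice. Implements 1-D gel-lane densitometry (band detection, Gaussian
    area fitting, nucleotide assignment), the per-nucleotide V1/T2 cleavage
    index with an empirical Gaussian null and 2-SD significance calling,
    guanine-count-corrected splicing isoform quantification, G4 candidate
    motif scanning, and fluorescence emission-spectrum binding classification.
    A synthetic-data generator with known ground truth (annotated transcripts,
    footprinting lanes, radiolabeled splicing gels, two-state binding spectra)
    makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    Biostrings,
    SummarizedExperiment,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
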