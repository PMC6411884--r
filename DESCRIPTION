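Package: paleoQC
Title: Quantitative Integrity Assessment of Ancient Nuclei, Proteins and DNA
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify how well biological material has survived
    post-mortem, combining three independent assays. An imaging track
    segments nuclei in two-channel 3D fluorescence stacks and computes a
    DNA damage index (DDI), the integrated gamma-H2A.X signal normalized
    by histone H2B and scaled so the reference cohort's median equals 1,
    together with many-to-one nonparametric (Steel-type) testing and
    Fisher exact tests on developmental outcomes. A proteomics track
    scores collagen deamidation from peptide-spectrum-match tables and
    quantifies deamidated peptide fractions from extracted-ion
    chromatograms with isotope-interference-aware peak decomposition. A
    genomics track profiles terminal cytosine-deamination damage in
    aligned ancient-DNA reads, fits a geometric decay model, analyses
    nucleosome-scale fragment-length distributions, and applies
    depth/allele-count thresholds for variant filtering. A synthetic-data
    module generates every input class with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    igraph,
    jsonlite,
    minpack.lm,
    pracma,
    rlang,
    Rsamtools,
    stats,
    tibble,
    tiff,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
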