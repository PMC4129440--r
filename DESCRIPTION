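Package: aneuprot
Title: Copy-Number-Aware Proteome Analysis of Aneuploid Yeast
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative-proteomics toolkit for disomic (single extra
    chromosome) yeast strains. Rolls peptide-level SILAC and TMT
    measurements up to protein log2 ratios with the platform-appropriate
    filters, recenters ratio distributions copy-number-awarely, decomposes
    duplicated-gene log2-ratio histograms into one- or two-Gaussian models
    to detect dosage compensation, calls attenuated proteins, quantifies
    protein-complex attenuation and enrichment, discovers a consistent
    aneuploidy-associated protein signature by weighted correlation
    clustering, analyses short turnover-inhibition timecourses, and ships a
    synthetic disome study generator so the whole pipeline runs with known
    ground truth and no external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    utils,
    minpack.lm,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
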