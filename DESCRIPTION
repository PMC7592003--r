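Package: refstab
Title: Endogenous Reference Selection for RT-qPCR Cq Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for identifying stable endogenous normalizers from RT-qPCR
    quantification-cycle (Cq) matrices, aimed at circulating (serum) miRNA
    studies where no universal reference gene exists. Provides dispersion
    screening (SD, IQR, CV of raw Cq), from-scratch implementations of the
    geNorm M-value / pairwise-variation algorithm, the NormFinder
    variance-decomposition model, and the comparative delta-Cq statistic,
    plus consensus ranking across the three methods. Reference combinations
    (geometric-mean normalizers) can be built and scored as pseudo-genes, and
    candidate references are evaluated by cross-normalization: each candidate
    is normalized to every other and tested for group differences by one-way
    ANOVA and Kruskal-Wallis. A seeded synthetic Cq generator with known
    ground truth supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests: testthat (>= 3.0.0), withr, optparse
Config/testthat/edition: 3
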