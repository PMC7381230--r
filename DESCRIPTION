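Package: seroglycan
Title: Serum Anti-Glycan Antibody Reactivity and Sorted-Fraction Microbiome
    Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline linking serum anti-glycan antibody reactivity
    measured on oligosaccharide microarrays to gut-bacterial targets.
    Parses monosaccharide composition labels (hexose/HexNAc/fucose/sialic
    acid) and classifies glycans by decoration; turns spot-level scanner
    exports into per-sample log2 RFU reactivity matrices (background
    subtraction, replicate averaging, clamping); tests differential
    reactivity per glycan with an empirical-Bayes moderated t-statistic and
    a log-fold-change hit rule; runs selected-pair ANOVA/Bonferroni and
    Kruskal-Wallis/Dunn group comparisons, isotype correlation and
    correlation-based complete-linkage clustering; quantifies taxon fold
    enrichment in lectin- and IgG-sorted bacterial fractions against
    matched unsorted communities with candidate-taxon intersection; and
    computes qPCR relative quantities by the 2^-dCt method. A synthetic
    study generator with machine-readable ground truth makes every stage
    verifiable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    limma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
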