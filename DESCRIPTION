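Package: stressregulon
Title: Multi-Omics Definition of a Stress-Response Regulon
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to define a stress-response regulon by integrating RNA-seq,
    ribosome-profiling and shotgun-proteomics contrasts: negative-binomial Wald
    differential expression with median-of-ratios size factors, quantile plus
    p-value regulated-gene gates, ribosome loading scores for differential
    translation, a median +/- 2 SD proteomics regulation cutoff, two-treatment
    co-regulation filtering and a cross-layer decision tree for regulon
    membership. Also provides the accompanying assay calculators (isotopologue
    fractions and mitochondrial dTTP attribution for heavy-serine tracing,
    internal-standard quantification, NADP/NADPH ratios, efficiency-corrected
    qPCR via the Pfaffl model, four-parameter-logistic IC50 fits) and a seeded
    synthetic multi-omics experiment generator with known ground truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    limma,
    minpack.lm,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
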