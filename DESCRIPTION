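Package: perturbscope
Title: Perturbation Scoring and Regulatory-Variant Enrichment for Single-Cell CRISPR Multiome Screens
Version: 0.1.0
Authors@R:
    person("Perturbscope", "Developers", email = "perturbscope@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for pooled CRISPR transcription-factor knock-out
    screens read out with paired single-cell RNA and ATAC (multiome) profiling.
    Computes per-cell perturbation scores against nearest-neighbor control
    cells, calls transcription-factor-sensitive genes and accessible chromatin
    regions with a linear model on the continuous perturbation level, links
    regulatory regions to target genes by single-cell correlation with
    TAD/CRISPRi/ChIP enrichment tests, and quantifies fine-mapped GWAS variant
    overlap and partitioned heritability enrichment in region categories with
    matched resampling nulls. Ships a fully parameterised synthetic multiome
    generator with planted ground truth for calibration and power analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    Matrix,
    data.table,
    jsonlite,
    IRanges,
    S4Vectors,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
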