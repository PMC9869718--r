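Package: trendtide
Title: Pairwise Trend Comparison of Quantitative Omics Datasets
Version: 0.1.0
Authors@R:
    person("trendtide", "developers", email = "trendtide@example.org",
           role = c("aut", "cre"))
Description: Headless pairwise comparison of abundance trends between two or
    more gene-based quantitative omics datasets (e.g. transcriptome versus
    proteome). Intersecting genes are clustered jointly by early integration
    (stacked z-scored profiles, k-means++), yielding two trend labels per gene
    in a shared label space so genes classify as concordant or discordant.
    Includes percentile-based variance/abundance filtering, a Sankey
    trend-intersection model with size filters and gene highlighting, local
    GO enrichment via Fisher's exact test with Benjamini-Hochberg FDR,
    static plot exports, a synthetic-data generator with planted trends, and
    a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ggplot2,
    jsonlite,
    optparse,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
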