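Package: cernaflow
Title: lncRNA Identification and ceRNA Network Inference for Staged Flower Transcriptomes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: A tested reimplementation of a multi-omics lncRNA analysis for
    flower development: cuffcompare-style class codes and novel-transcript
    filters, lncRNA calling from coding-potential scores, five-way positional
    classification, per-layer differential filtering with Venn arithmetic over
    stage comparisons, the three direct lncRNA-mRNA acting models (antisense
    duplex minimum free energy, cis proximity, trans co-expression),
    sign-constrained ceRNA triad inference with shared-MRE hypergeometric
    enrichment and metabolite correlation integration, qPCR 2^-ddCt validation
    statistics, and a seeded synthetic-data generator that emulates the
    9-sample three-stage study design with planted ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Biostrings,
    rtracklayer,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
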