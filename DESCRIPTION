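Package: selectigene
Title: Microbiome-Selective Gene Design
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Designs heterologous genes for selective expression inside a
    microbiome whose members are partitioned into wanted and unwanted hosts.
    The coding region is recoded by differential codon-usage-bias
    optimization (CAI, tAI or typical-decoding-rate weights; proteome-relative
    greedy hill climbing or per-amino-acid ratio/difference scores), a
    promoter is chosen and tailored by contrastive motif-set construction
    (position-specific scoring matrices, Spearman similarity thresholds and
    percentile filtering), and restriction-site presence is edited so that
    unwanted hosts gain recognition sites while wanted-host sites are removed
    by synonymous changes. Includes a seeded synthetic-microbiome generator
    so the whole pipeline is testable without external genome downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
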