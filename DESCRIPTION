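Package: ciscreen
Title: Directional Cis-Regulatory Pathway Tests and Upstream Divergence Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for detecting polygenic, directional cis-regulatory
    evolution from allele-specific expression in F1-hybrid RNA-seq, and for
    following up candidate pathways with population-genomic screens of
    transcription-factor binding sites upstream of genes. Implements a
    per-gene allelic-imbalance test with a signed significance statistic, a
    resampling null for coordinated shifts across gene sets, a simulated-read
    mapping-bias quality-control filter, haploid pseudogenome construction
    from population VCFs under both heterozygote-assignment modes, counting
    of polymorphic and fixed-divergent upstream positions inside and outside
    binding sites, and a per-regulator interaction screen on normalized
    divergence. A synthetic-data module generates genomes, annotations,
    binding sites, population VCFs and allele-count tables with known ground
    truth so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    vcfR,
    data.table,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
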