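Package: tandemCGI
Title: CpG-Island-Region Methylation Context and Tandem-Gene Promoter
    Hypermethylation Analysis for 450K Arrays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Segments CpG islands into island/shore/shelf regions (CGIR),
    annotates CpG probes with CGIR class, gene context (TSS1500, TSS200,
    5'-UTR, first exon, gene body, 3'-UTR), TSS proximity and strand-aware
    5'/3' shore orientation; detects tandem-oriented gene pairs with
    TES-to-TSS intergenic distances and the downstream promoter CpG island;
    aggregates beta values per region, sample and group; scores and ranks
    tumor-versus-normal promoter hypermethylation; and ships a synthetic
    450K-style data generator so the full pipeline is exercisable and its
    parameter recovery testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    optparse,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
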