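Package: exontig
Title: Exon-Aware Assignment of Paralogous Genes to Contigs in Fragmented Assemblies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building accurate gene models of paralogous gene
    families on fragmented genome assemblies. Similarity hits of translated
    coding exons (TCEs) against contigs are parsed from BLAST tabular or
    HMMER per-domain output, filtered, and turned into an instance of the
    paralog-to-contig assignment problem (PCAP): find the collectively best
    assignment of whole paralogs to contigs such that each contig carries at
    most one paralog and every assigned contig takes all of its compatible
    exon hits. The problem is NP-complete (it embeds graph 3-coloring); an
    exact branch-and-bound solver with sub-optimal solution enumeration is
    provided, together with a greedy full-length-score baseline, a
    protein-family simulator with contig fragmentation for benchmarking,
    the 3-coloring reduction as a hard-instance generator, and
    post-processing utilities that concatenate and interleave assigned
    contigs into merged loci.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    igraph,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
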