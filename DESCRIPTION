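Package: odinphase
Title: Phasing-Based Organellar Genome Assembly and Detection of
    Organellar-Derived Nuclear Insertions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reference-guided assembly of organellar (mitochondrial and
    plastid) genomes from high-throughput sequencing reads that
    simultaneously identifies and reconstructs organellar-derived inserted
    sequences (numts, nupts, mtpts). Heterozygous-looking sites created by
    cross-mapping insertion reads are phased into blocks with
    haplotype-informative reads, the two sequences of each phased region
    are reconstructed, and their origin (organellar versus insertion) is
    decided by alignment score against a secondary reference. Includes
    majority-count and 2/3-ratio consensus baselines, an iterative
    remapping loop with allele-separation rescue for multiallelic regions,
    a seeded simulator for modern and ancient-DNA read sets with full
    ground truth, and a command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    jsonlite,
    methods,
    S4Vectors,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
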