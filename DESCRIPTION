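Package: tetrarec
Title: Tetrad-Based Meiotic Recombination Analysis from Gamete Sequencing Evidence
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for tetrad analysis of meiotic recombination. Builds a
    filtered catalog of biallelic SNV markers segregating between two crossing
    parents (repeat, copy-number, indel-flank, depth-deviation, reciprocality
    and consensus filters), calls per-marker gamete genotypes from allele
    observations using a cumulative base-quality score (Q_net) and a base
    purity score, infers missing genotypes under the tetrad-wide 2:2
    segregation assumption, segments genotype matrices into linkage blocks,
    and classifies crossover and gene-conversion events from genotype switch
    patterns between adjacent blocks. A recombinant-tetrad simulator generates
    parental genomes, four-chromatid genotype paths with crossover and
    non-crossover events carrying gene-conversion tracts, and noisy per-marker
    allele observations with full ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils,
    Biostrings,
    GenomicRanges,
    IRanges,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    Rsamtools,
    jsonlite,
    optparse,
    rtracklayer,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
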