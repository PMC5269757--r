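Package: sagco
Title: Co-Assembly Analysis of Single Amplified Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to decide which single amplified genomes (SAGs) of an
    uncultured microbial eukaryote can be co-assembled and to quantify what a
    co-assembly gains. Implements tetranucleotide-frequency profiling with a
    toroidal batch self-organizing map and U-matrix cluster extraction,
    k-mer-anchored average nucleotide identity (ANI) with shared-genome
    fractions, marker-gene completeness and genome-size estimation,
    read-subsampling saturation curves with Michaelis-Menten extrapolation,
    and per-base partitioning of a co-assembly by SAG support. A bundled
    simulator of multiple-displacement-amplification (MDA) coverage bias
    generates genomes, SAG assemblies, paired-end reads, marker catalogs and
    foreign-DNA contaminants so the whole pipeline runs and is tested
    offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    IRanges,
    S4Vectors,
    data.table,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    minpack.lm,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
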