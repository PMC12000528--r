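Package: haplosv
Title: Local-Haplotype Structural Variant Discovery and Joint Genotyping for Long Reads
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Calls and jointly genotypes structural variants (deletions,
    insertions, duplications, inversions and breakends >= 50 bp) from mapped
    high-accuracy long reads. Read-level alignment signatures (large CIGAR
    indels, split-read junctions, long soft clips) are clustered into
    candidate loci, supporting reads are assembled into local consensus
    haplotypes, haplotypes are merged across samples and realigned to the
    reference to obtain basepair-resolution breakpoints with microhomology
    and breakpoint-insertion annotation, and each sample is genotyped from
    relative read support with phred-scaled genotype qualities. Unbalanced
    candidates are corroborated against binned read depth, and overlapping
    heterozygous calls are locally phased. Includes a deterministic diploid
    read simulator and a pedigree genotype-concordance evaluator.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomeInfoDb,
    GenomicAlignments,
    GenomicRanges,
    IRanges,
    Rsamtools,
    S4Vectors,
    jsonlite,
    stats,
    utils
Suggests:
    VariantAnnotation,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
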