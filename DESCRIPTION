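Package: orgsnp
Title: Organellar Genome SNP Analysis with Cross-Mapping Read Filtering
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects single nucleotide polymorphisms in plant organellar
    (plastid and mitochondrial) genomes from whole-genome sequencing reads,
    with explicit handling of plastid-to-mitochondrion DNA transfer (MTPT)
    artifacts. Reads aligning to both organellar genomes are removed before
    pileup-based SNP calling with depth, mapping-quality and variant-quality
    thresholds; retained SNPs are classified as homoplasmic or heteroplasmic,
    annotated by genomic context (gene, intron, intergenic spacer; synonymous
    versus nonsynonymous), and summarised across cultivars (unique SNPs,
    sharing spectra). SNP supermatrices support Fitch parsimony, Jukes-Cantor
    maximum-likelihood trees with nonparametric bootstrap, and the
    incongruence length difference (ILD) permutation test. A synthetic-data
    module simulates miniature organellar genomes, heteroplasmic cultivar
    profiles and paired-end reads with ground truth so the whole pipeline is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    ape,
    Biostrings,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    rtracklayer,
    optparse
Config/testthat/edition: 3
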