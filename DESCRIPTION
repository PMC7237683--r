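Package: polyguide
Title: Allele-Aware CRISPR/Cas9 Guide Design and Editing Analysis for
    Autopolyploid Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Design and analysis toolkit for CRISPR/Cas9 genome editing in
    autopolyploid plants such as cultivated alfalfa. Locates all allelic
    copies of a target gene in an allele-aware genome assembly, enumerates
    and ranks SpCas9 guide sequences that cover every allele, performs exact
    mismatch-bounded off-target scans with NGG/NAG PAMs, designs
    restriction-digest (PCR-RE) mutant screens around the predicted Cas9
    cleavage site, genotypes edited plants from Sanger-sequenced amplicon
    clones (wild-type, partial, null, chimeric), filters whole-genome
    resequencing variant calls down to candidate Cas9-induced off-target
    indels, and computes Nei-Gojobori (1986) Ka/Ks statistics with
    whole-genome-duplication-calibrated mutation rates. Includes a seeded
    synthetic-fixture generator for autotetraploid genomes, gene models,
    and edited clone sets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    vcfR,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
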