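## Shared fixture builders.

PALM1_GUIDE <- "GGAGACGAGCACGGTCGCGG"  # printed protospacer, PAM CGG

## Two-exon tetraploid fixture around the printed protospacer.
basic_fixture <- function(seed, chromosome_length = 12000,
                          allelic_divergence = 1e-4, gene_divergence = 0,
                          decoy_sites = NULL, ploidy = 4,
                          exon_lengths = c(300, 350), intron_lengths = 120,
                          enzyme_sites = NULL) {
  spec <- fixture_spec(
    seed = seed, ploidy = ploidy, chromosome_length = chromosome_length,
    allelic_divergence = allelic_divergence, gene_divergence = gene_divergence,
    target_gene = list(exon_lengths = exon_lengths,
                       intron_lengths = intron_lengths,
                       protospacer = PALM1_GUIDE),
    decoy_sites = decoy_sites, enzyme_sites = enzyme_sites)
  generate_genome(spec)
}

## CDS query of the planted gene, read back from one chromosome.
fixture_query <- function(fx, chrom = "chr1.1") {
  ex <- fx$truth[fx$truth$type == "exon" & fx$truth$chrom == chrom, ]
  chr <- as.character(fx$genome[[chrom]])
  paste(substring(chr, ex$start, ex$end), collapse = "")
}

## Truth exon intervals for one chromosome.
fixture_exons <- function(fx, chrom) {
  ex <- fx$truth[fx$truth$type == "exon" & fx$truth$chrom == chrom, ]
  ex[order(ex$start), c("start", "end")]
}

## Wild-type amplicon around the planted protospacer (plus strand).
fixture_amplicon <- function(fx, chrom = "chr1.1", flank = 90) {
  pr <- fx$truth[fx$truth$type == "protospacer" & fx$truth$chrom == chrom, ]
  chr <- as.character(fx$genome[[chrom]])
  substring(chr, pr$start - flank, pr$end + 3 + flank)
}

random_seq <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

rc <- function(x) as.character(
  Biostrings::reverseComplement(Biostrings::DNAString(x)))
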