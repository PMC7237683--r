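# polyguide

Allele-aware CRISPR/Cas9 guide design and editing analysis for
autopolyploid genomes.

## The problem

Knocking a gene out in an autotetraploid crop such as cultivated alfalfa
(*Medicago sativa*, 2n = 4x = 32) means disrupting **all four allelic
copies at once**. That puts unusual demands on the computational side of
an editing experiment:

* the target gene must be located on every allelic chromosome of an
  allele-aware assembly, with its exon structure and copy number;
* the guide must match all alleles exactly (allelic copies differ by up
  to ~1% — a guide that misses one allele cannot produce a null mutant);
* off-target sites must be enumerated exhaustively under the permissive
  matching Cas9 actually exhibits (up to 5 mismatches, NGG **and** NAG
  PAMs);
* mutant screening is cheapest when a restriction site overlaps the
  predicted cut (PCR-RE assay: edited alleles lose the site and resist
  digestion), so the designer should find such sites;
* Sanger-sequenced amplicon clones must be collapsed into per-plant
  genotypes — wild type, partial, null, or chimeric — and mutagenesis
  frequencies (mutants per transformed callus) computed;
* whole-genome resequencing calls of edited plants must be reduced to
  credible Cas9-induced off-target mutations (SNVs excluded; only indels
  at or near the −3 position relative to the PAM count);
* and the genome-evolution side: Nei–Gojobori (1986) Ka/Ks on syntenic
  gene pairs, with the per-site mutation rate calibrated on a shared
  whole-genome duplication as μ = Ks / 2T.

`polyguide` implements this pipeline end to end in R, plus a seeded
synthetic-fixture generator (autotetraploid genomes with four nearly
identical allelic gene copies, planted guide/decoy/enzyme sites, and
simulated edited clone sets) so that every component is testable without
any external data.

## The core conventions

* SpCas9 cuts bluntly 3 bp 5′ of the PAM, between protospacer positions
  17 and 18; that inter-base position is used consistently for PCR-RE
  design, clone genotyping, and the off-target variant filter ("−3
  position").
* Off-target search is exact and complete: every site on either strand
  within K mismatches (Hamming; default K = 5) of the guide and adjacent
  to an NGG or NAG PAM.
* Guide ranking applies hard filters first — covers all alleles, no
  obvious off-target site (no non-allelic hit at ≤ 3 mismatches) — then
  scores GC content, start-codon proximity and exon conservation. A
  non-G 5′ base is satisfied by prepending a G to the vector spacer
  (`--strict-5g` restores the hard filter).
* NG86: synonymous site fractions from all nine single-base codon
  neighbours; multi-difference codons averaged over stop-free
  substitution pathways; Jukes–Cantor correction
  d = −(3/4)·ln(1 − 4p/3), with p ≥ 3/4 flagged as saturated.

## Worked example

Design a guide for a four-allele target in a synthetic tetraploid and
check the PCR-RE screen:

```r
library(polyguide)

spec <- fixture_spec(seed = 101, ploidy = 4, chromosome_length = 12000,
                     target_gene = list(exon_lengths = c(300, 350),
                                        intron_lengths = 120,
                                        protospacer = "GGAGACGAGCACGGTCGCGG"))
fx <- generate_genome(spec)

ex <- fx$truth[fx$truth$type == "exon" & fx$truth$chrom == "chr1.1", ]
query <- paste(substring(as.character(fx$genome[["chr1.1"]]),
                         ex$start, ex$end), collapse = "")
al <- locate_alleles(query, fx$genome, gene_id = "target")
al
#> Allele set 'target': 4 copies
#>   chr1.1:3000-3769 (+), 2 exon(s), identity 1.0000
#>   chr1.2:3000-3769 (+), 2 exon(s), identity 1.0000
#>   chr1.3:3000-3769 (+), 2 exon(s), identity 1.0000
#>   chr1.4:3000-3769 (+), 2 exon(s), identity 1.0000

g <- enumerate_guides(al, fx$genome)
g <- annotate_offtargets(g, fx$genome, al)
scored <- score_guides(g, ploidy = 4)
scored[scored$protospacer == "GGAGACGAGCACGGTCGCGG",
       c("protospacer", "pam", "allele_coverage", "gc_fraction",
         "passes_filters")]
#>            protospacer pam allele_coverage gc_fraction passes_filters
#> 3 GGAGACGAGCACGGTCGCGG CGG               4        0.75           TRUE

amp <- substring(as.character(fx$genome[["chr1.1"]]), 3047, 3230)
find_overlapping_sites("GGAGACGAGCACGGTCGCGG", read_enzymes()[["BstUI"]], amp)
#>   enzyme start end overlaps_cut
#> 1  BstUI   106 109         TRUE
```

This guide covers all four alleles, has GC 0.75, passes every hard
filter, and a BstUI (CGCG) site overlaps its predicted cut — so T0
regenerants can be
screened by digesting the target amplicon: plants whose amplicons resist
digestion carry edited alleles. Clone-level genotyping then classifies
each plant:

```r
mutagenesis_frequency(26, 1508)   # mutants per transformed callus, percent
#> [1] 1.72
mutation_rate_from_wgd(0.63, 58e6)  # per site per year
#> [1] 5.431034e-09
```

A thin command-line wrapper over the same functions is at
`inst/scripts/polyguide.R` (subcommands `find-alleles`, `design`,
`offtarget`, `pcr-re`, `genotype`, `kaks`, `mu`).

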