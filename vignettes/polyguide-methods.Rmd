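---
title: "Methods: allele-aware guide design and editing analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: allele-aware guide design and editing analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polyguide)
```

# Scope and model

`polyguide` supports CRISPR/Cas9 knockout experiments in autopolyploid
plants, where a null mutant requires disrupting every allelic copy of the
target gene simultaneously. The package covers the computational path of
such an experiment: locating the allelic copies, designing a guide that
covers them all, exhaustively scanning for off-target sites, designing a
restriction-digest (PCR-RE) screen, genotyping edited plants from
Sanger-sequenced amplicon clones, filtering resequencing variant calls to
candidate Cas9-induced off-target mutations, and the Nei–Gojobori Ka/Ks /
mutation-rate arithmetic used on the genome-evolution side. It does not
perform genome assembly, read mapping, or variant calling; it consumes
FASTA, GFF3 and VCF.

A single geometric convention ties the modules together: SpCas9 cuts
bluntly 3 bp 5′ of the PAM, between protospacer positions 17 and 18. That
inter-base position is the predicted cleavage site for PCR-RE design, the
anchor for clone edit positions (0 = at the cut, negative = PAM-distal),
and the "−3 position" of the off-target variant filter. The printed
BstUI/guide geometry that motivates the PCR-RE module is consistent with
this convention: the guide `GGAGACGAGCACGGTCGCGG` carries `CGCG` at
protospacer positions 16–19, so the CG^CG cut site straddles the 17|18
Cas9 cut.

# The synthetic-fixture generator

Every module is tested against seeded synthetic data rather than
downloads. `fixture_spec()`/`generate_genome()` emulate an allele-aware
autotetraploid assembly:

* one chromosome per (homologous group, allele), named `chr<g>.<a>`;
* background sequence drawn uniformly over A/C/G/T (no `N` by default,
  keeping mismatch-count truth unambiguous; `N` handling is tested
  separately with hand-built sequences);
* a target gene (exons/introns, embedded protospacer + NGG PAM) planted
  identically in all copies at a fixed locus;
* allelic copies divergent at `allelic_divergence` substitutions per site
  (each copy is mutated at half the rate from a common ancestor, so any
  *pair* realizes the requested rate). The default is 1e-4;
  allele-aware tetraploid assemblies report allelic divergence up to
  ~0.01, and tests exercise that level too. `gene_divergence`
  optionally diverges the gene body as well, sparing the protospacer +
  PAM and the splice dinucleotides so planted guide-site truth stays
  exact;
* decoy protospacer sites with exactly *m* mismatches and an NGG or NAG
  PAM, planted on allele 1 only, spaced ≥ 200 bp apart and far from the
  real target so truth-table coordinates are unambiguous;
* restriction recognition sites planted at a stated offset from the
  predicted cut.

Introns carry canonical GT..AG splice dinucleotides. This is both
realistic (virtually all plant spliceosomal introns are GT–AG) and
necessary for exactness: when the last bases of an exon coincide with the
last bases of the intron, two spliced alignments are equally exact and
only the splice signal identifies the annotated boundary.

Truth tables record every planted feature with 1-based inclusive
coordinates; emitted formats are 60-column FASTA, GFF3 (gene/mRNA/
exon/CDS with phase) and TSV. All coordinates in R follow the 1-based
inclusive IRanges convention throughout — the format-compliance intent
(GFF3 is 1-based inclusive) is met without a separate internal 0-based
representation.

What the generator does **not** emulate: sequencing error,
chromatograms, structural variation between alleles, repeat families, or
realistic base composition. Passing tests therefore demonstrate
algorithmic correctness on substitution-divergent allelic copies, not
robustness to assembly artefacts or indel-divergent alleles.

`generate_clone_set()` emulates the 20–30-clone Sanger sampling of one
edited plant: per-allele edits (deletion/insertion/substitution at an
offset from the cut), sampling proportions over alleles (largest-
remainder allocation so every allele is observed when possible), and
optional injected extra mutation types emulating chimerism.

# Locating allelic copies

`locate_alleles()` uses exact k-mer anchoring (default k = 15), collapses
anchors into same-diagonal runs, selects the run chain that maximizes
anchored query length under query/genome colinearity (a small weighted
DP, robust to spurious repeat anchors), merges same-diagonal runs across
substitution gaps, and refines each inter-block junction over a ±k
window by minimizing `3·mismatches − 2·splice`, where splice counts the
GT/AG dinucleotides of the implied intron. Terminal blocks are snapped to
the query ends along their diagonals. Gapped extension beyond the
chained anchors is deliberately not implemented: the intended use is
allelic copies at ≤ ~1% divergence, which is substitution-dominated; on
such fixtures the recovery property (exact exon intervals for ≥ 95% of
copies over 50 seeded replicates at 1% within-gene divergence) passes
with margin.

Defaults `min_identity = 0.90` and `min_query_coverage = 0.80` are chosen
so ~1% allelic divergence always passes while unrelated loci (sharing
only a guide-length stretch) are rejected. Two loci are distinct copies
whenever their genomic spans do not overlap; overlapping reports of one
locus keep the higher identity. Zero hits return an empty allele set,
not an error. Copy number can also be estimated from read depth:
`copy_number_from_depth()` returns `round(median(depth)/baseline)`, the
median being robust to coverage noise.

# Guide enumeration and ranking

`enumerate_guides()` reports every 20-mer immediately 5′ of an NGG PAM
with protospacer and PAM fully inside an exon, on both strands,
deduplicated by protospacer. NGG-only for on-target design; NAG enters
only the off-target scan, where Cas9 tolerates it. `allele_coverage`
counts copies carrying the exact protospacer+NGG; `in_conserved_exon`
marks exons identical across all copies — a proxy for "functional
conserved domain" that deliberately stays sequence-level (protein-domain
annotation is out of scope).

`score_guides()` applies hard filters first: cover all alleles; no
obvious off-target site, operationalized (the term has no standard
definition) as zero non-allelic hits at ≤ 3 mismatches under any
accepted PAM — the threshold is exposed and logged. The 5′-G requirement
of U6-type promoters is satisfiable by prepending a G to the vector
spacer (a 21-nt spacer with prepended G is standard practice and
explains 21-nt published guides); `strict_5g = TRUE` restores the hard
filter. Survivors are ranked by

rank_score = w_gc · GC + w_prox / (1 + d/L) + w_cons · conserved

with defaults w = (1, 1, 0.5) and L = 200 bp of CDS. Proximity to the
start codon is a preference, not a cutoff, because early frameshifts are
likelier to produce nulls; GC is a ranking term because high GC
correlates with sgRNA efficacy but no published threshold exists. The
weights are declared defaults, not fitted values. Ties break by fewer
total off-target hits, then smaller genomic coordinate, making the
ranking fully deterministic.

# Off-target scanning

`scan_offtargets()` enumerates every site on either strand with ≤ K
mismatches (default 5) to the guide adjacent to an NGG or NAG PAM. The
search runs on Biostrings' mismatch-bounded exact matcher per strand with
an explicit PAM check; it is exhaustive, not heuristic, and the test
suite holds it set-equal to an independent brute-force sliding-window
Hamming scan on 50 seeded 100-kb genomes. Genomic `N` matches no guide
base and satisfies no PAM. Mismatch positions are numbered 1
(PAM-distal) to 20 (PAM-proximal), counted uniformly — no special
weighting of the seed region. Bulges are not modelled (mismatch-only
matching, as in the desktop scanners used for plant guide screening), and
no CFD/MIT-style scoring is attempted: the design rule is an exact count
threshold, not a score.

`classify_hits()` flags hits overlapping the intended gene's allelic
copies as on-target and summarizes the rest as a complete
(mismatch × PAM-kind) contingency table.

# PCR-RE screening design

`find_overlapping_sites()` matches enzyme recognition sites (full IUPAC
support) on both strands, reporting palindromes once per interval, and
flags sites whose interval contains the predicted cut inter-base.
`digest()` cuts at the top-strand offset of the leftmost non-overlapping
occurrences — close enough to physical digestion at screening scale —
and returns gel band sizes; fragment lengths always sum to the amplicon
length. The shipped enzyme table (`inst/extdata/enzymes.tsv`) includes
BstUI (CG^CG) and a few common screening enzymes and is user-editable.
Star activity, methylation sensitivity and partial digestion are out of
scope.

# Clone genotyping

`call_clone()` aligns each clone globally against the wild-type amplicon
(Biostrings `pairwiseAlignment`, affine gaps; match 2, mismatch −3, gap
open 5, gap extend 1 — declared, deterministic scores) and keeps edits
within ±20 bp of the cut; more distant differences are treated as
PCR/sequencing noise, since Cas9 indels cluster at the cut. Alignments
below 70% identity are flagged unalignable and excluded with a warning.
Identical alignments collapse to one edit signature (e.g. `del2@0`,
`insA@0`), multiple events to a `complex:` signature.

`classify_plant()` counts distinct non-wild-type signatures. Distinct
mutation types are only a **lower bound** on mutated alleles — two
alleles can carry the same edit — so the field is named
`n_mutated_alleles_min` and capped at the ploidy. Classification: all
clones wild type → `wild-type`; no wild-type clone and ≤ ploidy types →
`null`; wild type observed alongside ≤ ploidy−1 types → `partial`; more
distinct genotypes than alleles, or an external conflict flag (e.g.
residual digested bands despite no wild-type clone) → `chimeric`. A T0
plant with five mutation types in a tetraploid is the canonical chimeric
pattern.

`mutagenesis_frequency()` is mutant plants per transformed callus, as a
percentage with half-up rounding to two decimals (matching how such
frequencies are reported; R's default banker's rounding would disagree on
exact .005 boundaries).

# Off-target variant filtering

`filter_offtarget_variants()` consumes VCF records (read with `vcfR`)
and the classified site list. SNVs are categorically excluded — Cas9
does not induce point mutations at meaningful rates, and germline SNV
background overwhelms any signal. Indels survive only within ±2 bp
(default, exposed as `tolerance`; "at or near" has no published number)
of the cut inter-base of a *non*-on-target site; indels at the target
itself are rejected as `targeted region`. Every input record receives
exactly one verdict with a reason — nothing is silently dropped — and
`summarize_coding_offtargets()` counts candidates inside CDS features,
the headline safety readout. Manual review remains necessary; the
verdicts carry the evidence columns (matched site, distance, coding
overlap) for it.

# Nei–Gojobori Ka/Ks and WGD-calibrated mutation rate

`nei_gojobori()` implements NG86 with Jukes–Cantor correction. Per-codon
synonymous site fractions come from all nine single-base neighbours
(changes to stop codons count as nonsynonymous, preserving
S + N = 3 × codons); multi-difference codons average over all
substitution pathways avoiding stop codons (all pathways are used in the
degenerate case where every pathway passes through a stop); S and N are
averaged between the two sequences. Codons containing gaps or `N`, and
pairs where either codon is a stop, are excluded. Proportions at or
beyond the JC saturation bound p ≥ 3/4 yield a flagged `NA`, never a
silent `NaN`. The implementation memoizes codon-pair difference counts;
the test suite holds it to 1e-10 against an independent recursive
pathway-enumeration oracle on 1000 random 50-codon pairs. Plain NG86 is
used (no transition/transversion weighting), matching the method named
for syntenic-pair Ks estimation in allele-aware assemblies;
maximum-likelihood dN/dS is out of scope.

`mutation_rate_from_wgd()` computes μ = Ks / (2T): paralog pairs born at
a duplication of age T accumulate synonymous divergence along two
lineages. The formula reproduces both published calibration points used
as worked examples (Ks 0.63 at 58 Mya → 5.43e-9; Ks 0.65 → 5.60e-9),
confirming the convention. `monoploid_size_delta()` is the companion
assembly arithmetic (total/ploidy and difference from a reference).

# Numerical and design choices

* **Determinism.** All stochastic components (fixtures, clone sets) are
  seeded; identical seed + spec produce byte-identical files. RNG state
  is restored after generation.
* **Problem sizes.** The shipped tests use 12–20-kb chromosomes for
  module tests, 50 × 100-kb genomes for the off-target equivalence
  property, 200 simulated clone sets for genotype recovery, and 1000
  random codon pairs for the NG86 oracle — sizes at which brute-force
  oracles remain exact and the full suite runs in minutes on one core.
* **Build-vs-buy.** Standard primitives come from established packages
  (Biostrings for sequence matching and pairwise alignment, rtracklayer
  for GFF3, vcfR for VCF, GenomicRanges/IRanges for intervals). The
  contributed logic — allele-aware chaining and junction refinement,
  guide criteria, PCR-RE geometry, genotype classification, the −3
  indel filter, NG86 — is implemented here and cross-checked against
  independent oracles, never against the same library that implements
  it.

# Known limitations

* The locator does not model indel divergence between alleles or
  pseudogenes; it reports evidence (identity, coverage) and leaves
  curation to the user.
* Off-target scanning has no bulge tolerance and no activity scoring.
* Clone genotyping assumes the amplicon is oriented with the protospacer
  on its plus strand and cannot separate two alleles sharing one edit
  (hence the lower-bound convention).
* The variant filter deliberately leaves final judgement to manual
  review; it reduces, it does not decide.
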