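test_that("same seed and spec give byte-identical outputs", {
  spec <- fixture_spec(seed = 7, chromosome_length = 6000,
                       target_gene = list(exon_lengths = 300,
                                          protospacer = PALM1_GUIDE),
                       decoy_sites = data.frame(mismatches = 2,
                                                pam_kind = "NGG"))
  d1 <- file.path(tempdir(), "fx1"); d2 <- file.path(tempdir(), "fx2")
  generate_genome(spec, out_dir = d1)
  generate_genome(spec, out_dir = d2)
  for (f in c("genome.fa", "genes.gff3", "truth.tsv"))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
})

test_that("zero divergence yields identical allele sequences", {
  fx <- basic_fixture(seed = 3, allelic_divergence = 0)
  seqs <- as.character(fx$genome)
  expect_length(seqs, 4)
  expect_length(unique(unname(seqs)), 1)
})

test_that("realized allelic divergence is close to the specified rate", {
  div <- 0.01
  fx <- basic_fixture(seed = 5, chromosome_length = 20000,
                      allelic_divergence = div)
  gene <- fx$truth[fx$truth$type == "gene" & fx$truth$chrom == "chr1.1", ]
  for (pair in list(c(1, 2), c(2, 3), c(3, 4))) {
    a <- strsplit(as.character(fx$genome[[pair[1]]]), "")[[1]]
    b <- strsplit(as.character(fx$genome[[pair[2]]]), "")[[1]]
    outside <- setdiff(seq_along(a), gene$start:gene$end)
    p_hat <- mean(a[outside] != b[outside])
    tol <- 3 * sqrt(div * (1 - div) / length(outside))
    expect_lt(abs(p_hat - div), tol + 1e-9)
  }
})

test_that("truth table is self-consistent with the emitted sequences", {
  fx <- basic_fixture(seed = 11, decoy_sites = data.frame(
    mismatches = c(1, 3, 5, 6), pam_kind = "NGG"))
  tr <- fx$truth
  withseq <- tr[!is.na(tr$sequence), ]
  expect_gt(nrow(withseq), 0)
  for (i in seq_len(nrow(withseq))) {
    row <- withseq[i, ]
    sl <- substring(as.character(fx$genome[[row$chrom]]), row$start, row$end)
    expect_identical(sl, row$sequence)
  }
})

test_that("planted decoys are recorded exactly, with their mismatch counts", {
  fx <- basic_fixture(seed = 11, decoy_sites = data.frame(
    mismatches = c(1, 3, 5, 6), pam_kind = "NGG"))
  dec <- fx$truth[fx$truth$type == "decoy", ]
  expect_equal(nrow(dec), 4)
  expect_setequal(dec$mismatches, c(1, 3, 5, 6))
  gch <- strsplit(PALM1_GUIDE, "")[[1]]
  for (i in seq_len(nrow(dec))) {
    site <- strsplit(dec$sequence[i], "")[[1]]
    expect_equal(sum(site != gch), dec$mismatches[i])
    pam <- substring(as.character(fx$genome[[dec$chrom[i]]]),
                     dec$end[i] + 1, dec$end[i] + 3)
    expect_match(pam, "^[ACGT]GG$")
  }
})

test_that("oversized genes and decoy overflows are rejected", {
  expect_error(fixture_spec(seed = 1, chromosome_length = 1000,
                            target_gene = list(exon_lengths = c(400, 400),
                                               intron_lengths = 100)),
               "sizing")
  expect_error(fixture_spec(seed = 1, allelic_divergence = 1),
               "allelic_divergence")
  expect_error(fixture_spec(seed = 1,
                            target_gene = list(exon_lengths = 300,
                                               protospacer = PALM1_GUIDE),
                            decoy_sites = data.frame(mismatches = 25,
                                                     pam_kind = "NGG")),
               "exceeds guide length")
})

test_that("clone sets realize the requested edits and labels", {
  amp <- paste0(random_seq(90, seed = 2), PALM1_GUIDE, "CGG",
                random_seq(90))
  ## all wild type -> all clones equal the reference
  wt <- clone_set_spec(n_clones = 10, allele_edits = replicate(
    4, list(type = "wt"), simplify = FALSE), seed = 1)
  s1 <- generate_clone_set(wt, amp, PALM1_GUIDE)
  expect_true(all(s1$clones == amp))
  expect_true(all(s1$labels$is_wt))

  ## four distinct deletions over 30 clones -> 4 types, 0 wild type
  dl <- clone_set_spec(n_clones = 30, allele_edits = list(
    a1 = list(type = "del", length = 1), a2 = list(type = "del", length = 2),
    a3 = list(type = "del", length = 4), a4 = list(type = "del", length = 5)),
    seed = 2)
  s2 <- generate_clone_set(dl, amp, PALM1_GUIDE)
  expect_equal(length(unique(s2$labels$edit_type)), 4)
  expect_equal(sum(s2$labels$is_wt), 0)
  expect_equal(nrow(s2$labels), 30)

  ## one injected chimeric type on a 4-allele design -> 5 distinct types
  ch <- clone_set_spec(n_clones = 20, allele_edits = dl$allele_edits,
                       chimera_extra_types = 1, seed = 3)
  s3 <- generate_clone_set(ch, amp, PALM1_GUIDE)
  expect_equal(length(unique(s3$labels$edit_type)), 5)
})

test_that("clone-set specs validate proportions and edit placement", {
  amp <- paste0(random_seq(30, seed = 4), PALM1_GUIDE, "CGG", random_seq(30))
  expect_error(clone_set_spec(n_clones = 10,
                              allele_edits = list(a = list(type = "wt")),
                              sampling_proportions = c(0.5, 0.5)),
               "one sampling proportion")
  expect_error(clone_set_spec(n_clones = 10,
                              allele_edits = list(a = list(type = "wt"),
                                                  b = list(type = "wt")),
                              sampling_proportions = c(0.6, 0.6)),
               "sum to 1")
  far <- clone_set_spec(n_clones = 5, allele_edits = list(
    a = list(type = "del", length = 4, offset = 500)), seed = 1)
  expect_error(generate_clone_set(far, amp, PALM1_GUIDE),
               "outside amplicon")
})
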