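test_that("a planted site with NGG is found as a 0-mismatch hit", {
  genome <- c(chr1 = paste0(random_seq(40, seed = 1), PALM1_GUIDE, "TGG",
                            random_seq(40)))
  hits <- scan_offtargets(PALM1_GUIDE, genome)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$n_mismatches, 0)
  expect_equal(hits$start, 41)
  expect_equal(hits$pam_kind, "NGG")
  expect_equal(hits$mismatch_positions, "")
})

test_that("decoys beyond the mismatch bound and bad PAMs are excluded", {
  fx <- basic_fixture(seed = 41, decoy_sites = data.frame(
    mismatches = c(1, 3, 5, 6), pam_kind = "NGG"))
  hits <- scan_offtargets(PALM1_GUIDE, fx$genome, max_mismatches = 5)
  dec <- fx$truth[fx$truth$type == "decoy", ]
  for (i in seq_len(nrow(dec))) {
    found <- any(hits$chrom == dec$chrom[i] & hits$start == dec$start[i] &
                   hits$strand == "+")
    expect_equal(found, dec$mismatches[i] <= 5)
    if (dec$mismatches[i] <= 5)
      expect_equal(hits$n_mismatches[hits$chrom == dec$chrom[i] &
                                       hits$start == dec$start[i]],
                   dec$mismatches[i])
  }
  ## a perfect protospacer next to a non-NGG/NAG PAM is not a site
  genome <- c(chr1 = paste0(random_seq(30, seed = 2), PALM1_GUIDE, "ATG",
                            random_seq(30)))
  expect_equal(nrow(scan_offtargets(PALM1_GUIDE, genome)), 0)
})

test_that("guides with ambiguity codes are rejected; genomic N never matches", {
  expect_error(scan_offtargets("GGAGACGAGCACGGTCGCNG", c(chr1 = "ACGT")),
               "ambiguity")
  expect_error(scan_offtargets("ACGT", c(chr1 = "ACGT")), "20 nt")
  ## N inside the protospacer window counts as a mismatch
  site <- PALM1_GUIDE
  substr(site, 5, 5) <- "N"
  genome <- c(chr1 = paste0(random_seq(30, seed = 3), site, "AGG",
                            random_seq(30)))
  h <- scan_offtargets(PALM1_GUIDE, genome, max_mismatches = 2)
  planted <- h[h$start == 31 & h$strand == "+", ]
  expect_equal(nrow(planted), 1)
  expect_equal(planted$n_mismatches, 1)
  expect_equal(planted$mismatch_positions, "5")
  ## N inside the PAM satisfies no PAM pattern
  genome2 <- c(chr1 = paste0(random_seq(30, seed = 4), PALM1_GUIDE, "ANG",
                             random_seq(30)))
  h2 <- scan_offtargets(PALM1_GUIDE, genome2)
  expect_false(any(h2$start == 31 & h2$strand == "+"))
})

test_that("scan equals the brute-force Hamming oracle on seeded genomes", {
  for (seed in 1:6) {
    fx <- basic_fixture(seed = seed, chromosome_length = 20000, ploidy = 2,
                        decoy_sites = expand.grid(mismatches = c(0, 2, 4, 5),
                                                  pam_kind = c("NGG", "NAG")))
    hits <- scan_offtargets(PALM1_GUIDE, fx$genome, 5)
    bf <- oracle_offtargets(PALM1_GUIDE, fx$genome, 5)
    expect_identical(hit_key(hits), hit_key(bf))
  }
})

test_that("hits are monotone in the mismatch bound", {
  fx <- basic_fixture(seed = 42, decoy_sites = data.frame(
    mismatches = 0:6, pam_kind = "NGG"))
  prev <- character(0)
  for (K in 0:6) {
    h <- scan_offtargets(PALM1_GUIDE, fx$genome, K)
    keys <- paste(h$chrom, h$strand, h$start)
    expect_true(all(prev %in% keys))
    expect_true(all(h$n_mismatches <= K))
    prev <- keys
  }
})

test_that("scanning the reverse-complemented genome mirrors the hits", {
  fx <- basic_fixture(seed = 43, ploidy = 1, decoy_sites = data.frame(
    mismatches = c(1, 2), pam_kind = c("NGG", "NAG")))
  h_fwd <- scan_offtargets(PALM1_GUIDE, fx$genome, 5)
  h_rev <- scan_offtargets(PALM1_GUIDE,
                           Biostrings::reverseComplement(fx$genome), 5)
  expect_equal(nrow(h_rev), nrow(h_fwd))
  L <- length(fx$genome[[1]])
  k_fwd <- sort(paste(h_fwd$chrom, ifelse(h_fwd$strand == "+", "-", "+"),
                      L - h_fwd$start + 1, h_fwd$n_mismatches))
  k_rev <- sort(paste(h_rev$chrom, h_rev$strand, h_rev$start,
                      h_rev$n_mismatches))
  expect_identical(k_rev, k_fwd)
})

test_that("on-target hits are excluded from the off-target summary", {
  fx <- basic_fixture(seed = 44)
  al <- locate_alleles(fixture_query(fx), fx$genome)
  hits <- scan_offtargets(PALM1_GUIDE, fx$genome, 3)
  cl <- classify_hits(hits, al)
  ## the four allelic sites are on-target; nothing else is within 3 mm
  expect_equal(sum(cl$hits$is_on_target), 4)
  expect_true(all(cl$summary$n == 0))
  expect_true(no_obvious_offtargets(cl$summary))

  ## a planted decoy shows up in the summary at its mismatch class
  fx2 <- basic_fixture(seed = 45, decoy_sites = data.frame(
    mismatches = 2, pam_kind = "NGG"))
  al2 <- locate_alleles(fixture_query(fx2), fx2$genome)
  cl2 <- classify_hits(scan_offtargets(PALM1_GUIDE, fx2$genome, 3), al2)
  expect_equal(cl2$summary$n[cl2$summary$n_mismatches == 2 &
                               cl2$summary$pam_kind == "NGG"], 1)
  expect_equal(sum(cl2$summary$n), 1)
  expect_false(no_obvious_offtargets(cl2$summary))

  ## an empty hit list gives an all-zero summary
  empty <- scan_offtargets(PALM1_GUIDE, c(chr1 = random_seq(100, seed = 5)))
  cl3 <- classify_hits(empty, al)
  expect_true(all(cl3$summary$n == 0))
  expect_equal(nrow(cl3$summary), 12)  # 0..5 mismatches x NGG/NAG
})
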