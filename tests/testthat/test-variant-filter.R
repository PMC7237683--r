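## Fixture: genome with 4 on-target allelic sites plus planted decoys,
## scanned and classified so sites carry on-target flags.
vf_fixture <- function(seed = 51) {
  fx <- basic_fixture(seed = seed, chromosome_length = 20000,
                      decoy_sites = data.frame(mismatches = c(2, 4),
                                               pam_kind = c("NGG", "NAG")))
  al <- locate_alleles(fixture_query(fx), fx$genome)
  cl <- classify_hits(scan_offtargets(PALM1_GUIDE, fx$genome, 5), al)
  list(fx = fx, sites = cl$hits,
       decoys = fx$truth[fx$truth$type == "decoy", ],
       ontarget = fx$truth[fx$truth$type == "protospacer", ])
}

test_that("SNVs are never candidates, even exactly at the -3 position", {
  v <- vf_fixture()
  cut <- v$decoys$start[1] + 16
  vars <- data.frame(chrom = v$decoys$chrom[1], pos = cut, ref = "G",
                     alt = "T", type = "SNV", passes_quality = TRUE)
  verd <- filter_offtarget_variants(vars, v$sites)
  expect_false(verd$is_candidate)
  expect_equal(verd$reason, "SNV excluded")
})

test_that("indels at or near the cut of a non-on-target site are candidates", {
  v <- vf_fixture()
  cut <- v$decoys$start[1] + 16
  vars <- data.frame(
    chrom = v$decoys$chrom[1],
    pos = c(cut, cut - 2, cut + 2, cut - 10),
    ref = c("ACG", "A", "AGT", "G"),
    alt = c("A", "AT", "A", "GTT"),
    type = c("deletion", "insertion", "deletion", "insertion"),
    passes_quality = TRUE)
  verd <- filter_offtarget_variants(vars, v$sites, tolerance = 2)
  expect_equal(verd$is_candidate, c(TRUE, TRUE, TRUE, FALSE))
  expect_equal(verd$distance_to_minus3[1:3], c(0, -2, 2))
  expect_equal(verd$reason[4], "no off-target site nearby")
})

test_that("indels at on-target allelic sites are excluded as targeted region", {
  v <- vf_fixture()
  cut <- v$ontarget$start[1] + 16
  vars <- data.frame(chrom = v$ontarget$chrom[1], pos = cut, ref = "AC",
                     alt = "A", type = "deletion", passes_quality = TRUE)
  verd <- filter_offtarget_variants(vars, v$sites)
  expect_false(verd$is_candidate)
  expect_equal(verd$reason, "targeted region")
})

test_that("raising the tolerance never shrinks the candidate set", {
  v <- vf_fixture()
  cut <- v$decoys$start[2] + 16
  set.seed(5)
  vars <- data.frame(chrom = v$decoys$chrom[2],
                     pos = cut + sample(-8:8, 12, replace = TRUE),
                     ref = "AC", alt = "A", type = "deletion",
                     passes_quality = TRUE)
  prev <- rep(FALSE, nrow(vars))
  for (tol in 0:8) {
    cand <- filter_offtarget_variants(vars, v$sites,
                                      tolerance = tol)$is_candidate
    expect_true(all(cand[prev]))
    prev <- cand
  }
})

test_that("every record gets exactly one verdict; candidates are never SNVs", {
  v <- vf_fixture()
  set.seed(7)
  n <- 40
  chroms <- sample(names(v$fx$genome), n, replace = TRUE)
  pos <- sample(100:19000, n)
  is_snv <- runif(n) < 0.5
  vars <- data.frame(chrom = chroms, pos = pos,
                     ref = ifelse(is_snv, "A", "ACT"),
                     alt = ifelse(is_snv, "G", "A"),
                     type = ifelse(is_snv, "SNV", "deletion"),
                     passes_quality = TRUE)
  verd <- filter_offtarget_variants(vars, v$sites, v$fx$annotation)
  expect_equal(nrow(verd), n)
  expect_equal(verd$pos, vars$pos)
  expect_false(any(verd$is_candidate & verd$type == "SNV"))
  expect_true(all(nzchar(verd$reason)))
})

test_that("VCF round trip preserves records and classifies types", {
  vars <- data.frame(chrom = "chr1.1", pos = c(100, 200, 300, 400),
                     ref = c("A", "ACGT", "A", "AT"),
                     alt = c("G", "A", "ATTT", "CG"))
  tmp <- tempfile(fileext = ".vcf")
  write_simple_vcf(vars, tmp)
  rv <- read_variants(tmp)
  expect_equal(nrow(rv), 4)
  expect_equal(rv$type, c("SNV", "deletion", "insertion", "other"))
  expect_true(all(rv$passes_quality))
})

test_that("malformed records are rejected with a reason, never dropped", {
  v <- vf_fixture()
  vars <- data.frame(chrom = "chr1.1", pos = c(100, NA),
                     ref = c("AXT", "AC"), alt = c("A", "A"),
                     type = c("malformed", "deletion"),
                     passes_quality = TRUE)
  verd <- filter_offtarget_variants(vars, v$sites)
  expect_equal(nrow(verd), 2)
  expect_equal(verd$reason, c("malformed record", "malformed record"))
  expect_false(any(verd$is_candidate))
})

test_that("coding off-target candidates are counted per gene", {
  v <- vf_fixture()
  ## a deletion at a decoy cut is intergenic in this fixture
  cut <- v$decoys$start[1] + 16
  vars <- data.frame(chrom = v$decoys$chrom[1], pos = cut, ref = "AC",
                     alt = "A", type = "deletion", passes_quality = TRUE)
  verd <- filter_offtarget_variants(vars, v$sites, v$fx$annotation)
  expect_true(verd$is_candidate)
  expect_false(verd$in_coding_region)
  expect_equal(summarize_coding_offtargets(verd,
                                           v$fx$annotation)$n_coding_candidates,
               0)
  ## force a coding "site" by marking a fake off-target inside the gene CDS
  exon <- v$fx$truth[v$fx$truth$type == "exon" &
                       v$fx$truth$chrom == "chr1.2", ][1, ]
  fake_site <- data.frame(chrom = "chr1.2", strand = "+",
                          start = exon$start + 40, is_on_target = FALSE)
  vars2 <- data.frame(chrom = "chr1.2", pos = exon$start + 40 + 16,
                      ref = "AC", alt = "A", type = "deletion",
                      passes_quality = TRUE)
  verd2 <- filter_offtarget_variants(vars2, fake_site, v$fx$annotation)
  expect_true(verd2$is_candidate)
  expect_true(verd2$in_coding_region)
  s <- summarize_coding_offtargets(verd2, v$fx$annotation)
  expect_equal(s$n_coding_candidates, 1)
  expect_equal(nrow(s$per_gene), 1)
})
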