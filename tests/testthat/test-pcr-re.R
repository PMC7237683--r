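test_that("the blunt cut falls between protospacer positions 17 and 18", {
  expect_equal(predict_cut_site(1, "+"), 17)
  expect_equal(predict_cut_site(101, "+"), 117)
  ## minus strand: apply the plus-strand rule to the reverse complement
  ## and map back. A protospacer whose 5' base sits at genomic s on the
  ## minus strand spans s-19..s; its position-17 base is at s-16, so the
  ## cut lies between s-17 and s-16.
  s <- 200
  expect_equal(predict_cut_site(s, "-"), s - 17)
  L <- 500
  expect_equal(L - predict_cut_site(L - s + 1, "+"), predict_cut_site(s, "-"))
})

test_that("the BstUI site overlaps the predicted cut of the printed guide", {
  context <- paste0(random_seq(50, seed = 1), PALM1_GUIDE, "CGG",
                    random_seq(50))
  bstui <- read_enzymes()[["BstUI"]]
  expect_equal(bstui$recognition_site, "CGCG")
  expect_equal(bstui$cut_offset, 2)
  sites <- find_overlapping_sites(PALM1_GUIDE, bstui, context)
  ov <- sites[sites$overlaps_cut, ]
  expect_equal(nrow(ov), 1)
  ## CGCG sits at protospacer positions 16-19 = context 65-69... relative
  expect_equal(ov$start, 50 + 16)
  expect_equal(ov$end, 50 + 19)
  ## cut between protospacer 17|18 is inside the site
  expect_equal(attr(sites, "cut_after"), 50 + 17)
})

test_that("contexts without the recognition site return no matches", {
  ecoRI <- enzyme("EcoRI", "GAATTC", 1)
  context <- paste0(random_seq(40, seed = 6), PALM1_GUIDE, "CGG")
  context <- gsub("GAATTC", "GAATAC", context)
  sites <- find_overlapping_sites(PALM1_GUIDE, ecoRI, context)
  expect_equal(nrow(sites), 0)
})

test_that("palindromic sites are reported once per interval", {
  context <- paste0(random_seq(20, seed = 8), PALM1_GUIDE, "CGG",
                    "AAAA", "GGATCC", "AAAA")
  bamhi <- enzyme("BamHI", "GGATCC", 1)
  sites <- find_overlapping_sites(PALM1_GUIDE, bamhi, context)
  expect_equal(sum(sites$start == nchar(context) - 9), 1)
})

test_that("digest fragments are computed left to right and sum to length", {
  bstui <- enzyme("BstUI", "CGCG", 2)
  ## zero sites: one fragment
  amp0 <- gsub("CGCG", "CTCG", random_seq(300, seed = 9))
  d0 <- digest(amp0, bstui)
  expect_equal(d0$fragment_lengths, nchar(amp0))
  expect_equal(d0$n_sites, 0)
  ## one CGCG at position 121: CG^CG cuts after base 122
  amp1 <- paste0(strrep("A", 120), "CGCG", strrep("T", 176))
  d1 <- digest(amp1, bstui)
  expect_equal(d1$fragment_lengths, c(122, 178))
  expect_equal(d1$n_sites, 1)
  ## a deletion spanning the site disrupts it
  amp_del <- paste0(strrep("A", 120), "CG", strrep("T", 176))
  dd <- digest(amp_del, bstui, reference = amp1)
  expect_equal(dd$n_sites, 0)
  expect_true(dd$disrupted_by_edit)
})

test_that("fragment lengths always sum to the amplicon length", {
  enzymes <- read_enzymes()
  for (seed in 1:10) {
    amp <- random_seq(80 + 37 * seed, seed = seed)
    for (e in enzymes) {
      d <- digest(amp, e)
      expect_equal(sum(d$fragment_lengths), nchar(amp))
      expect_equal(length(d$fragment_lengths), d$n_sites + 1)
    }
  }
})

test_that("every single-base substitution of CGCG destroys the site", {
  bstui <- enzyme("BstUI", "CGCG", 2)
  amp <- paste0(strrep("A", 50), "CGCG", strrep("T", 50))
  expect_equal(digest(amp, bstui)$n_sites, 1)
  for (p in 1:4) for (b in setdiff(c("A", "C", "G", "T"),
                                   substr("CGCG", p, p))) {
    mut <- amp
    substr(mut, 50 + p, 50 + p) <- b
    d <- digest(mut, bstui, reference = amp)
    expect_equal(d$n_sites, 0)
    expect_true(d$disrupted_by_edit)
  }
})

test_that("cut-overlap detection matches interval arithmetic on random placements", {
  set.seed(77)
  bstui <- enzyme("BstUI", "CGCG", 2)
  guide <- "CTGGAGGCAAGAGATGTTCT"  # contains no CGCG itself
  tested <- 0
  for (rep in 1:60) {
    offset <- sample(-30:30, 1)
    flank <- 60
    context <- paste0(random_seq(flank), guide, "TGG", random_seq(flank))
    context <- gsub("CGCG", "ACGT", context)  # keep a single planted site
    site_start <- flank + 17 + 1 + offset
    substr(context, site_start, site_start + 3) <- "CGCG"
    if (substring(context, flank + 1, flank + 20) != guide) next
    sites <- find_overlapping_sites(guide, bstui, context)
    cut <- flank + 17
    planted <- sites[sites$start == site_start, ]
    if (nrow(planted) == 1) {
      tested <- tested + 1
      expect_equal(planted$overlaps_cut,
                   site_start <= cut && cut + 1 <= site_start + 3)
    }
  }
  expect_gte(tested, 15)
})

test_that("enzyme definitions are validated", {
  expect_error(enzyme("X", "CGC", 1), "at least 4")
  expect_error(enzyme("X", "CGCG", 5), "within the recognition site")
  expect_error(digest("ACG", enzyme("BstUI", "CGCG", 2)), "shorter")
})

test_that("IUPAC ambiguity codes in recognition sites are honoured", {
  ddeI <- enzyme("DdeI", "CTNAG", 1)  # N matches any base
  for (b in c("A", "C", "G", "T")) {
    amp <- paste0(strrep("A", 30), "CT", b, "AG", strrep("T", 30))
    expect_equal(digest(amp, ddeI)$n_sites, 1)
  }
})
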