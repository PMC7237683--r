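## Exact mismatch-bounded off-target enumeration. A candidate site is any
## 20-mer on either strand lying immediately 5' of an NGG or NAG PAM and
## within `max_mismatches` Hamming mismatches of the guide. The search is
## complete: every qualifying site in the genome is reported exactly once.

pam_kind_of <- function(pam) {
  ifelse(grepl("^[ACGT]GG$", pam), "NGG",
         ifelse(grepl("^[ACGT]AG$", pam), "NAG", NA_character_))
}

#' Scan a genome for off-target sites of a guide
#'
#' Enumerates every genomic site on either strand that (i) lies
#' immediately 5' of a PAM of one of the requested kinds and (ii) matches
#' the 20-nt guide with at most `max_mismatches` mismatches (Hamming
#' distance; bulges are not modelled). An `N` in the genome matches no
#' guide base and satisfies no PAM pattern. Mismatch positions are
#' numbered 1 (PAM-distal, 5' end of the protospacer) to 20
#' (PAM-proximal).
#'
#' @param guide 20-nt protospacer over A/C/G/T (no ambiguity codes).
#' @param genome A [Biostrings::DNAStringSet], named character vector, or
#'   FASTA path.
#' @param max_mismatches Maximum mismatches allowed (default 5, the bound
#'   used for sgRNA screening in polyploid editing pipelines; at most 10).
#' @param pams PAM kinds to accept, subset of `c("NGG", "NAG")`. SpCas9
#'   targets NGG; NAG is tolerated at off-target sites.
#' @return Data frame, one row per hit: `chrom`, `strand`, `start` (1-based
#'   genomic coordinate of the protospacer's 5' base on its own strand),
#'   `gstart`/`gend` (genomic interval of the protospacer on the plus
#'   strand), `site_sequence`, `pam`, `pam_kind`, `n_mismatches`,
#'   `mismatch_positions` (comma-separated, 1-20), `is_on_target`
#'   (`NA` until [classify_hits()] is applied). Attributes
#'   `max_mismatches` and `pams` record the scan parameters.
#' @examples
#' g <- "GGAGACGAGCACGGTCGCGG"
#' genome <- c(chr1 = paste0(strrep("A", 30), g, "CGG", strrep("T", 30)))
#' scan_offtargets(g, genome)[, c("start", "n_mismatches", "pam_kind")]
#' @export
scan_offtargets <- function(guide, genome, max_mismatches = 5L,
                            pams = c("NGG", "NAG")) {
  guide <- as_dna_character(guide, "guide")
  if (nchar(guide) != 20L) stop("'guide' must be exactly 20 nt")
  if (!grepl("^[ACGT]+$", guide))
    stop("'guide' contains ambiguity codes; only A/C/G/T are supported")
  if (max_mismatches > 10L) stop("'max_mismatches' must be <= 10")
  pams <- match.arg(pams, c("NGG", "NAG"), several.ok = TRUE)
  genome <- as_genome(genome)

  guide_chars <- strsplit(guide, "")[[1]]
  rows <- list()
  for (chrom in names(genome)) {
    chrseq <- genome[[chrom]]
    L <- length(chrseq)
    if (L < 23L) next
    for (strand in c("+", "-")) {
      subj <- if (strand == "+") chrseq else Biostrings::reverseComplement(chrseq)
      m <- Biostrings::matchPattern(Biostrings::DNAString(guide), subj,
                                    max.mismatch = max_mismatches)
      st <- Biostrings::start(m)
      st <- st[st + 22L <= L]  # PAM must fit
      if (length(st) == 0L) next
      sites <- as.character(Biostrings::extractAt(
        subj, IRanges::IRanges(st, width = 20L)))
      pamseq <- as.character(Biostrings::extractAt(
        subj, IRanges::IRanges(st + 20L, width = 3L)))
      kind <- pam_kind_of(pamseq)
      keep <- !is.na(kind) & kind %in% pams
      if (!any(keep)) next
      st <- st[keep]; sites <- sites[keep]; pamseq <- pamseq[keep]
      kind <- kind[keep]
      mmpos <- lapply(sites, function(s)
        which(strsplit(s, "")[[1]] != guide_chars))
      nmm <- lengths(mmpos)
      ok <- nmm <= max_mismatches  # N-containing windows can exceed the bound
      if (!any(ok)) next
      st <- st[ok]; sites <- sites[ok]; pamseq <- pamseq[ok]
      kind <- kind[ok]; mmpos <- mmpos[ok]; nmm <- nmm[ok]
      if (strand == "+") {
        start5 <- st; gstart <- st; gend <- st + 19L
      } else {
        start5 <- L - st + 1L; gstart <- L - st - 18L; gend <- L - st + 1L
      }
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = chrom, strand = strand, start = start5,
        gstart = gstart, gend = gend, site_sequence = sites, pam = pamseq,
        pam_kind = kind, n_mismatches = nmm,
        mismatch_positions = vapply(mmpos, paste, character(1), collapse = ","),
        is_on_target = NA, row.names = NULL)
    }
  }
  hits <- if (length(rows)) do.call(rbind, rows) else
    data.frame(chrom = character(0), strand = character(0),
               start = integer(0), gstart = integer(0), gend = integer(0),
               site_sequence = character(0), pam = character(0),
               pam_kind = character(0), n_mismatches = integer(0),
               mismatch_positions = character(0), is_on_target = logical(0))
  hits <- hits[order(hits$chrom, hits$gstart, hits$strand), , drop = FALSE]
  rownames(hits) <- NULL
  attr(hits, "max_mismatches") <- as.integer(max_mismatches)
  attr(hits, "pams") <- pams
  attr(hits, "guide") <- guide
  hits
}

#' Classify off-target hits against the intended target's allelic copies
#'
#' Hits whose protospacer interval overlaps any allelic copy of the
#' intended gene are flagged on-target and excluded from the off-target
#' summary. The summary is a complete contingency table of the remaining
#' hits over mismatch count (0..`max_mismatches`) and PAM kind.
#'
#' @param hits Result of [scan_offtargets()].
#' @param alleles An `allele_set` (see [locate_alleles()]), a
#'   [GenomicRanges::GRanges] of copy spans, or `NULL` (no on-target
#'   exclusion).
#' @return List with `hits` (input with `is_on_target` filled) and
#'   `summary` (data frame `n_mismatches`, `pam_kind`, `n`).
#' @export
classify_hits <- function(hits, alleles = NULL) {
  K <- attr(hits, "max_mismatches")
  if (is.null(K)) K <- max(c(hits$n_mismatches, 0L))
  pams <- attr(hits, "pams")
  if (is.null(pams)) pams <- c("NGG", "NAG")

  on_target <- rep(FALSE, nrow(hits))
  if (!is.null(alleles) && nrow(hits) > 0L) {
    spans <- if (inherits(alleles, "allele_set")) allele_spans(alleles)
             else alleles
    if (length(spans) > 0L) {
      q <- GenomicRanges::GRanges(hits$chrom,
                                  IRanges::IRanges(hits$gstart, hits$gend))
      on_target <- IRanges::overlapsAny(q, spans, ignore.strand = TRUE)
    }
  }
  hits$is_on_target <- on_target
  off <- hits[!on_target, , drop = FALSE]
  grid <- expand.grid(n_mismatches = 0L:K, pam_kind = pams,
                      stringsAsFactors = FALSE)
  grid$n <- mapply(function(m, p)
    sum(off$n_mismatches == m & off$pam_kind == p), grid$n_mismatches,
    grid$pam_kind)
  list(hits = hits, summary = grid)
}

#' Apply the "no obvious off-target site" rule
#'
#' Operationalizes the design requirement that a chosen guide have no
#' obvious off-target site: by default, zero non-on-target hits with at
#' most `max_obvious_mismatches` mismatches under any accepted PAM.
#'
#' @param summary The `summary` component of [classify_hits()].
#' @param max_obvious_mismatches Mismatch bound below which any hit
#'   disqualifies the guide (default 3).
#' @return `TRUE` when no disqualifying off-target site exists.
#' @export
no_obvious_offtargets <- function(summary, max_obvious_mismatches = 3L) {
  sum(summary$n[summary$n_mismatches <= max_obvious_mismatches]) == 0L
}

#' Write off-target hits as BED6+
#'
#' BED6 interval of each protospacer site plus extra columns: site
#' sequence, PAM, mismatch count, mismatch positions.
#'
#' @param hits Result of [scan_offtargets()] or [classify_hits()]`$hits`.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_hits_bed <- function(hits, path) {
  bed <- data.frame(chrom = hits$chrom, start = hits$gstart - 1L,
                    end = hits$gend, name = hits$site_sequence,
                    score = hits$n_mismatches, strand = hits$strand,
                    pam = hits$pam, mismatch_positions = hits$mismatch_positions)
  write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
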