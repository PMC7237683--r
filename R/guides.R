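## Guide enumeration and ranking. Candidates are every 20-nt protospacer
## immediately 5' of an NGG PAM, both strands, with protospacer + PAM
## fully inside an exon of an allelic copy. Ranking follows five design
## criteria: cover all alleles; no obvious off-target site; proximity to
## the start codon (or a conserved exon); high GC content; 5' G for U6 /
## MtU6-driven expression (satisfiable by prepending a G to the vector
## spacer).

#' GC fraction of a sequence
#'
#' `(#G + #C) / length`; `N` and other ambiguity codes count as non-GC.
#' High protospacer GC correlates with sgRNA efficacy.
#'
#' @param seq Non-empty sequence (character or DNAString); vectorized.
#' @return Numeric fraction in `[0, 1]`.
#' @examples
#' gc_fraction("GGAGACGAGCACGGTCGCGG")  # 0.75
#' @export
gc_fraction <- function(seq) {
  seq <- as_dna_character(seq, "seq")
  if (any(nchar(seq) == 0L)) stop("empty sequence")
  vapply(strsplit(seq, ""), function(b) sum(b %in% c("G", "C")) / length(b),
         numeric(1))
}

## Enumerate protospacer+NGG windows fully inside one exon sequence.
## Returns local 1-based coordinates of the protospacer 5' end on the
## given strand of the exon.
exon_guides_one_strand <- function(exon_seq) {
  n <- nchar(exon_seq)
  if (n < 23L) return(integer(0))
  b <- strsplit(exon_seq, "")[[1]]
  pam_at <- which(b == "G" & c(b[-1], "") == "G")  # positions i: b[i]=b[i+1]=G
  pam_at <- pam_at[pam_at >= 22L & pam_at + 1L <= n]
  pam_at - 21L  # protospacer start
}

#' Enumerate candidate guides from an allele set
#'
#' Scans every exon of every allelic copy, both strands, for 20-mer
#' protospacers immediately 5' of an NGG PAM (protospacer and PAM fully
#' inside the exon). Candidates are deduplicated by protospacer sequence;
#' `allele_coverage` counts the copies carrying the exact
#' protospacer+NGG, and `distance_to_start_codon` is the CDS offset (bp)
#' of the protospacer's 5'-most CDS base from the A of the start codon.
#'
#' @param alleles An `allele_set` from [locate_alleles()] (non-empty).
#' @param genome The genome the alleles were located in.
#' @return Data frame of class `guide_candidates`: `protospacer`, `pam`,
#'   `chrom`, `strand`, `start` (protospacer 5' end on its own strand),
#'   `exon_index`, `distance_to_start_codon`, `gc_fraction`,
#'   `starts_with_g`, `allele_coverage`, `in_conserved_exon`. Attribute
#'   `ploidy` records the number of copies.
#' @export
enumerate_guides <- function(alleles, genome) {
  stopifnot(inherits(alleles, "allele_set"))
  if (alleles$copy_number == 0L) stop("allele set is empty")
  genome <- as_genome(genome)
  for (cp in alleles$copies)
    if (nrow(cp$exons) == 0L) stop("copy with no exons")

  ## per-copy exon sequences in coding orientation, for coverage and
  ## conserved-exon comparison
  copy_exon_seqs <- lapply(alleles$copies, function(cp) {
    s <- substring(as.character(genome[[cp$chromosome]]),
                   cp$exons$start, cp$exons$end)
    if (cp$strand == "-") s <- vapply(s, revcomp, character(1))
    unname(s)
  })
  n_exons <- vapply(copy_exon_seqs, length, integer(1))
  conserved <- rep(FALSE, max(n_exons))
  if (length(unique(n_exons)) == 1L) {
    for (e in seq_len(n_exons[1]))
      conserved[e] <- length(unique(vapply(copy_exon_seqs, `[`, character(1),
                                           e))) == 1L
  }

  rows <- list()
  for (ci in seq_along(alleles$copies)) {
    cp <- alleles$copies[[ci]]
    chrseq <- as.character(genome[[cp$chromosome]])
    cum_cds <- c(0L, cumsum(cp$exons$end - cp$exons$start + 1L))
    for (ei in seq_len(nrow(cp$exons))) {
      es <- cp$exons$start[ei]; ee <- cp$exons$end[ei]
      exon_plus <- substring(chrseq, es, ee)
      cds_of_plus <- function(pos) {
        # CDS coordinate (1-based from start codon) of a plus-strand base
        if (cp$strand == "+") cum_cds[ei] + (pos - es + 1L)
        else cum_cds[ei] + (ee - pos + 1L)
      }
      for (gstrand in c("+", "-")) {
        eseq <- if (gstrand == "+") exon_plus else revcomp(exon_plus)
        loc <- exon_guides_one_strand(eseq)
        for (p in loc) {
          proto <- substr(eseq, p, p + 19L)
          pam <- substr(eseq, p + 20L, p + 22L)
          if (gstrand == "+") {
            start5 <- es + p - 1L
            ends_plus <- c(start5, start5 + 19L)
          } else {
            start5 <- ee - p + 1L
            ends_plus <- c(start5 - 19L, start5)
          }
          dist <- min(cds_of_plus(ends_plus[1]), cds_of_plus(ends_plus[2])) - 1L
          rows[[length(rows) + 1L]] <- data.frame(
            protospacer = proto, pam = pam, chrom = cp$chromosome,
            strand = gstrand, start = start5, exon_index = ei,
            distance_to_start_codon = dist, copy = ci)
        }
      }
    }
  }
  if (length(rows) == 0L) {
    out <- data.frame(protospacer = character(0), pam = character(0),
                      chrom = character(0), strand = character(0),
                      start = integer(0), exon_index = integer(0),
                      distance_to_start_codon = integer(0),
                      gc_fraction = numeric(0), starts_with_g = logical(0),
                      allele_coverage = integer(0),
                      in_conserved_exon = logical(0))
    attr(out, "ploidy") <- alleles$copy_number
    class(out) <- c("guide_candidates", "data.frame")
    return(out)
  }
  cand <- do.call(rbind, rows)
  cand <- cand[order(cand$protospacer, cand$chrom, cand$start), ]
  first <- !duplicated(cand$protospacer)

  ## exact protospacer+NGG presence per copy (either strand of the exons)
  coverage_of <- function(proto) {
    pat1 <- paste0(proto, "[ACGT]GG")
    rc <- revcomp(proto)
    pat2 <- paste0("CC[ACGT]", rc)
    sum(vapply(copy_exon_seqs, function(ex)
      any(grepl(pat1, ex) | grepl(pat2, ex)), logical(1)))
  }

  out <- cand[first, , drop = FALSE]
  out$copy <- NULL
  out$gc_fraction <- gc_fraction(out$protospacer)
  out$starts_with_g <- startsWith(out$protospacer, "G")
  out$allele_coverage <- vapply(out$protospacer, coverage_of, numeric(1))
  out$in_conserved_exon <- conserved[out$exon_index]
  out <- out[order(out$chrom, out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "ploidy") <- alleles$copy_number
  class(out) <- c("guide_candidates", "data.frame")
  out
}

#' Annotate guide candidates with off-target summaries
#'
#' Runs [scan_offtargets()] and [classify_hits()] for each candidate and
#' records the total off-target hit count, the count at up to
#' `max_obvious_mismatches` mismatches, and a per-class breakdown.
#'
#' @param candidates A `guide_candidates` data frame.
#' @param genome Genome to scan.
#' @param alleles The `allele_set` whose copies are on-target.
#' @param max_mismatches,pams Passed to [scan_offtargets()].
#' @param max_obvious_mismatches Bound for the "obvious off-target" rule.
#' @return The candidates with columns `offtarget_total`, `offtarget_obvious`
#'   and `offtarget_by_class` added.
#' @export
annotate_offtargets <- function(candidates, genome, alleles,
                                max_mismatches = 5L, pams = c("NGG", "NAG"),
                                max_obvious_mismatches = 3L) {
  genome <- as_genome(genome)
  res <- lapply(candidates$protospacer, function(g) {
    cl <- classify_hits(scan_offtargets(g, genome, max_mismatches, pams),
                        alleles)
    cl$summary
  })
  candidates$offtarget_total <- vapply(res, function(s) sum(s$n), numeric(1))
  candidates$offtarget_obvious <- vapply(res, function(s)
    sum(s$n[s$n_mismatches <= max_obvious_mismatches]), numeric(1))
  candidates$offtarget_by_class <- vapply(res, function(s)
    paste(sprintf("%dmm/%s:%d", s$n_mismatches, s$pam_kind, s$n)[s$n > 0],
          collapse = ";"), character(1))
  candidates
}

#' Score and rank guide candidates
#'
#' Hard filters come first: the guide must cover all alleles
#' (`allele_coverage == ploidy`), must have no obvious off-target site
#' (zero non-allelic hits at up to `max_obvious_mismatches` mismatches),
#' and — only with `strict_5g = TRUE` — must start with G. By default a
#' non-G 5' end is satisfied by prepending a G for vector expression,
#' reported in `vector_spacer`. Survivors are ranked by
#' `rank_score = w_gc * GC + w_prox / (1 + d/L) + w_cons * conserved`,
#' where `d` is the distance to the start codon; ties break by fewer
#' total off-target hits, then smaller genomic coordinate.
#'
#' @param candidates Output of [annotate_offtargets()].
#' @param weights Named numeric vector `c(gc=, proximity=, conserved=)`.
#' @param L Length scale (bp of CDS) for the proximity term (default 200).
#' @param ploidy Number of alleles a guide must cover; defaults to the
#'   `ploidy` attribute of the candidates.
#' @param strict_5g Require a genomic 5' G instead of allowing a
#'   prepended one.
#' @param max_obvious_mismatches Mismatch bound of the off-target rule.
#' @return The candidates with `passes_filters`, `filter_reason`,
#'   `vector_spacer`, `rank_score` and `rank` (NA for filtered-out rows),
#'   ordered by rank.
#' @export
score_guides <- function(candidates,
                         weights = c(gc = 1, proximity = 1, conserved = 0.5),
                         L = 200, ploidy = attr(candidates, "ploidy"),
                         strict_5g = FALSE, max_obvious_mismatches = 3L) {
  if (is.null(candidates$offtarget_obvious))
    stop("off-target summary not populated; run annotate_offtargets() first")
  if (is.null(ploidy)) stop("'ploidy' is required")
  reason <- character(nrow(candidates))
  ok <- rep(TRUE, nrow(candidates))
  miss <- candidates$allele_coverage < ploidy
  ok[miss] <- FALSE
  reason[miss] <- paste0(reason[miss], "does not cover all alleles;")
  bad_ot <- candidates$offtarget_obvious > 0
  ok[bad_ot] <- FALSE
  reason[bad_ot] <- paste0(reason[bad_ot], "obvious off-target site;")
  if (strict_5g) {
    no_g <- !candidates$starts_with_g
    ok[no_g] <- FALSE
    reason[no_g] <- paste0(reason[no_g], "does not start with G;")
  }
  candidates$passes_filters <- ok
  candidates$filter_reason <- sub(";$", "", reason)
  candidates$vector_spacer <- ifelse(candidates$starts_with_g,
                                     candidates$protospacer,
                                     paste0("G", candidates$protospacer))
  candidates$rank_score <-
    weights[["gc"]] * candidates$gc_fraction +
    weights[["proximity"]] / (1 + candidates$distance_to_start_codon / L) +
    weights[["conserved"]] * as.numeric(candidates$in_conserved_exon)
  ord <- order(!candidates$passes_filters, -candidates$rank_score,
               candidates$offtarget_total, candidates$start)
  candidates <- candidates[ord, , drop = FALSE]
  candidates$rank <- NA_integer_
  candidates$rank[candidates$passes_filters] <-
    seq_len(sum(candidates$passes_filters))
  rownames(candidates) <- NULL
  candidates
}

#' Write ranked guide candidates as TSV and BED6
#'
#' @param candidates Scored candidates from [score_guides()].
#' @param tsv Path for the full table; `NULL` to skip.
#' @param bed Path for BED6 protospacer intervals; `NULL` to skip.
#' @return Invisibly, the candidates.
#' @export
write_guides <- function(candidates, tsv = NULL, bed = NULL) {
  if (!is.null(tsv))
    write.table(candidates, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(bed)) {
    gstart <- ifelse(candidates$strand == "+", candidates$start,
                     candidates$start - 19L)
    bed6 <- data.frame(candidates$chrom, gstart - 1L, gstart + 19L,
                       candidates$protospacer,
                       ifelse(is.na(candidates$rank), 0L, candidates$rank),
                       candidates$strand)
    write.table(bed6, bed, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
  }
  invisible(candidates)
}
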