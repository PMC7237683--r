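## Locate every allelic copy of a target gene in an allele-aware assembly
## by aligning a query CDS/mRNA against the genome. The engine is k-mer
## anchoring (exact k-mer seeds, default k = 15) with same-diagonal block
## merging and chaining; blocks become exons and genome-side gaps between
## blocks become introns. Designed for allelic copies at <= ~1%
## divergence, where substitutions dominate and gapped extension beyond
## the chained anchors is unnecessary.

## Anchors of query k-mers in a subject string. Returns (qpos, gpos).
kmer_anchors <- function(query, subject, k) {
  nq <- nchar(query); ns <- nchar(subject)
  if (nq < k || ns < k) return(NULL)
  qk <- substring(query, 1:(nq - k + 1L), k:nq)
  gk <- substring(subject, 1:(ns - k + 1L), k:ns)
  m <- match(gk, qk)
  hit <- which(!is.na(m))
  if (length(hit) == 0L) return(NULL)
  list(qpos = m[hit], gpos = hit)
}

## Chain anchors of one locus into exon blocks on one subject strand.
## Returns data.frame(qs, qe, gs, ge, mm) in query order, covering
## q = 1..nq (terminal blocks snapped to the query ends along their
## diagonal, clipped at subject bounds).
chain_blocks <- function(anchors, query, subject, k, max_intron = 10000L) {
  diag <- anchors$gpos - anchors$qpos
  ord <- order(diag, anchors$qpos)
  qp <- anchors$qpos[ord]; dg <- diag[ord]
  if (length(qp) == 0L) return(NULL)

  ## collapse anchors into maximal same-diagonal runs
  new_run <- c(TRUE, dg[-1] != dg[-length(dg)] |
                 qp[-1] > qp[-length(qp)] + 1L)
  rid <- cumsum(new_run)
  runs <- data.frame(qs = tapply(qp, rid, min),
                     qe = tapply(qp, rid, max) + k - 1L,
                     diag = tapply(dg, rid, min))
  runs <- runs[order(runs$qs, runs$diag), , drop = FALSE]

  ## weighted chain: maximize anchored query length over runs compatible
  ## in both query and genome order (robust to spurious repeat anchors)
  nr <- nrow(runs)
  len <- runs$qe - runs$qs + 1L
  dp <- len; prev <- rep(NA_integer_, nr)
  for (i in seq_len(nr)) {
    for (j in seq_len(i - 1L)) {
      gap_g <- (runs$qs[i] + runs$diag[i]) - (runs$qe[j] + runs$diag[j])
      if (runs$qs[i] > runs$qs[j] && runs$qe[i] > runs$qe[j] &&
          (runs$diag[i] == runs$diag[j] || gap_g > 0L) &&
          gap_g <= max_intron && dp[j] + len[i] > dp[i]) {
        dp[i] <- dp[j] + len[i]
        prev[i] <- j
      }
    }
  }
  sel <- integer(0)
  i <- which.max(dp)
  while (!is.na(i)) { sel <- c(i, sel); i <- prev[i] }
  runs <- runs[sel, , drop = FALSE]

  qc <- strsplit(query, "")[[1]]
  sc <- strsplit(subject, "")[[1]]
  nq <- length(qc); ns <- length(sc)
  count_mm <- function(qs, qe, gs) {
    if (qe < qs) return(0L)
    g_idx <- gs:(gs + (qe - qs))
    ok <- g_idx >= 1L & g_idx <= ns
    sum(qc[qs:qe][ok] != sc[g_idx[ok]]) + sum(!ok)
  }

  ## merge same-diagonal runs (bridging substitution gaps) into blocks
  blocks <- list()
  cur <- list(qs = runs$qs[1], qe = runs$qe[1], diag = runs$diag[1], mm = 0L)
  for (i in seq_len(nrow(runs))[-1]) {
    if (runs$diag[i] == cur$diag) {
      if (runs$qe[i] > cur$qe) {
        gap_from <- cur$qe + 1L
        if (runs$qs[i] > gap_from)
          cur$mm <- cur$mm + count_mm(gap_from, runs$qs[i] - 1L,
                                      gap_from + cur$diag)
        cur$qe <- runs$qe[i]
      }
    } else {
      blocks[[length(blocks) + 1L]] <- cur
      cur <- list(qs = runs$qs[i], qe = runs$qe[i], diag = runs$diag[i],
                  mm = 0L)
    }
  }
  blocks[[length(blocks) + 1L]] <- cur

  ## snap terminal blocks to the query ends along their diagonals
  b1 <- blocks[[1]]
  ext <- b1$qs - 1L
  ext <- min(ext, b1$qs + b1$diag - 1L)  # clip at subject start
  if (ext > 0L) {
    b1$mm <- b1$mm + count_mm(b1$qs - ext, b1$qs - 1L, b1$qs - ext + b1$diag)
    b1$qs <- b1$qs - ext
  }
  blocks[[1]] <- b1
  bl <- blocks[[length(blocks)]]
  ext <- nq - bl$qe
  ext <- min(ext, ns - (bl$qe + bl$diag))  # clip at subject end
  if (ext > 0L) {
    bl$mm <- bl$mm + count_mm(bl$qe + 1L, bl$qe + ext, bl$qe + 1L + bl$diag)
    bl$qe <- bl$qe + ext
  }
  blocks[[length(blocks)]] <- bl

  ## resolve inter-block query overlaps and gaps. Overlaps arise when the
  ## exon/intron junction is locally sequence-ambiguous (several spliced
  ## alignments are exact); canonical GT..AG splice dinucleotides of the
  ## implied intron break such ties, then maximal 5' exon extension.
  splice_score <- function(b, diag_left, diag_right) {
    gi_s <- b + diag_left + 1L   # first intron base
    gi_e <- b + diag_right       # last intron base
    if (gi_e - gi_s + 1L < 4L || gi_s < 1L || gi_e > ns) return(-1L)
    sum(sc[gi_s] == "G", sc[gi_s + 1L] == "T",
        sc[gi_e - 1L] == "A", sc[gi_e] == "G")
  }
  if (length(blocks) > 1L) {
    safe <- function(idx) ifelse(idx >= 1L & idx <= ns,
                                 sc[pmax(pmin(idx, ns), 1L)], "!")
    W <- k  # junction refinement window on either side
    for (i in seq_len(length(blocks) - 1L)) {
      left <- blocks[[i]]; right <- blocks[[i + 1L]]
      ## candidate junctions b (last query base of the left exon), spanning
      ## the inter-block gap or overlap plus a window into both blocks
      b_lo <- max(left$qs, min(left$qe, right$qs - 1L) - W)
      b_hi <- min(right$qe - 1L, max(left$qe, right$qs - 1L) + W)
      if (b_lo > b_hi) next
      bs <- b_lo:b_hi
      p <- (b_lo + 1L):b_hi  # positions whose side depends on b
      if (length(p) > 0L && b_lo < b_hi) {
        mmL <- qc[p] != safe(p + left$diag)
        mmR <- qc[p] != safe(p + right$diag)
        mm <- c(0L, cumsum(mmL)) + c(rev(cumsum(rev(mmR))), 0L)
      } else mm <- 0L
      sp <- vapply(bs, splice_score, integer(1), left$diag, right$diag)
      ## spliced-alignment style scoring: a canonical GT..AG junction
      ## outweighs one substitution near the boundary
      comb <- 2L * sp - 3L * mm
      b <- bs[max(which(comb == max(comb)))]
      left$qe <- b
      right$qs <- b + 1L
      left$mm <- count_mm(left$qs, left$qe, left$qs + left$diag)
      right$mm <- count_mm(right$qs, right$qe, right$qs + right$diag)
      blocks[[i]] <- left; blocks[[i + 1L]] <- right
    }
  }
  blocks <- Filter(function(b) b$qs <= b$qe, blocks)
  do.call(rbind, lapply(blocks, function(b)
    data.frame(qs = b$qs, qe = b$qe, gs = b$qs + b$diag, ge = b$qe + b$diag,
               mm = b$mm)))
}

#' Locate all allelic copies of a gene in a genome
#'
#' Searches every chromosome (both strands) for loci where the query
#' CDS/mRNA aligns with at least `min_identity` identity over at least
#' `min_query_coverage` of its length. Each qualifying locus is reported
#' exactly once as one gene copy; alignment blocks become exon intervals
#' and genome-side gaps between blocks are introns. In an allele-aware
#' autopolyploid assembly the copy number equals the number of allelic
#' chromosomes carrying the gene.
#'
#' @param query Query CDS or mRNA sequence (>= 60 bp).
#' @param genome [Biostrings::DNAStringSet], named character vector, or
#'   FASTA path.
#' @param min_identity Minimum alignment identity (default 0.90; allelic
#'   copies at ~1% divergence pass comfortably).
#' @param min_query_coverage Minimum fraction of the query aligned
#'   (default 0.80).
#' @param k Seed k-mer length for anchoring (default 15).
#' @param max_intron Maximum intron length bridged when chaining (bp).
#' @param gene_id Identifier recorded in the result.
#' @return An object of class `allele_set`: list with `gene_id`, `copies`
#'   (each a list with `chromosome`, `strand`, `exons` data frame of
#'   1-based inclusive plus-strand intervals ordered 5' to 3' on the
#'   coding strand, `cds_sequence`, `identity_to_query`) and
#'   `copy_number`. Zero hits give `copy_number = 0`, not an error.
#' @export
locate_alleles <- function(query, genome, min_identity = 0.90,
                           min_query_coverage = 0.80, k = 15L,
                           max_intron = 10000L, gene_id = "query") {
  query <- as_dna_character(query, "query")
  if (nchar(query) == 0L) stop("empty query")
  if (nchar(query) < 60L) stop("query must be at least 60 bp")
  if (min_identity <= 0 || min_identity > 1)
    stop("min_identity must be in (0, 1]")
  genome <- as_genome(genome)
  if (length(genome) == 0L) stop("empty genome")

  copies <- list()
  for (chrom in names(genome)) {
    L <- length(genome[[chrom]])
    for (strand in c("+", "-")) {
      subject <- if (strand == "+") as.character(genome[[chrom]])
                 else revcomp(as.character(genome[[chrom]]))
      anc <- kmer_anchors(query, subject, k)
      if (is.null(anc)) next
      ## cluster anchors into candidate loci by genomic proximity
      ord <- order(anc$gpos)
      gpos <- anc$gpos[ord]; qpos <- anc$qpos[ord]
      brk <- c(0L, which(diff(gpos) > max_intron), length(gpos))
      for (ci in seq_len(length(brk) - 1L)) {
        idx <- (brk[ci] + 1L):brk[ci + 1L]
        bl <- chain_blocks(list(qpos = qpos[idx], gpos = gpos[idx]),
                           query, subject, k, max_intron)
        if (is.null(bl)) next
        covered <- sum(bl$qe - bl$qs + 1L)
        identity <- 1 - sum(bl$mm) / covered
        coverage <- covered / nchar(query)
        if (identity < min_identity || coverage < min_query_coverage) next
        ## map subject-strand blocks back to plus-strand coordinates
        if (strand == "+") {
          exons <- data.frame(start = bl$gs, end = bl$ge)
        } else {
          exons <- data.frame(start = L - bl$ge + 1L, end = L - bl$gs + 1L)
        }
        cds <- paste(substring(subject, bl$gs, bl$ge), collapse = "")
        copies[[length(copies) + 1L]] <- list(
          chromosome = chrom, strand = strand, exons = exons,
          cds_sequence = cds, identity_to_query = identity,
          query_coverage = coverage)
      }
    }
  }

  ## one report per locus: drop lower-identity copies overlapping a better
  ## one on the same chromosome (e.g. palindromic double reports)
  if (length(copies) > 1L) {
    spans <- GenomicRanges::GRanges(
      vapply(copies, `[[`, character(1), "chromosome"),
      IRanges::IRanges(vapply(copies, function(x) min(x$exons$start), numeric(1)),
                       vapply(copies, function(x) max(x$exons$end), numeric(1))))
    idn <- vapply(copies, `[[`, numeric(1), "identity_to_query")
    keep <- rep(TRUE, length(copies))
    ov <- GenomicRanges::findOverlaps(spans, spans)
    for (h in seq_along(ov)) {
      i <- S4Vectors::queryHits(ov)[h]; j <- S4Vectors::subjectHits(ov)[h]
      if (i < j && keep[i] && keep[j]) {
        if (idn[j] > idn[i]) keep[i] <- FALSE else keep[j] <- FALSE
      }
    }
    copies <- copies[keep]
  }
  ## deterministic order
  if (length(copies) > 1L) {
    o <- order(vapply(copies, `[[`, character(1), "chromosome"),
               vapply(copies, function(x) min(x$exons$start), numeric(1)))
    copies <- copies[o]
  }
  structure(list(gene_id = gene_id, copies = copies,
                 copy_number = length(copies)),
            class = "allele_set")
}

#' @export
print.allele_set <- function(x, ...) {
  cat("Allele set '", x$gene_id, "': ", x$copy_number, " cop",
      if (x$copy_number == 1) "y" else "ies", "\n", sep = "")
  for (cp in x$copies)
    cat(sprintf("  %s:%d-%d (%s), %d exon(s), identity %.4f\n",
                cp$chromosome, min(cp$exons$start), max(cp$exons$end),
                cp$strand, nrow(cp$exons), cp$identity_to_query))
  invisible(x)
}

#' Genomic spans of an allele set's copies
#'
#' @param alleles An `allele_set`.
#' @return [GenomicRanges::GRanges] with one range per copy.
#' @export
allele_spans <- function(alleles) {
  stopifnot(inherits(alleles, "allele_set"))
  if (alleles$copy_number == 0L) return(GenomicRanges::GRanges())
  GenomicRanges::GRanges(
    vapply(alleles$copies, `[[`, character(1), "chromosome"),
    IRanges::IRanges(
      vapply(alleles$copies, function(x) min(x$exons$start), numeric(1)),
      vapply(alleles$copies, function(x) max(x$exons$end), numeric(1))),
    strand = vapply(alleles$copies, `[[`, character(1), "strand"))
}

#' Write an allele set as GFF3 (one gene per copy)
#'
#' @param alleles An `allele_set`.
#' @param path Output GFF3 path.
#' @return The path, invisibly.
#' @export
write_alleles_gff3 <- function(alleles, path) {
  stopifnot(inherits(alleles, "allele_set"))
  grl <- lapply(seq_along(alleles$copies), function(i) {
    cp <- alleles$copies[[i]]
    gid <- sprintf("%s.copy%d", alleles$gene_id, i)
    n <- nrow(cp$exons)
    GenomicRanges::GRanges(
      cp$chromosome,
      IRanges::IRanges(c(min(cp$exons$start), cp$exons$start),
                       c(max(cp$exons$end), cp$exons$end)),
      strand = cp$strand,
      type = c("gene", rep("exon", n)),
      ID = c(gid, sprintf("%s.exon%d", gid, seq_len(n))),
      Parent = c(NA_character_, rep(gid, n)))
  })
  export_gff3(suppressWarnings(do.call(c, grl)), path)
}

#' Copy number from read-depth ratio over a CDS
#'
#' Whole-genome sequencing reads mapped to a CDS accumulate depth
#' proportional to the number of genomic copies; the rounded ratio of
#' median CDS depth to the haploid baseline depth estimates copy number
#' (the median is robust to coverage noise).
#'
#' @param per_base_depth Numeric vector of per-base depths over the CDS.
#' @param haploid_baseline_depth Positive baseline depth of a single-copy
#'   region.
#' @return List with `copy_number` (integer) and `ratio` (unrounded).
#' @examples
#' copy_number_from_depth(rep(88, 100), 22)
#' @export
copy_number_from_depth <- function(per_base_depth, haploid_baseline_depth) {
  if (length(per_base_depth) == 0L) stop("empty depth vector")
  stopifnot_scalar_number(haploid_baseline_depth, "haploid_baseline_depth")
  if (haploid_baseline_depth <= 0) stop("baseline depth must be positive")
  ratio <- stats::median(per_base_depth) / haploid_baseline_depth
  list(copy_number = as.integer(round(ratio)), ratio = ratio)
}
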