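## Reduce whole-genome resequencing variant calls of edited plants to
## candidate Cas9-induced off-target mutations: SNVs are excluded, and
## only indels at or near the -3 position relative to the PAM (the blunt
## cut between protospacer positions 17 and 18) of a non-on-target site
## survive.

classify_variant_type <- function(ref, alt) {
  ifelse(is.na(ref) | is.na(alt) | ref == "" | alt == "" |
           grepl("[^ACGTN]", ref) | grepl("[^ACGTN]", alt), "malformed",
  ifelse(nchar(ref) == 1L & nchar(alt) == 1L, "SNV",
  ifelse(nchar(ref) > nchar(alt), "deletion",
  ifelse(nchar(ref) < nchar(alt), "insertion", "other"))))
}

#' Read variant records from a VCF
#'
#' Reads the fixed VCF columns with [vcfR::read.vcfR()] and derives the
#' variant type from the REF/ALT lengths. Multi-allelic records (comma
#' in ALT) are typed `other` and never become candidates.
#'
#' @param path VCF path (4.x, plain text or gzipped).
#' @return Data frame: `chrom`, `pos`, `ref`, `alt`, `type`
#'   (`SNV`/`insertion`/`deletion`/`other`/`malformed`), `passes_quality`
#'   (FILTER is PASS or missing).
#' @export
read_variants <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  alt <- fix$ALT
  type <- ifelse(grepl(",", alt), "other",
                 classify_variant_type(toupper(fix$REF), toupper(alt)))
  data.frame(chrom = fix$CHROM, pos = as.integer(fix$POS),
             ref = toupper(fix$REF), alt = toupper(alt), type = type,
             passes_quality = is.na(fix$FILTER) | fix$FILTER %in% c(".", "PASS"))
}

#' Filter variants down to candidate Cas9 off-target mutations
#'
#' Every input variant receives exactly one verdict. SNVs are always
#' rejected. Indels are candidates only when their inter-base position
#' (the VCF anchor base, for left-anchored indel records) lies within
#' `tolerance` bp of the cut inter-base of a non-on-target site; indels
#' near on-target sites are rejected with reason `targeted region`.
#' Coding-region overlap is annotated from CDS features.
#'
#' @param variants Data frame from [read_variants()] (or with the same
#'   columns).
#' @param sites Off-target hits with `is_on_target` filled (the `hits`
#'   component of [classify_hits()]).
#' @param annotation Optional gene annotation: a
#'   [GenomicRanges::GRanges] with a `type` column (CDS rows are used)
#'   or a GFF3 path.
#' @param tolerance Maximum |distance| in bp from the cut inter-base
#'   (default 2: "at or near" the -3 position).
#' @return Data frame of verdicts, one row per variant: the variant
#'   columns plus `matched_site`, `distance_to_minus3`,
#'   `in_coding_region`, `is_candidate`, `reason`. The tolerance used is
#'   stored in the `tolerance` attribute.
#' @export
filter_offtarget_variants <- function(variants, sites, annotation = NULL,
                                      tolerance = 2L) {
  stopifnot(is.data.frame(variants), is.data.frame(sites))
  if (nrow(sites) > 0L && any(is.na(sites$is_on_target)))
    stop("sites must carry on-target flags; run classify_hits() first")
  if (is.character(annotation))
    annotation <- rtracklayer::import(annotation)

  site_cut <- ifelse(sites$strand == "+", sites$start + 16L,
                     sites$start - 17L)  # predict_cut_site(), vectorized

  n <- nrow(variants)
  matched <- rep(NA_character_, n)
  dist <- rep(NA_integer_, n)
  cand <- rep(FALSE, n)
  reason <- rep("", n)
  for (i in seq_len(n)) {
    v <- variants[i, ]
    if (is.na(v$pos) || v$type == "malformed") {
      reason[i] <- "malformed record"; next
    }
    if (v$type == "SNV") { reason[i] <- "SNV excluded"; next }
    if (v$type == "other") { reason[i] <- "not a simple indel"; next }
    if (!isTRUE(v$passes_quality)) { reason[i] <- "failed quality filter"; next }
    same <- which(sites$chrom == v$chrom)
    if (length(same) == 0L) { reason[i] <- "no off-target site nearby"; next }
    gap <- v$pos  # inter-base position after the VCF anchor base
    d <- ifelse(sites$strand[same] == "+", gap - site_cut[same],
                site_cut[same] - gap)
    near <- which(abs(d) <= tolerance)
    if (length(near) == 0L) { reason[i] <- "no off-target site nearby"; next }
    near <- near[order(abs(d[near]))]
    off_near <- near[!sites$is_on_target[same[near]]]
    if (length(off_near) == 0L) { reason[i] <- "targeted region"; next }
    j <- same[off_near[1]]
    matched[i] <- sprintf("%s:%d(%s)", sites$chrom[j], sites$start[j],
                          sites$strand[j])
    dist[i] <- d[off_near[1]]
    cand[i] <- TRUE
    reason[i] <- "indel near cut of off-target site"
  }

  in_cds <- rep(NA, n)
  if (!is.null(annotation)) {
    cds <- annotation[S4Vectors::mcols(annotation)$type %in% c("CDS", "cds")]
    if (length(cds) > 0L && n > 0L) {
      span_end <- ifelse(is.na(variants$pos), 1L,
                         variants$pos + pmax(nchar(variants$ref) - 1L, 0L))
      q <- GenomicRanges::GRanges(variants$chrom,
                                  IRanges::IRanges(
                                    ifelse(is.na(variants$pos), 1L, variants$pos),
                                    span_end))
      in_cds <- IRanges::overlapsAny(q, cds, ignore.strand = TRUE)
      in_cds[is.na(variants$pos)] <- NA
    } else in_cds <- rep(FALSE, n)
  }

  out <- cbind(variants,
               data.frame(matched_site = matched, distance_to_minus3 = dist,
                          in_coding_region = in_cds, is_candidate = cand,
                          reason = reason))
  rownames(out) <- NULL
  attr(out, "tolerance") <- as.integer(tolerance)
  out
}

#' Count candidate off-target mutations in protein-coding regions
#'
#' The headline safety readout of an editing experiment: how many
#' candidate Cas9-induced off-target indels fall inside protein-coding
#' sequence.
#'
#' @param verdicts Result of [filter_offtarget_variants()] (with an
#'   annotation supplied).
#' @param annotation Optional [GenomicRanges::GRanges] of gene features
#'   (rows with `type == "gene"`) for a per-gene breakdown.
#' @return List with `n_coding_candidates` (integer) and `per_gene`
#'   (data frame `gene`, `n`; empty without an annotation).
#' @export
summarize_coding_offtargets <- function(verdicts, annotation = NULL) {
  hit <- verdicts$is_candidate & !is.na(verdicts$in_coding_region) &
    verdicts$in_coding_region
  per_gene <- data.frame(gene = character(0), n = integer(0))
  if (!is.null(annotation) && any(hit)) {
    if (is.character(annotation)) annotation <- rtracklayer::import(annotation)
    genes <- annotation[S4Vectors::mcols(annotation)$type == "gene"]
    if (length(genes) > 0L) {
      q <- GenomicRanges::GRanges(verdicts$chrom[hit],
                                  IRanges::IRanges(verdicts$pos[hit],
                                                   verdicts$pos[hit]))
      ov <- GenomicRanges::findOverlaps(q, genes, ignore.strand = TRUE)
      ids <- S4Vectors::mcols(genes)$ID[S4Vectors::subjectHits(ov)]
      if (length(ids) > 0L) {
        tab <- table(ids)
        per_gene <- data.frame(gene = names(tab), n = as.integer(tab))
      }
    }
  }
  list(n_coding_candidates = sum(hit), per_gene = per_gene)
}

#' Write a minimal VCF for simulated variant calls
#'
#' Emits VCF 4.2 text from a variant data frame so fixture variant sets
#' can round-trip through [read_variants()]. Fixture plumbing, not a
#' general-purpose VCF writer.
#'
#' @param variants Data frame with `chrom`, `pos`, `ref`, `alt` (and
#'   optionally `filter`).
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_simple_vcf <- function(variants, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
  filt <- if (is.null(variants$filter)) rep("PASS", nrow(variants))
          else variants$filter
  if (nrow(variants) > 0L)
    writeLines(sprintf("%s\t%d\t.\t%s\t%s\t100\t%s\t.", variants$chrom,
                       variants$pos, variants$ref, variants$alt, filt), con)
  invisible(path)
}
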