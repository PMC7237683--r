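## Synthetic autotetraploid fixtures: seeded genomes with allelic gene
## copies, planted guide/decoy/enzyme sites, and simulated edited clone
## sets. Every downstream module is testable against the emitted truth
## tables without any external data.

#' Specification for a synthetic autopolyploid genome fixture
#'
#' Describes a deterministic synthetic genome: `n_chromosome_groups`
#' homologous groups, each with `ploidy` allelic chromosome copies that
#' differ by `allelic_divergence` substitutions per site (the realized
#' divergence between any two copies; each copy is mutated at half that
#' rate from a common ancestor). A target gene (exons, introns, embedded
#' protospacer + PAM) is planted identically in every copy; mismatched
#' protospacer decoys and restriction-enzyme recognition sites are planted
#' at recorded coordinates.
#'
#' @param seed Integer seed; the same seed and spec produce byte-identical
#'   output files.
#' @param n_chromosome_groups Number of homologous chromosome groups.
#' @param ploidy Number of allelic copies per group (4 for an
#'   autotetraploid).
#' @param chromosome_length Length of each chromosome in bp.
#' @param allelic_divergence Expected substitutions per site between any
#'   two allelic copies, in `[0, 1)`. Default `1e-4`; allele-aware
#'   assemblies of autotetraploids show allelic divergence up to ~0.01.
#' @param target_gene List describing the planted gene:
#'   `exon_lengths` (integer vector), `intron_lengths` (integer vector of
#'   length `length(exon_lengths) - 1`, recycled), `protospacer` (20-nt
#'   character), `pam` (3-nt, default `"CGG"`), `protospacer_exon` (which
#'   exon carries the protospacer, default 1).
#' @param gene_divergence Expected substitutions per site between allelic
#'   copies *within the target gene* (default 0: the gene is embedded
#'   identically in every copy). The protospacer + PAM and the intron
#'   splice dinucleotides are never mutated, so planted guide sites stay
#'   exact while exon bodies and boundaries diverge.
#' @param decoy_sites Data frame with columns `mismatches` (integer) and
#'   `pam_kind` (`"NGG"` or `"NAG"`): protospacer-like sites planted on the
#'   first allelic copy of each group, each carrying exactly that many
#'   mismatches to the planted protospacer.
#' @param enzyme_sites Data frame with columns `name`, `recognition_site`
#'   and `offset` placing each recognition sequence relative to the
#'   predicted Cas9 cut: the site's first base sits at
#'   `cut + 1 + offset` (offset `-2` centres a 4-bp site on the cut).
#'   Sites overlapping the protospacer must agree with its bases.
#' @return An object of class `fixture_spec`.
#' @seealso [generate_genome()]
#' @export
fixture_spec <- function(seed,
                         n_chromosome_groups = 1L,
                         ploidy = 4L,
                         chromosome_length = 20000L,
                         allelic_divergence = 1e-4,
                         gene_divergence = 0,
                         target_gene = list(exon_lengths = c(300L, 400L),
                                            intron_lengths = 150L,
                                            protospacer = NULL,
                                            pam = "CGG",
                                            protospacer_exon = 1L),
                         decoy_sites = NULL,
                         enzyme_sites = NULL) {
  stopifnot_scalar_number(seed, "seed")
  if (ploidy < 1L) stop("'ploidy' must be >= 1")
  if (allelic_divergence < 0 || allelic_divergence >= 1)
    stop("'allelic_divergence' must be in [0, 1)")
  tg <- target_gene
  if (is.null(tg$exon_lengths)) stop("target_gene$exon_lengths is required")
  if (is.null(tg$pam)) tg$pam <- "CGG"
  if (is.null(tg[["protospacer_exon"]])) tg[["protospacer_exon"]] <- 1L
  if (length(tg$exon_lengths) > 1L && is.null(tg$intron_lengths))
    tg$intron_lengths <- 150L
  if (length(tg$exon_lengths) > 1L)
    tg$intron_lengths <- rep_len(tg$intron_lengths, length(tg$exon_lengths) - 1L)
  else tg$intron_lengths <- integer(0)
  if (!is.null(tg[["protospacer"]])) {
    tg[["protospacer"]] <- as_dna_character(tg[["protospacer"]], "protospacer")
    if (!grepl("^[ACGT]+$", tg[["protospacer"]]))
      stop("protospacer must contain only A/C/G/T")
    plen <- nchar(tg[["protospacer"]]) + nchar(tg$pam)
    if (plen > tg$exon_lengths[tg[["protospacer_exon"]]])
      stop("protospacer + PAM does not fit in its exon: sizing error")
  }
  if (!is.null(decoy_sites)) {
    decoy_sites <- as.data.frame(decoy_sites)
    stopifnot(all(c("mismatches", "pam_kind") %in% names(decoy_sites)))
    if (is.null(tg[["protospacer"]]))
      stop("decoy_sites require target_gene$protospacer")
    if (any(decoy_sites$mismatches > nchar(tg[["protospacer"]])))
      stop("decoy mismatch count exceeds guide length")
    if (!all(decoy_sites$pam_kind %in% c("NGG", "NAG")))
      stop("decoy pam_kind must be NGG or NAG")
  }
  if (!is.null(enzyme_sites)) {
    enzyme_sites <- as.data.frame(enzyme_sites)
    stopifnot(all(c("name", "recognition_site", "offset") %in% names(enzyme_sites)))
  }
  gene_len <- sum(tg$exon_lengths) + sum(tg$intron_lengths)
  if (gene_len > floor(chromosome_length * 0.35))
    stop("target gene (", gene_len, " bp) does not fit in chromosome_length ",
         chromosome_length, ": sizing error")
  structure(list(seed = as.integer(seed),
                 n_chromosome_groups = as.integer(n_chromosome_groups),
                 ploidy = as.integer(ploidy),
                 chromosome_length = as.integer(chromosome_length),
                 allelic_divergence = allelic_divergence,
                 gene_divergence = gene_divergence,
                 target_gene = tg,
                 decoy_sites = decoy_sites,
                 enzyme_sites = enzyme_sites),
            class = "fixture_spec")
}

## Build the gene sequence and its internal feature map (1-based offsets
## within the gene).
build_gene <- function(tg) {
  n_ex <- length(tg$exon_lengths)
  exons <- vapply(tg$exon_lengths, random_dna, character(1))
  proto_local <- NULL
  if (!is.null(tg[["protospacer"]])) {
    site <- paste0(tg[["protospacer"]], tg$pam)
    ex <- tg[["protospacer_exon"]]
    off <- max(1L, (tg$exon_lengths[ex] - nchar(site)) %/% 2L)
    substr(exons[ex], off, off + nchar(site) - 1L) <- site
    proto_local <- list(exon = ex, offset = off)
  }
  ## canonical GT..AG splice sites so exon/intron boundaries are
  ## resolvable even when junction sequence is locally ambiguous
  introns <- vapply(tg$intron_lengths, function(n) {
    if (n < 4L) stop("intron lengths must be at least 4 bp")
    s <- random_dna(n)
    substr(s, 1L, 2L) <- "GT"
    substr(s, n - 1L, n) <- "AG"
    s
  }, character(1))
  pieces <- character(0)
  exon_start <- integer(n_ex)
  pos <- 1L
  for (i in seq_len(n_ex)) {
    exon_start[i] <- pos
    pieces <- c(pieces, exons[i])
    pos <- pos + tg$exon_lengths[i]
    if (i < n_ex) {
      pieces <- c(pieces, introns[i])
      pos <- pos + tg$intron_lengths[i]
    }
  }
  list(seq = paste(pieces, collapse = ""), exon_start = exon_start,
       exon_seqs = exons, proto_local = proto_local)
}

## Mutate a decoy from the protospacer: exactly m mismatches at distinct
## positions, plus a realized PAM of the requested kind.
make_decoy <- function(protospacer, m, pam_kind) {
  b <- strsplit(protospacer, "")[[1]]
  if (m > 0) {
    pos <- sample(length(b), m)
    for (p in pos) b[p] <- sample(setdiff(DNA_BASES4, b[p]), 1)
  }
  pam <- paste0(sample(DNA_BASES4, 1),
                if (pam_kind == "NGG") "GG" else "AG")
  paste0(paste(b, collapse = ""), pam)
}

## Substitute a fraction `rate` of positions within [from, to], sparing
## `protect` (IRanges in the same coordinates).
diverge_region <- function(seq, rate, from, to, protect) {
  if (rate <= 0) return(seq)
  w <- to - from + 1L
  n_mut <- rbinom(1, w, rate)
  if (n_mut == 0) return(seq)
  pos <- from - 1L + sample.int(w, n_mut)
  if (length(protect) > 0) {
    keep <- !IRanges::overlapsAny(IRanges::IRanges(pos, pos), protect)
    pos <- pos[keep]
  }
  b <- strsplit(seq, "")[[1]]
  for (p in pos) b[p] <- sample(setdiff(DNA_BASES4, b[p]), 1)
  paste(b, collapse = "")
}

#' Generate a synthetic autopolyploid genome with truth table
#'
#' Emits one chromosome per (group, allele) pair, named `chr<g>.<a>`. The
#' target gene is embedded identically in every allelic copy; background
#' sequence diverges between copies at the specified rate. Decoy
#' protospacer sites are planted on allele 1 of each group, spaced more
#' than twice the guide length apart from each other and from the real
#' target. The truth table records every planted feature with 1-based
#' inclusive coordinates and strand.
#'
#' @param spec A [fixture_spec()].
#' @param out_dir Optional directory; if given, writes `genome.fa` (60-column
#'   FASTA), `genes.gff3` and `truth.tsv` there.
#' @return A list with elements `genome` ([Biostrings::DNAStringSet]),
#'   `annotation` ([GenomicRanges::GRanges] with gene/mRNA/exon/CDS rows),
#'   `truth` (data frame: `chrom`, `start`, `end`, `strand`, `type`,
#'   `name`, `sequence`, `mismatches`, `pam`), and `spec`.
#' @examples
#' spec <- fixture_spec(seed = 1, chromosome_length = 5000,
#'                      target_gene = list(exon_lengths = 400,
#'                                         protospacer = "GGAGACGAGCACGGTCGCGG"))
#' fx <- generate_genome(spec)
#' names(fx$genome)
#' @export
generate_genome <- function(spec, out_dir = NULL) {
  stopifnot(inherits(spec, "fixture_spec"))
  with_seed(spec$seed, {
    tg <- spec$target_gene
    L <- spec$chromosome_length
    seqs <- list()
    truth <- list()
    ann <- list()
    for (g in seq_len(spec$n_chromosome_groups)) {
      gene <- build_gene(tg)
      gene_len <- nchar(gene$seq)
      g0 <- max(1L, floor(L * 0.25))
      ancestor <- random_dna(L)
      substr(ancestor, g0, g0 + gene_len - 1L) <- gene$seq

      protect <- IRanges::IRanges(g0, g0 + gene_len - 1L)
      gene_id <- sprintf("gene%d", g)

      ## per-feature genomic offsets (same on every allele)
      exon_iv <- IRanges::IRanges(g0 + gene$exon_start - 1L,
                                  width = tg$exon_lengths)
      proto_iv <- NULL
      cut_after <- NA_integer_
      if (!is.null(gene$proto_local)) {
        ps <- g0 + gene$exon_start[gene$proto_local$exon] - 1L +
          gene$proto_local$offset - 1L
        proto_iv <- IRanges::IRanges(ps, width = nchar(tg[["protospacer"]]))
        cut_after <- ps + 16L  # blunt cut between protospacer pos 17|18
      }

      ## enzyme recognition sites relative to the cut
      if (!is.null(spec$enzyme_sites)) {
        if (is.na(cut_after)) stop("enzyme_sites require a protospacer")
        for (i in seq_len(nrow(spec$enzyme_sites))) {
          es <- spec$enzyme_sites[i, ]
          s0 <- cut_after + 1L + es$offset
          old <- substr(ancestor, s0, s0 + nchar(es$recognition_site) - 1L)
          new_anc <- ancestor
          substr(new_anc, s0, s0 + nchar(es$recognition_site) - 1L) <-
            toupper(es$recognition_site)
          ## planting must not alter the protospacer+PAM itself
          pp <- substr(new_anc, IRanges::start(proto_iv),
                       IRanges::start(proto_iv) + nchar(tg[["protospacer"]]) + 2L)
          if (pp != paste0(tg[["protospacer"]], tg$pam))
            stop("enzyme site '", es$name, "' conflicts with the planted protospacer")
          ancestor <- new_anc
          truth[[length(truth) + 1L]] <- lapply(seq_len(spec$ploidy), function(a)
            data.frame(chrom = sprintf("chr%d.%d", g, a),
                       start = s0, end = s0 + nchar(es$recognition_site) - 1L,
                       strand = "+", type = "enzyme_site", name = es$name,
                       sequence = toupper(es$recognition_site),
                       mismatches = NA_integer_, pam = NA_character_))
        }
      }

      ## allelic copies; decoys planted on allele 1 after divergence
      decoy_rows <- NULL
      ## within-gene protection for gene_divergence: guide site and
      ## splice dinucleotides stay exact
      gene_keep <- IRanges::IRanges()
      if (!is.null(proto_iv))
        gene_keep <- IRanges::IRanges(IRanges::start(proto_iv),
                                      IRanges::end(proto_iv) + 3L)
      if (length(exon_iv) > 1L) {
        is_ <- IRanges::end(exon_iv)[-length(exon_iv)] + 1L
        ie_ <- IRanges::start(exon_iv)[-1L] - 1L
        gene_keep <- c(gene_keep, IRanges::IRanges(is_, is_ + 1L),
                       IRanges::IRanges(ie_ - 1L, ie_))
      }

      for (a in seq_len(spec$ploidy)) {
        chrom <- sprintf("chr%d.%d", g, a)
        s <- diverge_region(ancestor, spec$allelic_divergence / 2, 1L, L,
                            protect)
        if (spec$gene_divergence > 0)
          s <- diverge_region(s, spec$gene_divergence / 2, g0,
                              g0 + gene_len - 1L, gene_keep)
        if (a == 1L && !is.null(spec$decoy_sites)) {
          d0 <- floor(L * 0.6)
          stride <- max(200L, 3L * (nchar(tg[["protospacer"]]) + 3L))
          if (d0 + nrow(spec$decoy_sites) * stride > L)
            stop("decoy sites do not fit in chromosome_length: sizing error")
          rows <- list()
          for (i in seq_len(nrow(spec$decoy_sites))) {
            ds <- spec$decoy_sites[i, ]
            dseq <- make_decoy(tg[["protospacer"]], ds$mismatches, ds$pam_kind)
            p0 <- d0 + (i - 1L) * stride
            substr(s, p0, p0 + nchar(dseq) - 1L) <- dseq
            rows[[i]] <- data.frame(chrom = chrom, start = p0,
                                    end = p0 + nchar(tg[["protospacer"]]) - 1L,
                                    strand = "+", type = "decoy",
                                    name = sprintf("decoy%d_%d", g, i),
                                    sequence = substr(dseq, 1, nchar(tg[["protospacer"]])),
                                    mismatches = ds$mismatches,
                                    pam = substr(dseq, nchar(tg[["protospacer"]]) + 1L,
                                                 nchar(dseq)))
          }
          decoy_rows <- do.call(rbind, rows)
        }
        seqs[[chrom]] <- s

        truth[[length(truth) + 1L]] <- data.frame(
          chrom = chrom, start = g0, end = g0 + gene_len - 1L, strand = "+",
          type = "gene", name = gene_id, sequence = NA_character_,
          mismatches = NA_integer_, pam = NA_character_)
        truth[[length(truth) + 1L]] <- data.frame(
          chrom = chrom, start = IRanges::start(exon_iv),
          end = IRanges::end(exon_iv), strand = "+", type = "exon",
          name = sprintf("%s.exon%d", gene_id, seq_along(exon_iv)),
          sequence = NA_character_, mismatches = NA_integer_,
          pam = NA_character_)
        if (!is.null(proto_iv))
          truth[[length(truth) + 1L]] <- data.frame(
            chrom = chrom, start = IRanges::start(proto_iv),
            end = IRanges::end(proto_iv), strand = "+", type = "protospacer",
            name = sprintf("%s.guide", gene_id),
            sequence = tg[["protospacer"]], mismatches = 0L, pam = tg$pam)

        tid <- sprintf("%s.%s.t1", gene_id, chrom)
        gid <- sprintf("%s.%s", gene_id, chrom)
        cds_phase <- (3L - cumsum(c(0L, tg$exon_lengths))[seq_along(exon_iv)] %% 3L) %% 3L
        ann[[length(ann) + 1L]] <- GenomicRanges::GRanges(
          chrom,
          IRanges::IRanges(c(g0, g0, IRanges::start(exon_iv), IRanges::start(exon_iv)),
                           c(g0 + gene_len - 1L, g0 + gene_len - 1L,
                             IRanges::end(exon_iv), IRanges::end(exon_iv))),
          strand = "+",
          type = c("gene", "mRNA", rep("exon", length(exon_iv)),
                   rep("CDS", length(exon_iv))),
          ID = c(gid, tid,
                 sprintf("%s.exon%d", tid, seq_along(exon_iv)),
                 sprintf("%s.cds%d", tid, seq_along(exon_iv))),
          Parent = c(NA_character_, gid, rep(tid, 2L * length(exon_iv))),
          phase = c(rep(NA_integer_, 2L + length(exon_iv)), cds_phase))
      }
      if (!is.null(decoy_rows)) truth[[length(truth) + 1L]] <- decoy_rows
    }

    truth <- do.call(rbind, lapply(truth, function(x)
      if (is.list(x) && !is.data.frame(x)) do.call(rbind, x) else x))
    truth <- truth[order(truth$chrom, truth$start, truth$type), ]
    rownames(truth) <- NULL
    genome <- Biostrings::DNAStringSet(unlist(seqs))
    annotation <- suppressWarnings(do.call(c, ann))

    if (!is.null(out_dir)) {
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      Biostrings::writeXStringSet(genome, file.path(out_dir, "genome.fa"),
                                  width = 60L)
      export_gff3(annotation, file.path(out_dir, "genes.gff3"))
      write.table(truth, file.path(out_dir, "truth.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
    }
    list(genome = genome, annotation = annotation, truth = truth, spec = spec)
  })
}

export_gff3 <- function(gr, path) {
  ## rtracklayer expects Parent as a CharacterList
  p <- S4Vectors::mcols(gr)$Parent
  S4Vectors::mcols(gr)$Parent <- IRanges::CharacterList(
    lapply(p, function(x) if (is.na(x)) character(0) else x))
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Specification of a simulated edited clone set
#'
#' Describes the Sanger-clone sampling of a single edited plant: each
#' allele carries one edit (or is wild type), clones are drawn from the
#' alleles in the given proportions, and `chimera_extra_types` additional
#' distinct mutation types can be injected to emulate chimeric plants
#' whose cellular genotypes are not uniform.
#'
#' @param n_clones Number of clones to emit (Sanger screens typically
#'   sample 20-30 clones per plant).
#' @param allele_edits Named list, one entry per allele. Each entry is one
#'   of `list(type = "wt")`, `list(type = "del", length = , offset = 0)`,
#'   `list(type = "ins", seq = , offset = 0)` or
#'   `list(type = "sub", to = , offset = )`. Offsets are bp relative to
#'   the Cas9 cut inter-base (0 = at the cut; negative = PAM-distal).
#' @param chimera_extra_types Number of additional distinct deletion types
#'   to inject beyond the allelic edits.
#' @param sampling_proportions Numeric vector (one per allele) summing to
#'   1; equal by default.
#' @param seed Integer seed for the clone-to-allele assignment.
#' @return An object of class `clone_set_spec`.
#' @export
clone_set_spec <- function(n_clones = 30L, allele_edits,
                           chimera_extra_types = 0L,
                           sampling_proportions = NULL, seed = 1L) {
  stopifnot(is.list(allele_edits), length(allele_edits) >= 1L)
  if (is.null(sampling_proportions))
    sampling_proportions <- rep(1 / length(allele_edits), length(allele_edits))
  if (abs(sum(sampling_proportions) - 1) > 1e-8)
    stop("sampling_proportions must sum to 1")
  if (length(sampling_proportions) != length(allele_edits))
    stop("one sampling proportion per allele is required")
  if (is.null(names(allele_edits)))
    names(allele_edits) <- paste0("allele", seq_along(allele_edits))
  structure(list(n_clones = as.integer(n_clones),
                 allele_edits = allele_edits,
                 chimera_extra_types = as.integer(chimera_extra_types),
                 sampling_proportions = sampling_proportions,
                 seed = as.integer(seed)),
            class = "clone_set_spec")
}

## Apply one edit to an amplicon. `cut_after` is the 1-based index of the
## last base 5' of the blunt cut on the protospacer strand.
apply_edit <- function(amplicon, edit, cut_after) {
  n <- nchar(amplicon)
  switch(edit$type,
    wt = amplicon,
    del = {
      off <- if (is.null(edit$offset)) 0L else edit$offset
      e <- cut_after + off
      s <- e - edit$length + 1L
      if (s < 1L || e > n) stop("edit outside amplicon")
      paste0(substr(amplicon, 1L, s - 1L), substr(amplicon, e + 1L, n))
    },
    ins = {
      off <- if (is.null(edit$offset)) 0L else edit$offset
      p <- cut_after + off
      if (p < 0L || p > n) stop("edit outside amplicon")
      paste0(substr(amplicon, 1L, p), toupper(edit$seq),
             substr(amplicon, p + 1L, n))
    },
    sub = {
      off <- if (is.null(edit$offset)) 0L else edit$offset
      p <- cut_after + off
      if (p < 1L || p > n) stop("edit outside amplicon")
      ref_base <- substr(amplicon, p, p)
      if (toupper(edit$to) == ref_base)
        stop("substitution 'to' equals the reference base")
      substr(amplicon, p, p) <- toupper(edit$to)
      amplicon
    },
    stop("unknown edit type: ", edit$type))
}

#' Generate a simulated edited clone set
#'
#' Applies the per-allele edits of a [clone_set_spec()] around the Cas9
#' cut site in the reference amplicon and samples clones from the alleles
#' (plus any injected chimeric types). The truth labels record each
#' clone's allele of origin and mutation type.
#'
#' @param spec A [clone_set_spec()].
#' @param reference_amplicon Character or DNAString: the wild-type
#'   amplicon; must contain `protospacer` followed by an NGG PAM.
#' @param protospacer 20-nt protospacer defining the cut position
#'   (between protospacer bases 17 and 18).
#' @param out_dir Optional directory; writes `clones.fa` and `labels.tsv`.
#' @return List with `clones` (named character vector of clone sequences),
#'   `labels` (data frame: `clone_id`, `origin`, `edit_type`, `is_wt`) and
#'   `cut_after` (1-based amplicon index of the base 5' of the cut).
#' @export
generate_clone_set <- function(spec, reference_amplicon, protospacer,
                               out_dir = NULL) {
  stopifnot(inherits(spec, "clone_set_spec"))
  amp <- as_dna_character(reference_amplicon, "reference_amplicon")
  protospacer <- as_dna_character(protospacer, "protospacer")
  hit <- regexpr(protospacer, amp, fixed = TRUE)
  if (hit < 0) stop("reference amplicon does not contain the protospacer")
  pam <- substr(amp, hit + nchar(protospacer), hit + nchar(protospacer) + 2L)
  if (!grepl("^[ACGT]GG$", pam))
    stop("protospacer in amplicon is not followed by an NGG PAM")
  cut_after <- as.integer(hit) + 16L

  with_seed(spec$seed, {
    n_all <- length(spec$allele_edits)
    ## deterministic allocation: floor + largest remainders
    raw <- spec$sampling_proportions * spec$n_clones
    cnt <- floor(raw)
    rem <- spec$n_clones - sum(cnt)
    if (rem > 0) {
      ord <- order(raw - cnt, decreasing = TRUE)
      cnt[ord[seq_len(rem)]] <- cnt[ord[seq_len(rem)]] + 1L
    }
    ## every allele observed at least once when possible
    while (any(cnt == 0L) && any(cnt > 1L) && spec$n_clones >= n_all) {
      i <- which.max(cnt); j <- which(cnt == 0L)[1]
      cnt[i] <- cnt[i] - 1L; cnt[j] <- cnt[j] + 1L
    }
    origin <- rep(names(spec$allele_edits), cnt)

    ## chimeric extra types displace clones from the most-sampled alleles
    extra_edits <- list()
    if (spec$chimera_extra_types > 0L) {
      used_del <- vapply(spec$allele_edits, function(e)
        if (identical(e$type, "del")) e$length else 0L, numeric(1))
      base_len <- max(c(used_del, 0)) + 1L
      for (k in seq_len(spec$chimera_extra_types)) {
        nm <- sprintf("chimera%d", k)
        extra_edits[[nm]] <- list(type = "del", length = base_len + k - 1L,
                                  offset = 0L)
        i <- which.max(table(origin)[unique(origin)])
        victim <- which(origin == names(i))[1]
        origin[victim] <- nm
      }
    }
    edits <- c(spec$allele_edits, extra_edits)
    origin <- sample(origin)  # shuffle clone order

    seqs <- vapply(origin, function(o) apply_edit(amp, edits[[o]], cut_after),
                   character(1))
    ids <- sprintf("clone%02d", seq_along(seqs))
    names(seqs) <- ids
    sig <- vapply(origin, function(o) edit_signature(edits[[o]]), character(1))
    labels <- data.frame(clone_id = ids, origin = origin, edit_type = sig,
                         is_wt = sig == "wt", row.names = NULL)

    if (!is.null(out_dir)) {
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs),
                                  file.path(out_dir, "clones.fa"), width = 60L)
      write.table(labels, file.path(out_dir, "labels.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
    }
    list(clones = seqs, labels = labels, cut_after = cut_after)
  })
}

edit_signature <- function(edit) {
  switch(edit$type,
    wt = "wt",
    del = sprintf("del%d@%d", edit$length,
                  if (is.null(edit$offset)) 0L else edit$offset),
    ins = sprintf("ins%s@%d", toupper(edit$seq),
                  if (is.null(edit$offset)) 0L else edit$offset),
    sub = sprintf("sub%s@%d", toupper(edit$to),
                  if (is.null(edit$offset)) 0L else edit$offset))
}
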