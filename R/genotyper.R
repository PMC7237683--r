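## Clone-based genotyping of edited plants. Each Sanger-sequenced clone
## of the target amplicon is aligned globally against the wild-type
## reference; edits inside a window around the Cas9 cut become the
## clone's mutation signature. A plant's clones are then summarised into
## wild-type / partial / null / chimeric calls, and mutagenesis
## frequencies are computed as mutants per transformed callus.

## Parse one global alignment into edit events in reference coordinates.
alignment_events <- function(aligned_clone, aligned_ref) {
  pc <- strsplit(aligned_clone, "")[[1]]
  pr <- strsplit(aligned_ref, "")[[1]]
  events <- list()
  rpos <- 0L
  i <- 1L
  n <- length(pc)
  while (i <= n) {
    if (pr[i] == "-") {            # insertion in the clone
      j <- i
      while (j < n && pr[j + 1L] == "-") j <- j + 1L
      events[[length(events) + 1L]] <- list(
        type = "ins", seq = paste(pc[i:j], collapse = ""), ref_gap = rpos)
      i <- j + 1L
    } else if (pc[i] == "-") {     # deletion from the reference
      j <- i
      while (j < n && pc[j + 1L] == "-" && pr[j + 1L] != "-") j <- j + 1L
      events[[length(events) + 1L]] <- list(
        type = "del", ref_start = rpos + 1L, ref_end = rpos + (j - i + 1L))
      rpos <- rpos + (j - i + 1L)
      i <- j + 1L
    } else {
      rpos <- rpos + 1L
      if (pc[i] != pr[i])
        events[[length(events) + 1L]] <- list(
          type = "sub", ref_pos = rpos, from = pr[i], to = pc[i])
      i <- i + 1L
    }
  }
  events
}

## Position of an event relative to the cut inter-base (0 = at/spanning
## the cut; negative = 5' of the cut, i.e. PAM-distal for a plus-strand
## guide).
event_rel_position <- function(ev, cut_after) {
  switch(ev$type,
    ins = ev$ref_gap - cut_after,
    del = {
      if (ev$ref_start - 1L <= cut_after && cut_after <= ev$ref_end) 0L
      else if (ev$ref_end < cut_after) ev$ref_end - cut_after
      else (ev$ref_start - 1L) - cut_after
    },
    sub = ev$ref_pos - cut_after)
}

event_signature <- function(ev, rel) {
  switch(ev$type,
    ins = sprintf("ins%s@%d", ev$seq, rel),
    del = sprintf("del%d@%d", ev$ref_end - ev$ref_start + 1L, rel),
    sub = sprintf("sub%s@%d", ev$to, rel))
}

#' Call the mutation type of one amplicon clone
#'
#' Globally aligns the clone against the wild-type reference amplicon
#' (affine gaps; match 2, mismatch -3, gap open 5, gap extend 1) and
#' extracts edits within `window` bp of the Cas9 cut. Edits outside the
#' window are treated as PCR/sequencing noise and ignored. Clones whose
#' alignment identity falls below 70% are flagged unalignable.
#'
#' Positions are bp relative to the cut inter-base on the protospacer
#' strand: 0 means the edit sits at (or spans) the cut, negative values
#' are PAM-distal. The reference amplicon is assumed oriented with the
#' protospacer on its plus strand.
#'
#' @param clone_seq Clone sequence (character or DNAString).
#' @param reference_amplicon Wild-type amplicon sequence.
#' @param cut_after 1-based reference index of the base 5' of the blunt
#'   cut. Supply either this or `protospacer`.
#' @param protospacer 20-nt guide used to locate the cut in the
#'   reference.
#' @param window Half-width (bp) of the edit-calling window around the
#'   cut (default 20; CRISPR indels cluster at the cut).
#' @return List of class `clone_call`: `signature` (`"wt"`, e.g.
#'   `"del2@0"`, or `"complex:..."` for multiple events), `events`,
#'   `identity`, `unalignable`.
#' @export
call_clone <- function(clone_seq, reference_amplicon, cut_after = NULL,
                       protospacer = NULL, window = 20L) {
  clone_seq <- as_dna_character(clone_seq, "clone_seq")
  ref <- as_dna_character(reference_amplicon, "reference_amplicon")
  if (is.null(cut_after)) {
    if (is.null(protospacer))
      stop("supply 'cut_after' or 'protospacer'")
    protospacer <- as_dna_character(protospacer, "protospacer")
    hit <- regexpr(protospacer, ref, fixed = TRUE)
    if (hit < 0) stop("reference amplicon does not contain the protospacer")
    cut_after <- as.integer(hit) + 16L
  }
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(clone_seq), Biostrings::DNAString(ref),
    type = "global",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = 2, mismatch = -3, baseOnly = FALSE),
    gapOpening = 5, gapExtension = 1)
  identity <- Biostrings::pid(aln) / 100
  if (identity < 0.70)
    return(structure(list(signature = NA_character_, events = list(),
                          identity = identity, unalignable = TRUE),
                     class = "clone_call"))
  evs <- alignment_events(as.character(Biostrings::alignedPattern(aln)),
                          as.character(Biostrings::alignedSubject(aln)))
  kept <- list()
  for (ev in evs) {
    rel <- event_rel_position(ev, cut_after)
    if (abs(rel) <= window)
      kept[[length(kept) + 1L]] <- c(ev, list(rel = rel,
                                              signature = event_signature(ev, rel)))
  }
  sig <- if (length(kept) == 0L) "wt"
         else if (length(kept) == 1L) kept[[1L]]$signature
         else paste0("complex:", paste(vapply(kept, `[[`, character(1),
                                              "signature"), collapse = "+"))
  structure(list(signature = sig, events = kept, identity = identity,
                 unalignable = FALSE),
            class = "clone_call")
}

#' Call mutation types for a set of clones
#'
#' @param clones Named character vector or [Biostrings::DNAStringSet] of
#'   clone sequences, or a FASTA path.
#' @inheritParams call_clone
#' @return Data frame: `clone_id`, `signature`, `n_events`, `identity`,
#'   `unalignable`.
#' @export
call_clones <- function(clones, reference_amplicon, cut_after = NULL,
                        protospacer = NULL, window = 20L) {
  if (is.character(clones) && length(clones) == 1L && file.exists(clones))
    clones <- Biostrings::readDNAStringSet(clones)
  if (is(clones, "DNAStringSet")) clones <- as.character(clones)
  if (is.null(names(clones))) names(clones) <- paste0("clone", seq_along(clones))
  calls <- lapply(clones, call_clone, reference_amplicon = reference_amplicon,
                  cut_after = cut_after, protospacer = protospacer,
                  window = window)
  data.frame(clone_id = names(clones),
             signature = vapply(calls, `[[`, character(1), "signature"),
             n_events = vapply(calls, function(x) length(x$events), integer(1)),
             identity = vapply(calls, `[[`, numeric(1), "identity"),
             unalignable = vapply(calls, `[[`, logical(1), "unalignable"),
             row.names = NULL)
}

#' Classify a plant from its clone calls
#'
#' Distinct non-wild-type signatures are a lower bound on the number of
#' mutated alleles (two alleles can carry the same edit), reported as
#' `n_mutated_alleles_min`. Classification: `wild-type` when every clone
#' is wild type; `null` when no wild-type clone is seen and the number of
#' mutation types is within the ploidy; `partial` when wild type is seen
#' alongside at most ploidy-1 mutation types; `chimeric` when the
#' distinct genotypes exceed the ploidy (e.g. five mutation types in a
#' tetraploid) or an external conflict is flagged (such as residual
#' digested bands with no wild-type clone).
#'
#' @param calls Data frame from [call_clones()] (>= `min_clones` usable
#'   rows); unalignable clones are dropped with a warning.
#' @param ploidy Number of allelic copies (4 for an autotetraploid).
#' @param min_clones Minimum usable clones required (default 5).
#' @param conflict_flag External evidence of chimerism.
#' @param plant_id Identifier recorded in the result.
#' @return List of class `plant_genotype`: `plant_id`,
#'   `n_mutation_types`, `mutation_types`, `wild_type_observed`,
#'   `n_mutated_alleles_min`, `classification`, `ploidy`, `n_clones`.
#' @export
classify_plant <- function(calls, ploidy = 4L, min_clones = 5L,
                           conflict_flag = FALSE, plant_id = "plant") {
  if (any(calls$unalignable)) {
    warning(sum(calls$unalignable), " unalignable clone(s) excluded")
    calls <- calls[!calls$unalignable, , drop = FALSE]
  }
  if (nrow(calls) < min_clones)
    stop("fewer than ", min_clones, " usable clones")
  types <- sort(unique(calls$signature[calls$signature != "wt"]))
  wt_obs <- any(calls$signature == "wt")
  n_types <- length(types)
  distinct_genotypes <- n_types + as.integer(wt_obs)
  classification <-
    if (conflict_flag || distinct_genotypes > ploidy) "chimeric"
    else if (n_types == 0L) "wild-type"
    else if (!wt_obs) "null"
    else "partial"
  structure(list(plant_id = plant_id, n_mutation_types = n_types,
                 mutation_types = types, wild_type_observed = wt_obs,
                 n_mutated_alleles_min = min(n_types, as.integer(ploidy)),
                 classification = classification, ploidy = as.integer(ploidy),
                 n_clones = nrow(calls)),
            class = "plant_genotype")
}

#' @export
print.plant_genotype <- function(x, ...) {
  cat(sprintf("Plant %s: %s (%d clones, %d mutation type(s), wild type %s)\n",
              x$plant_id, x$classification, x$n_clones, x$n_mutation_types,
              if (x$wild_type_observed) "observed" else "absent"))
  invisible(x)
}

#' Mutagenesis frequency
#'
#' The number of mutant plants divided by the total number of transformed
#' calli, expressed as a percentage rounded half-up to 2 decimals.
#'
#' @param n_mutants Number of mutant plants (0 <= n_mutants <= n_calli).
#' @param n_calli Total transformed calli (> 0).
#' @return Percentage (numeric).
#' @examples
#' mutagenesis_frequency(5, 880)    # 0.57
#' mutagenesis_frequency(26, 1508)  # 1.72
#' @export
mutagenesis_frequency <- function(n_mutants, n_calli) {
  stopifnot_scalar_number(n_mutants, "n_mutants")
  stopifnot_scalar_number(n_calli, "n_calli")
  if (n_calli <= 0) stop("n_calli must be positive")
  if (n_mutants < 0 || n_mutants > n_calli)
    stop("n_mutants must lie in [0, n_calli]")
  round_half_up(100 * n_mutants / n_calli, 2)
}
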