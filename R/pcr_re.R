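## PCR-RE screening design: Cas9 cuts bluntly 3 bp 5' of the PAM (between
## protospacer positions 17 and 18). A restriction site overlapping that
## cut is destroyed by most editing outcomes, so edited alleles resist
## digestion and are visible as undigested bands on a gel.

#' Predict the Cas9 blunt cut position
#'
#' SpCas9 cleaves 3 bp 5' of the PAM, between protospacer positions 17
#' and 18. The cut is reported as the inter-base position `cut_after`:
#' the 1-based genomic coordinate of the base immediately 5' of the cut
#' on the plus strand (the cut lies between `cut_after` and
#' `cut_after + 1`).
#'
#' @param guide_start 1-based genomic coordinate of the protospacer's 5'
#'   base on its own strand.
#' @param strand `"+"` or `"-"`.
#' @param guide_length Protospacer length (default 20).
#' @return Integer `cut_after` coordinate.
#' @examples
#' predict_cut_site(1, "+")   # cut between 17 and 18
#' @export
predict_cut_site <- function(guide_start, strand = "+", guide_length = 20L) {
  stopifnot(strand %in% c("+", "-"))
  if (strand == "+") as.integer(guide_start + guide_length - 4L)
  else as.integer(guide_start - (guide_length - 3L))
}

#' Restriction enzyme definition
#'
#' @param name Enzyme name.
#' @param recognition_site Recognition sequence; full IUPAC ambiguity
#'   codes supported. Length at least 4.
#' @param cut_offset Number of site bases 5' of the top-strand cut
#'   (BstUI CG^CG has `cut_offset = 2`). Must lie in `[0, site length]`.
#' @return An object of class `enzyme`.
#' @export
enzyme <- function(name, recognition_site, cut_offset) {
  recognition_site <- toupper(recognition_site)
  if (nchar(recognition_site) < 4L)
    stop("recognition_site must be at least 4 bases")
  if (cut_offset < 0L || cut_offset > nchar(recognition_site))
    stop("cut_offset must be within the recognition site")
  structure(list(name = name, recognition_site = recognition_site,
                 cut_offset = as.integer(cut_offset)), class = "enzyme")
}

#' Read a restriction-enzyme table
#'
#' Tab-separated file with header columns `name`, `recognition_site`,
#' `cut_offset`. A default library including BstUI (CG^CG) ships with the
#' package (`system.file("extdata", "enzymes.tsv", package = "polyguide")`).
#'
#' @param path TSV path; defaults to the shipped library.
#' @return List of [enzyme()] objects, named by enzyme.
#' @export
read_enzymes <- function(path = system.file("extdata", "enzymes.tsv",
                                            package = "polyguide")) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  out <- lapply(seq_len(nrow(tab)), function(i)
    enzyme(tab$name[i], tab$recognition_site[i], tab$cut_offset[i]))
  setNames(out, tab$name)
}

## All IUPAC matches of a recognition site on both strands of `seq`,
## deduplicated by top-strand interval (palindromes match identically on
## both strands and are reported once).
iupac_site_matches <- function(site, seq) {
  subj <- Biostrings::DNAString(seq)
  pat <- Biostrings::DNAString(site)
  fwd <- Biostrings::matchPattern(pat, subj,
                                  fixed = c(pattern = FALSE, subject = TRUE))
  rev <- Biostrings::matchPattern(Biostrings::reverseComplement(pat), subj,
                                  fixed = c(pattern = FALSE, subject = TRUE))
  iv <- unique(rbind(
    data.frame(start = Biostrings::start(fwd), end = Biostrings::end(fwd)),
    data.frame(start = Biostrings::start(rev), end = Biostrings::end(rev))))
  iv[order(iv$start), , drop = FALSE]
}

#' Find restriction sites overlapping a guide's predicted cut
#'
#' Scans the amplicon/context sequence for every IUPAC match of each
#' enzyme's recognition site (both strands, one report per interval) and
#' flags the matches whose interval contains the predicted Cas9 cut
#' inter-base. A site overlapping the cut makes the enzyme usable for a
#' PCR-RE mutant screen.
#'
#' @param protospacer 20-nt guide sequence present in `context` (plus
#'   strand) with an NGG PAM.
#' @param enzymes List of [enzyme()] objects (e.g. [read_enzymes()]).
#' @param context Amplicon or surrounding sequence containing
#'   protospacer + PAM.
#' @return Data frame: `enzyme`, `start`, `end` (1-based within
#'   `context`), `overlaps_cut`.
#' @export
find_overlapping_sites <- function(protospacer, enzymes, context) {
  context <- as_dna_character(context, "context")
  protospacer <- as_dna_character(protospacer, "protospacer")
  hit <- regexpr(protospacer, context, fixed = TRUE)
  strand <- "+"
  if (hit < 0) {
    hit <- regexpr(revcomp(protospacer), context, fixed = TRUE)
    strand <- "-"
  }
  if (hit < 0) stop("context does not contain the protospacer")
  cut_after <- if (strand == "+") predict_cut_site(as.integer(hit), "+")
               else predict_cut_site(as.integer(hit) + 19L, "-")
  if (!inherits(enzymes, "enzyme") && !is.list(enzymes))
    stop("'enzymes' must be an enzyme or list of enzymes")
  if (inherits(enzymes, "enzyme")) enzymes <- list(enzymes)
  rows <- lapply(enzymes, function(e) {
    iv <- iupac_site_matches(e$recognition_site, context)
    if (nrow(iv) == 0L) return(NULL)
    data.frame(enzyme = e$name, start = iv$start, end = iv$end,
               overlaps_cut = iv$start <= cut_after & cut_after < iv$end)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(enzyme = character(0), start = integer(0),
                      end = integer(0), overlaps_cut = logical(0))
  rownames(out) <- NULL
  attr(out, "cut_after") <- cut_after
  out
}

#' In-silico restriction digest of an amplicon
#'
#' Computes the wild-type band sizes expected on a gel: recognition-site
#' matches (IUPAC, top strand, leftmost non-overlapping occurrences) are
#' cut at the enzyme's top-strand offset and fragment lengths are read
#' left to right. When a `reference` amplicon is supplied, an edited
#' amplicon that has lost sites is flagged `disrupted_by_edit`.
#'
#' @param amplicon Amplicon sequence (character or DNAString).
#' @param enz An [enzyme()].
#' @param reference Optional wild-type amplicon to compare against.
#' @return List of class `digest_result`: `fragment_lengths`, `n_sites`,
#'   `cut_positions` (inter-base, base count 5' of each cut),
#'   `disrupted_by_edit` (`NA` without a reference).
#' @examples
#' bstui <- enzyme("BstUI", "CGCG", 2)
#' digest(paste0(strrep("A", 120), "CGCG", strrep("T", 176)), bstui)
#' @export
digest <- function(amplicon, enz, reference = NULL) {
  amplicon <- as_dna_character(amplicon, "amplicon")
  stopifnot(inherits(enz, "enzyme"))
  if (nchar(amplicon) < nchar(enz$recognition_site))
    stop("amplicon shorter than the recognition site")
  m <- Biostrings::matchPattern(Biostrings::DNAString(enz$recognition_site),
                                Biostrings::DNAString(amplicon),
                                fixed = c(pattern = FALSE, subject = TRUE))
  starts <- Biostrings::start(m)
  ## leftmost non-overlapping occurrences
  kept <- integer(0)
  last_end <- 0L
  for (s in starts) {
    if (s > last_end) {
      kept <- c(kept, s)
      last_end <- s + nchar(enz$recognition_site) - 1L
    }
  }
  cuts <- kept + enz$cut_offset - 1L
  cuts <- cuts[cuts >= 1L & cuts < nchar(amplicon)]
  frags <- diff(c(0L, cuts, nchar(amplicon)))
  disrupted <- NA
  if (!is.null(reference)) {
    ref_d <- digest(reference, enz)
    disrupted <- length(cuts) < ref_d$n_sites
  }
  structure(list(fragment_lengths = as.integer(frags),
                 n_sites = length(cuts),
                 cut_positions = as.integer(cuts),
                 disrupted_by_edit = disrupted),
            class = "digest_result")
}

#' @export
print.digest_result <- function(x, ...) {
  cat("In-silico digest:", x$n_sites, "site(s); fragments:",
      paste(x$fragment_lengths, collapse = ", "), "bp\n")
  if (!is.na(x$disrupted_by_edit))
    cat("Site disrupted by edit:", x$disrupted_by_edit, "\n")
  invisible(x)
}
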