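#' @keywords internal
"_PACKAGE"

#' @import Biostrings
#' @import IRanges
#' @import GenomicRanges
#' @importFrom S4Vectors mcols mcols<- DataFrame
#' @importFrom methods is
#' @importFrom stats rbinom setNames
#' @importFrom utils read.delim write.table
NULL

DNA_BASES4 <- c("A", "C", "G", "T")

## Run code under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

random_dna <- function(n) {
  paste(sample(DNA_BASES4, n, replace = TRUE), collapse = "")
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

## Round half away from zero (printed frequencies use commercial rounding,
## not banker's rounding).
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * trunc(abs(x) * m + 0.5 + 1e-9) / m
}

as_dna_character <- function(x, arg = "sequence") {
  if (is(x, "DNAString") || is(x, "DNAStringSet")) x <- as.character(x)
  if (!is.character(x)) stop("'", arg, "' must be a character or DNAString")
  toupper(x)
}

stopifnot_scalar_number <- function(x, arg) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stop("'", arg, "' must be a single non-missing number")
}

#' Read a genome FASTA into a named DNAStringSet
#'
#' Thin wrapper around [Biostrings::readDNAStringSet()] that trims FASTA
#' descriptions down to the sequence identifier, so chromosome names match
#' those used in GFF3 and truth tables.
#'
#' @param path Path to a FASTA file.
#' @return A named [Biostrings::DNAStringSet].
#' @export
read_genome <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  names(x) <- sub("\\s.*$", "", names(x))
  x
}

## Coerce genome argument to a named DNAStringSet.
as_genome <- function(genome) {
  if (is.character(genome) && length(genome) == 1L && file.exists(genome))
    return(read_genome(genome))
  if (is.character(genome)) genome <- Biostrings::DNAStringSet(toupper(genome))
  if (!is(genome, "DNAStringSet"))
    stop("'genome' must be a DNAStringSet, a named character vector, or a FASTA path")
  if (length(genome) > 0L && is.null(names(genome)))
    names(genome) <- paste0("seq", seq_along(genome))
  genome
}
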