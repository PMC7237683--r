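## Nei-Gojobori (1986) Ka/Ks on pairwise codon alignments, with
## Jukes-Cantor correction, plus the whole-genome-duplication-calibrated
## mutation-rate arithmetic. Synonymous site fractions come from all nine
## single-base neighbours of each codon (changes to stop codons count as
## nonsynonymous); multi-difference codons average the synonymous /
## nonsynonymous difference counts over all substitution pathways that
## avoid stop codons.

ng_env <- new.env(parent = emptyenv())

ng_tables <- function() {
  if (!is.null(ng_env$syn_sites)) return(invisible(NULL))
  gc <- Biostrings::GENETIC_CODE
  codons <- names(gc)
  syn <- setNames(numeric(length(codons)), codons)
  for (cd in codons) {
    if (gc[[cd]] == "*") { syn[cd] <- NA_real_; next }
    s <- 0
    b <- strsplit(cd, "")[[1]]
    for (p in 1:3) for (alt in setdiff(DNA_BASES4, b[p])) {
      nb <- b; nb[p] <- alt
      ncd <- paste(nb, collapse = "")
      if (gc[[ncd]] == gc[[cd]]) s <- s + 1 / 3
    }
    syn[cd] <- s
  }
  ng_env$code <- gc
  ng_env$syn_sites <- syn
  ng_env$pair_cache <- new.env(parent = emptyenv())
  invisible(NULL)
}

## Pathway-averaged (synonymous, nonsynonymous) difference counts for one
## ordered codon pair. Pathways passing through a stop codon are excluded
## from the average; if every pathway is blocked, all pathways are used.
ng_pair_diffs <- function(ca, cb) {
  ng_tables()
  key <- paste0(ca, cb)
  hit <- ng_env$pair_cache[[key]]
  if (!is.null(hit)) return(hit)
  gc <- ng_env$code
  a <- strsplit(ca, "")[[1]]
  b <- strsplit(cb, "")[[1]]
  diffs <- which(a != b)
  nd <- length(diffs)
  res <- if (nd == 0L) c(0, 0) else {
    paths <- if (nd == 1L) list(diffs) else
      lapply(seq_len(factorial(nd)), function(i) perm_nth(diffs, i))
    count_path <- function(ord) {
      cur <- a
      sy <- 0; ns <- 0; blocked <- FALSE
      for (p in ord) {
        nxt <- cur; nxt[p] <- b[p]
        c1 <- paste(cur, collapse = ""); c2 <- paste(nxt, collapse = "")
        if (gc[[c2]] == "*" && c2 != cb) blocked <- TRUE
        if (gc[[c1]] == gc[[c2]]) sy <- sy + 1 else ns <- ns + 1
        cur <- nxt
      }
      c(sy, ns, blocked)
    }
    counts <- vapply(paths, count_path, numeric(3))
    ok <- counts[3, ] == 0
    if (!any(ok)) ok <- rep(TRUE, ncol(counts))
    c(mean(counts[1, ok]), mean(counts[2, ok]))
  }
  ng_env$pair_cache[[key]] <- res
  res
}

## The i-th permutation (1-based, lexicographic by position) of a vector.
perm_nth <- function(x, i) {
  n <- length(x)
  out <- integer(0)
  i <- i - 1L
  items <- x
  for (k in n:1) {
    f <- factorial(k - 1)
    j <- i %/% f + 1L
    out <- c(out, items[j])
    items <- items[-j]
    i <- i %% f
  }
  out
}

jc_correct <- function(p) {
  if (is.na(p)) return(list(d = NA_real_, saturated = NA))
  if (p >= 0.75) return(list(d = NA_real_, saturated = TRUE))
  list(d = -0.75 * log(1 - 4 * p / 3), saturated = FALSE)
}

#' Nei-Gojobori (1986) Ka/Ks for a pairwise codon alignment
#'
#' Codons containing a gap or `N` in either sequence, and codon pairs
#' where either codon is a stop, are excluded from counting. Synonymous
#' (S) and nonsynonymous (N) site counts are averaged between the two
#' sequences, so `S + N = 3 x counted codons`. Proportions `ps = Sd/S`
#' and `pn = Nd/N` are Jukes-Cantor corrected
#' (`d = -3/4 log(1 - 4p/3)`); a proportion at or beyond the 3/4
#' saturation bound yields an `NA` distance flagged `saturated`, never a
#' silent `NaN`.
#'
#' @param seq_a,seq_b Aligned sequences of equal length divisible by 3
#'   (gaps `-`).
#' @return List of class `kaks_result`: `S`, `N`, `Sd`, `Nd`, `ps`, `pn`,
#'   `Ks`, `Ka`, `KaKs` (NA when Ks is 0 or undefined), `n_codons`
#'   (counted codons), `Ks_saturated`, `Ka_saturated`.
#' @examples
#' a <- strrep("GAT", 50)
#' nei_gojobori(a, a)$Ks  # 0
#' @export
nei_gojobori <- function(seq_a, seq_b) {
  seq_a <- as_dna_character(seq_a, "seq_a")
  seq_b <- as_dna_character(seq_b, "seq_b")
  if (nchar(seq_a) != nchar(seq_b))
    stop("aligned sequences must have equal length")
  if (nchar(seq_a) %% 3L != 0L)
    stop("alignment length must be divisible by 3")
  ng_tables()
  gc <- ng_env$code
  n_cod <- nchar(seq_a) %/% 3L
  S <- 0; N <- 0; Sd <- 0; Nd <- 0; counted <- 0L
  for (i in seq_len(n_cod)) {
    ca <- substr(seq_a, 3L * i - 2L, 3L * i)
    cb <- substr(seq_b, 3L * i - 2L, 3L * i)
    if (grepl("[^ACGT]", ca) || grepl("[^ACGT]", cb)) next
    if (gc[[ca]] == "*" || gc[[cb]] == "*") next
    counted <- counted + 1L
    s_site <- (ng_env$syn_sites[[ca]] + ng_env$syn_sites[[cb]]) / 2
    S <- S + s_site
    N <- N + (3 - s_site)
    d <- ng_pair_diffs(ca, cb)
    Sd <- Sd + d[1]
    Nd <- Nd + d[2]
  }
  if (counted == 0L)
    return(structure(list(S = 0, N = 0, Sd = 0, Nd = 0, ps = NA_real_,
                          pn = NA_real_, Ks = NA_real_, Ka = NA_real_,
                          KaKs = NA_real_, n_codons = 0L,
                          Ks_saturated = NA, Ka_saturated = NA,
                          reason = "all codons excluded"),
                     class = "kaks_result"))
  ps <- if (S > 0) Sd / S else NA_real_
  pn <- if (N > 0) Nd / N else NA_real_
  ks <- jc_correct(ps)
  ka <- jc_correct(pn)
  kaks <- if (!is.na(ks$d) && !is.na(ka$d) && ks$d > 0) ka$d / ks$d
          else NA_real_
  structure(list(S = S, N = N, Sd = Sd, Nd = Nd, ps = ps, pn = pn,
                 Ks = ks$d, Ka = ka$d, KaKs = kaks, n_codons = counted,
                 Ks_saturated = ks$saturated, Ka_saturated = ka$saturated,
                 reason = NA_character_),
            class = "kaks_result")
}

#' @export
print.kaks_result <- function(x, ...) {
  cat(sprintf("NG86: %d codons; S=%.2f N=%.2f Sd=%.2f Nd=%.2f\n",
              x$n_codons, x$S, x$N, x$Sd, x$Nd))
  cat(sprintf("  Ks=%s%s  Ka=%s%s  Ka/Ks=%s\n",
              format(x$Ks), if (isTRUE(x$Ks_saturated)) " (saturated)" else "",
              format(x$Ka), if (isTRUE(x$Ka_saturated)) " (saturated)" else "",
              format(x$KaKs)))
  invisible(x)
}

#' Ka/Ks for a batch of aligned pairs
#'
#' Each input is an aligned FASTA with exactly two records.
#'
#' @param paths Character vector of aligned-pair FASTA paths.
#' @return Data frame, one row per pair: `pair`, `S`, `N`, `Sd`, `Nd`,
#'   `ps`, `pn`, `Ks`, `Ka`, `KaKs`.
#' @export
kaks_pairs <- function(paths) {
  rows <- lapply(paths, function(p) {
    aln <- Biostrings::readDNAStringSet(p)
    if (length(aln) != 2L)
      stop("aligned pair file must contain exactly 2 records: ", p)
    r <- nei_gojobori(as.character(aln[[1]]), as.character(aln[[2]]))
    data.frame(pair = basename(p), S = r$S, N = r$N, Sd = r$Sd, Nd = r$Nd,
               ps = r$ps, pn = r$pn, Ks = r$Ks, Ka = r$Ka, KaKs = r$KaKs)
  })
  do.call(rbind, rows)
}

#' Mutation rate calibrated on a whole-genome duplication
#'
#' A WGD of age `T` years leaves paralog pairs whose synonymous distance
#' `Ks` accumulated along two independent lineages, so the per-site
#' per-year rate is `mu = Ks / (2 T)`. With the shared legume WGD at
#' ~58 Mya, a Ks peak of 0.63 gives mu = 5.43e-9.
#'
#' @param Ks Synonymous distance at the WGD peak (>= 0).
#' @param wgd_age Age of the duplication in years (> 0).
#' @return Rate per site per year.
#' @examples
#' mutation_rate_from_wgd(0.63, 58e6)  # 5.43e-09
#' @export
mutation_rate_from_wgd <- function(Ks, wgd_age) {
  stopifnot_scalar_number(Ks, "Ks")
  stopifnot_scalar_number(wgd_age, "wgd_age")
  if (Ks < 0) stop("Ks must be non-negative")
  if (wgd_age <= 0) stop("wgd_age must be positive")
  Ks / (2 * wgd_age)
}

#' Monoploid genome size and difference from a reference
#'
#' @param total_assembly Total assembly size (Mb) across all allelic
#'   chromosome copies.
#' @param ploidy Number of allelic copies (>= 1).
#' @param reference_size Monoploid reference size to compare against (Mb).
#' @return List with `monoploid` (Mb) and `delta` (Mb).
#' @examples
#' monoploid_size_delta(2738, 4, 390)  # 685 Mb monoploid, +295 Mb
#' @export
monoploid_size_delta <- function(total_assembly, ploidy, reference_size) {
  if (ploidy < 1) stop("ploidy must be >= 1")
  mono <- total_assembly / ploidy
  list(monoploid = mono, delta = mono - reference_size)
}
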