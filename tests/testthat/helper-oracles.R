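## Independent oracles. These re-derive expected results by brute force
## with code paths fully separate from the package implementation.

## Sliding-window Hamming enumeration of guide matches with PAM check,
## via vectorized character comparison (no Biostrings matching).
oracle_offtargets <- function(guide, genome, K = 5, pams = c("NGG", "NAG")) {
  gch <- strsplit(guide, "")[[1]]
  out <- list()
  for (chrom in names(genome)) {
    for (strand in c("+", "-")) {
      s <- as.character(genome[[chrom]])
      if (strand == "-") s <- rc(s)
      b <- strsplit(s, "")[[1]]
      L <- length(b)
      if (L < 23) next
      n <- L - 22
      mm <- integer(n)
      for (i in 1:20) mm <- mm + (b[i:(n + i - 1)] != gch[i])
      p1 <- b[21:(n + 20)]; p2 <- b[22:(n + 21)]; p3 <- b[23:(n + 22)]
      acgt <- p1 %in% c("A", "C", "G", "T")
      kind <- ifelse(p2 == "G" & p3 == "G" & acgt, "NGG",
                     ifelse(p2 == "A" & p3 == "G" & acgt, "NAG",
                            NA_character_))
      hit <- which(mm <= K & !is.na(kind) & kind %in% pams)
      if (length(hit))
        out[[length(out) + 1]] <- data.frame(
          chrom = chrom, strand = strand,
          start = if (strand == "+") hit else L - hit + 1L,
          n_mismatches = mm[hit], pam_kind = kind[hit])
    }
  }
  if (length(out)) do.call(rbind, out)
  else data.frame(chrom = character(0), strand = character(0),
                  start = integer(0), n_mismatches = integer(0),
                  pam_kind = character(0))
}

hit_key <- function(d) sort(paste(d$chrom, d$strand, d$start,
                                  d$n_mismatches, d$pam_kind))

## Brute-force guide enumeration within exons (regex-style, both strands):
## every [ACGT]{20}[ACGT]GG window fully inside an exon, deduplicated by
## protospacer.
oracle_exon_guides <- function(exon_seqs_by_copy) {
  protos <- character(0)
  for (ex_set in exon_seqs_by_copy) {
    for (es in ex_set) {
      for (s in c(es, rc(es))) {
        b <- strsplit(s, "")[[1]]
        n <- length(b)
        if (n < 23) next
        for (i in 1:(n - 22)) {
          w <- b[i:(i + 22)]
          if (all(w %in% c("A", "C", "G", "T")) && w[22] == "G" &&
              w[23] == "G")
            protos <- c(protos, paste(w[1:20], collapse = ""))
        }
      }
    }
  }
  sort(unique(protos))
}

## Independent NG86: per-codon recursion over substitution pathways.
GC_TABLE <- Biostrings::GENETIC_CODE

oracle_ng86 <- function(a, b) {
  syn_frac <- function(cod) {
    s <- 0
    for (p in 1:3) for (nt in c("A", "C", "G", "T")) {
      if (substr(cod, p, p) == nt) next
      alt <- cod
      substr(alt, p, p) <- nt
      if (GC_TABLE[[alt]] == GC_TABLE[[cod]]) s <- s + 1 / 3
    }
    s
  }
  paths <- function(c1, c2) {
    dpos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
    if (!length(dpos)) return(matrix(c(0, 0, 0), 1))
    res <- NULL
    recurse <- function(cur, remaining, sy, ns, blocked) {
      if (!length(remaining)) {
        res <<- rbind(res, c(sy, ns, blocked))
        return()
      }
      for (p in remaining) {
        nxt <- cur
        substr(nxt, p, p) <- substr(c2, p, p)
        recurse(nxt, setdiff(remaining, p),
                sy + (GC_TABLE[[cur]] == GC_TABLE[[nxt]]),
                ns + (GC_TABLE[[cur]] != GC_TABLE[[nxt]]),
                blocked || (GC_TABLE[[nxt]] == "*" && nxt != c2))
      }
    }
    recurse(c1, dpos, 0, 0, FALSE)
    res
  }
  S <- 0; Sd <- 0; Nd <- 0; counted <- 0
  for (i in seq_len(nchar(a) / 3)) {
    c1 <- substr(a, 3 * i - 2, 3 * i)
    c2 <- substr(b, 3 * i - 2, 3 * i)
    if (grepl("[^ACGT]", c1) || grepl("[^ACGT]", c2)) next
    if (GC_TABLE[[c1]] == "*" || GC_TABLE[[c2]] == "*") next
    counted <- counted + 1
    S <- S + (syn_frac(c1) + syn_frac(c2)) / 2
    pp <- paths(c1, c2)
    keep <- pp[, 3] == 0
    if (!any(keep)) keep <- rep(TRUE, nrow(pp))
    Sd <- Sd + mean(pp[keep, 1])
    Nd <- Nd + mean(pp[keep, 2])
  }
  list(S = S, N = 3 * counted - S, Sd = Sd, Nd = Nd, n_codons = counted)
}

## Random codon pair: either a mutated copy (rate ~0.15) or fully random.
random_codon_pair <- function(n_codons = 50, mutated = TRUE) {
  codons <- names(GC_TABLE)
  a <- paste(sample(codons, n_codons, TRUE), collapse = "")
  if (!mutated) {
    b <- paste(sample(codons, n_codons, TRUE), collapse = "")
  } else {
    bb <- strsplit(a, "")[[1]]
    mut <- sample(3 * n_codons, rbinom(1, 3 * n_codons, 0.15))
    for (p in mut) bb[p] <- sample(setdiff(c("A", "C", "G", "T"), bb[p]), 1)
    b <- paste(bb, collapse = "")
  }
  list(a = a, b = b)
}

## Simulated plant: pick a truth class, build the clone-set spec.
simulate_plant <- function(class, seed, n_clones = 25) {
  dels <- function(lens) lapply(lens, function(l) list(type = "del", length = l))
  edits <- switch(class,
    "wild-type" = replicate(4, list(type = "wt"), simplify = FALSE),
    "partial"   = c(list(list(type = "wt")), dels(c(1, 2, 4))),
    "null"      = dels(c(1, 2, 4, 5)),
    "chimeric"  = dels(c(1, 2, 4, 5)))
  names(edits) <- paste0("allele", 1:4)
  clone_set_spec(n_clones = n_clones, allele_edits = edits,
                 chimera_extra_types = if (class == "chimeric") 1L else 0L,
                 seed = seed)
}
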