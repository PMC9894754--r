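# MGE characterization: six-frame ORF calling and terminal-repeat-based
# topology / completeness calls.
#
# Completeness here is strictly termini-based: a direct terminal repeat
# (DTR) marks a circularly permuted complete genome, an inverted terminal
# repeat (ITR) a complete linear genome; anything else is unresolved.
# Terminal repeats are exact matches only, DTR is checked before ITR.

STOP_CODONS <- c("TAA", "TAG", "TGA")
START_CODONS <- c("ATG", "GTG", "TTG")

#' Call open reading frames on all six frames
#'
#' Maximal stop-terminated ORFs with starts ATG/GTG/TTG (translated as M,
#' bacterial/archaeal-style start handling), at least `min_len_aa` amino
#' acids (stop excluded).  Within a stop-to-stop segment the first start
#' is used, which yields the longest ORF for that segment; ORFs fully
#' nested inside a longer ORF on the same strand are suppressed.
#'
#' @param sequence A single nucleotide sequence (character or
#'   `DNAString`); A/C/G/T/N only.
#' @param min_len_aa Minimum protein length in amino acids (default 50).
#' @return data.frame: `start`, `end` (0-based, half-open, forward frame,
#'   stop codon included), `strand`, `frame` (0..2 on its own strand),
#'   `aa` (protein, no stop, leading start as M).
#' @export
call_orfs <- function(sequence, min_len_aa = 50L) {
  s <- toupper(as.character(sequence))
  stopifnot(length(s) == 1L)
  if (nchar(s) < 3L) stop("sequence shorter than one codon", call. = FALSE)
  bad <- regexpr("[^ACGTN]", s)
  if (bad > 0)
    stop("non-ACGTN character at position ", bad, call. = FALSE)
  n <- nchar(s)
  code <- Biostrings::GENETIC_CODE
  rows <- list()
  for (strand in c("+", "-")) {
    w <- if (strand == "+") s else revcomp(s)
    for (f in 1:3) {
      starts_nt <- seq.int(f, n - 2L, by = 3L)
      if (!length(starts_nt)) next
      codons <- substring(w, starts_nt, starts_nt + 2L)
      is_stop <- codons %in% STOP_CODONS
      is_start <- codons %in% START_CODONS
      stop_at <- which(is_stop)
      prev <- 0L
      for (t in stop_at) {
        seg <- if (t > prev + 1L) (prev + 1L):(t - 1L) else integer(0)
        prev <- t
        if (!length(seg)) next
        st <- seg[is_start[seg]][1]
        if (is.na(st) || t - st < min_len_aa) next
        aa <- code[codons[st:(t - 1L)]]
        aa[is.na(aa)] <- "X"
        aa[1] <- "M"
        nt1 <- starts_nt[st]               # 1-based on working strand
        nt2 <- starts_nt[t] + 2L           # includes the stop codon
        if (strand == "+") {
          fwd1 <- nt1; fwd2 <- nt2
        } else {
          fwd1 <- n - nt2 + 1L; fwd2 <- n - nt1 + 1L
        }
        rows[[length(rows) + 1L]] <- data.frame(
          start = fwd1 - 1L, end = fwd2, strand = strand,
          frame = f - 1L, aa = paste(aa, collapse = ""))
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(start = integer(0), end = integer(0),
               strand = character(0), frame = integer(0),
               aa = character(0))
  if (nrow(out) > 1L) {
    # suppress ORFs nested within a strictly longer ORF on the same strand
    keep <- rep(TRUE, nrow(out))
    w <- out$end - out$start
    for (i in seq_len(nrow(out))) {
      nested <- out$strand == out$strand[i] & w > w[i] &
        out$start <= out$start[i] & out$end >= out$end[i]
      if (any(nested)) keep[i] <- FALSE
    }
    out <- out[keep, , drop = FALSE]
  }
  out <- out[order(out$start, out$end, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Detect terminal repeats and call genome topology
#'
#' Computes the longest exact terminal match in both senses: identical
#' first/last k bp (direct terminal repeat, DTR) and first k bp equal to
#' the reverse complement of the last k bp (inverted terminal repeat,
#' ITR).  Reports `circular-DTR` if the direct match reaches `min_tr`,
#' else `linear-ITR` if the inverted match does, else `unresolved`.
#'
#' @param sequence A single nucleotide sequence; must be at least
#'   `2 * min_tr` bp.
#' @param min_tr Minimum terminal repeat length in bp (default 20).
#' @param max_tr Search cap on terminal repeat length (default 5000 bp or
#'   half the sequence, whichever is smaller).
#' @return list with `topology` ("circular-DTR", "linear-ITR" or
#'   "unresolved") and `tr_len` (longest terminal match found, possibly
#'   below `min_tr`).
#' @export
detect_termini <- function(sequence, min_tr = 20L, max_tr = 5000L) {
  s <- toupper(as.character(sequence))
  n <- nchar(s)
  if (n < 2L * min_tr)
    stop("sequence shorter than twice the minimum terminal repeat",
         call. = FALSE)
  maxk <- min(n %/% 2L, max_tr)
  a <- utf8ToInt(substr(s, 1L, maxk))
  b <- utf8ToInt(substr(s, n - maxk + 1L, n))
  # DTR: prefix[1:k] == suffix-of-length-k; cheap two-character screen
  # before the full comparison
  ks <- seq_len(maxk)
  cand <- ks[a[ks] == b[maxk] & b[maxk - ks + 1L] == a[1]]
  dtr <- 0L
  for (k in rev(cand)) {
    if (all(a[1:k] == b[(maxk - k + 1L):maxk])) { dtr <- k; break }
  }
  # ITR: prefix[1:k] == revcomp(suffix)[1:k], so the longest ITR is the
  # longest common prefix of the two
  brc <- utf8ToInt(revcomp(substr(s, n - maxk + 1L, n)))
  mism <- which(a != brc)
  itr <- if (length(mism)) mism[1] - 1L else maxk
  if (dtr >= min_tr) {
    list(topology = "circular-DTR", tr_len = dtr)
  } else if (itr >= min_tr) {
    list(topology = "linear-ITR", tr_len = itr)
  } else {
    list(topology = "unresolved", tr_len = max(dtr, itr))
  }
}

#' Characterize a set of MGE contigs
#'
#' ORF calling plus topology/completeness for each contig.
#'
#' @param pool Contigs: FASTA path, named character vector or
#'   `DNAStringSet`.
#' @param ids Optional subset of contig ids to characterize.
#' @inheritParams call_orfs
#' @inheritParams detect_termini
#' @return list with `summary` (per contig: `contig`, `length`, `gc`,
#'   `n_orfs`, `topology`, `completeness`, `tr_len`) and `orfs` (per ORF,
#'   with `contig` and `orf_id` columns prepended).
#' @export
characterize_mges <- function(pool, ids = NULL, min_len_aa = 50L,
                              min_tr = 20L) {
  seqs <- as_seq_chr(pool, "DNA", "contigs")
  if (!is.null(ids)) {
    missing <- setdiff(ids, names(seqs))
    if (length(missing))
      stop("contigs not in pool: ", paste(missing, collapse = ", "),
           call. = FALSE)
    seqs <- seqs[ids]
  }
  orf_list <- list()
  summ <- lapply(names(seqs), function(id) {
    orfs <- call_orfs(seqs[[id]], min_len_aa = min_len_aa)
    term <- detect_termini(seqs[[id]], min_tr = min_tr)
    if (nrow(orfs)) {
      orfs <- cbind(contig = id,
                    orf_id = sprintf("%s|ORF%04d", id, seq_len(nrow(orfs))),
                    orfs)
      orf_list[[id]] <<- orfs
    }
    data.frame(contig = id, length = nchar(seqs[[id]]),
               gc = gc_fraction(seqs[[id]]), n_orfs = nrow(orfs),
               topology = term$topology,
               completeness = if (term$topology == "unresolved")
                 "unknown" else "complete",
               tr_len = term$tr_len)
  })
  orfs <- if (length(orf_list)) do.call(rbind, orf_list) else
    data.frame(contig = character(0), orf_id = character(0),
               start = integer(0), end = integer(0), strand = character(0),
               frame = integer(0), aa = character(0))
  rownames(orfs) <- NULL
  out <- do.call(rbind, summ)
  rownames(out) <- NULL
  list(summary = out, orfs = orfs)
}
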