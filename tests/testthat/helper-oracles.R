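# Independent brute-force oracles. These are deliberately written as
# direct transcriptions of the definitions (exhaustive scans and
# enumerations), separate from the package's seed-and-extend / summation
# implementations, so that agreement is an informative check.

oracle_revcomp <- function(x) {
  chartr("ACGT", "TGCA",
         vapply(x, function(s) paste(rev(strsplit(s, "")[[1]]),
                                     collapse = ""), character(1),
                USE.NAMES = FALSE))
}

# mismatch counts of a pattern at every offset of a subject
oracle_mismatch_profile <- function(pat, s) {
  L <- nchar(pat); n <- nchar(s)
  if (n < L) return(integer(0))
  sv <- utf8ToInt(s); pv <- utf8ToInt(pat)
  n_off <- n - L + 1L
  mm <- integer(n_off)
  for (i in seq_len(L)) mm <- mm + (sv[i:(i + n_off - 1L)] != pv[i])
  mm
}

# full-length gap-free Hamming search of spacers in a pool, both strands,
# one report per (spacer, contig, start); no array suppression
oracle_hamming_hits <- function(spacers, pool, max_mismatch = 1L) {
  rows <- list()
  for (sp in names(spacers)) {
    for (ct in names(pool)) {
      for (strand in c("+", "-")) {
        pat <- if (strand == "+") spacers[[sp]] else
          oracle_revcomp(spacers[[sp]])
        mm <- oracle_mismatch_profile(pat, pool[[ct]])
        hit <- which(mm <= max_mismatch)
        if (!length(hit)) next
        rows[[length(rows) + 1L]] <- data.frame(
          spacer_id = sp, contig = ct, start = hit - 1L,
          end = hit - 1L + nchar(pat), strand = strand,
          mismatches = mm[hit])
      }
    }
  }
  if (!length(rows))
    return(data.frame(spacer_id = character(0), contig = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), mismatches = integer(0)))
  out <- do.call(rbind, rows)
  out <- out[order(out$spacer_id, out$contig, out$start, out$strand), ]
  out <- out[!duplicated(out[, c("spacer_id", "contig", "start")]), ]
  rownames(out) <- NULL
  out
}

# exhaustive tandem-repeat scan: every substring length 20..50 occurring
# >= 3 times at spacer gaps 15..75, kept only when inextensible in both
# directions, then the same overlap-resolution rule
oracle_detect_arrays <- function(s, min_repeat = 20L, max_repeat = 50L,
                                 min_spacer = 15L, max_spacer = 75L,
                                 min_copies = 3L) {
  n <- nchar(s)
  cands <- list()
  for (L in min_repeat:max_repeat) {
    if (n < L) next
    subs <- substring(s, 1:(n - L + 1L), L:n)
    by <- split(seq_len(n - L + 1L), subs)
    by <- by[lengths(by) >= min_copies]
    by <- by[!grepl("[^ACGT]", names(by))]
    for (P0 in by) {
      P0 <- sort(P0)
      gaps <- diff(P0) - L
      ok <- gaps >= min_spacer & gaps <= max_spacer
      run_id <- cumsum(c(TRUE, !ok))
      for (run in split(seq_along(P0), run_id)) {
        if (length(run) < min_copies) next
        P <- P0[run]
        gap_min <- if (length(P) > 1) min(diff(P)) - L else Inf
        right_ok <- L < max_repeat && P[length(P)] + L <= n &&
          gap_min - 1L >= min_spacer &&
          length(unique(substring(s, P + L, P + L))) == 1L
        left_ok <- L < max_repeat && P[1] > 1L &&
          gap_min - 1L >= min_spacer &&
          length(unique(substring(s, P - 1L, P - 1L))) == 1L
        if (right_ok || left_ok) next
        cands[[length(cands) + 1L]] <- list(P = P, L = L)
      }
    }
  }
  oracle_arrays_df(s, cands, min_copies)
}

oracle_arrays_df <- function(s, cands, min_copies) {
  empty <- data.frame(start = integer(0), end = integer(0),
                      n_copies = integer(0), repeat_seq = character(0))
  if (!length(cands)) return(empty)
  meta <- data.frame(
    copies = vapply(cands, function(x) length(x$P), integer(1)),
    start = vapply(cands, function(x) x$P[1], numeric(1)),
    end = vapply(cands, function(x) x$P[length(x$P)] + x$L - 1,
                 numeric(1)))
  meta$span <- meta$end - meta$start + 1
  kept <- integer(0)
  for (i in order(-meta$copies, -meta$span, meta$start)) {
    if (!any(meta$start[kept] <= meta$end[i] &
               meta$end[kept] >= meta$start[i]))
      kept <- c(kept, i)
  }
  kept <- kept[order(meta$start[kept])]
  do.call(rbind, lapply(kept, function(i) {
    P <- cands[[i]]$P; L <- cands[[i]]$L
    data.frame(start = as.integer(P[1] - 1L),
               end = as.integer(P[length(P)] + L - 1L),
               n_copies = length(P),
               repeat_seq = substring(s, P[1], P[1] + L - 1L))
  }))
}

# all ORFs by scanning every start codon on both strands, reduced to the
# longest per stop, with same-strand containment suppression
oracle_orfs <- function(s, min_len_aa = 50L) {
  code <- Biostrings::GENETIC_CODE
  stops <- c("TAA", "TAG", "TGA")
  starts <- c("ATG", "GTG", "TTG")
  n <- nchar(s)
  rows <- list()
  for (strand in c("+", "-")) {
    w <- if (strand == "+") s else oracle_revcomp(s)
    for (i in seq_len(n - 2L)) {
      if (!substring(w, i, i + 2L) %in% starts) next
      j <- i
      stop_at <- NA_integer_
      while (j + 2L <= n) {
        if (substring(w, j, j + 2L) %in% stops && j > i) {
          stop_at <- j
          break
        }
        j <- j + 3L
      }
      if (is.na(stop_at)) next
      aa_len <- (stop_at - i) / 3
      if (aa_len < min_len_aa) next
      codons <- substring(w, seq(i, stop_at - 3L, 3L),
                          seq(i + 2L, stop_at - 1L, 3L))
      aa <- code[codons]
      aa[is.na(aa)] <- "X"
      aa[1] <- "M"
      nt2 <- stop_at + 2L
      if (strand == "+") { f1 <- i; f2 <- nt2 } else {
        f1 <- n - nt2 + 1L; f2 <- n - i + 1L
      }
      rows[[length(rows) + 1L]] <- data.frame(
        start = f1 - 1L, end = f2, strand = strand,
        stop_key = paste(strand, stop_at),
        aa = paste(aa, collapse = ""))
    }
  }
  if (!length(rows))
    return(data.frame(start = integer(0), end = integer(0),
                      strand = character(0), aa = character(0)))
  all_orfs <- do.call(rbind, rows)
  # longest ORF per stop codon
  keep <- unlist(lapply(split(seq_len(nrow(all_orfs)), all_orfs$stop_key),
                        function(ix) {
    w <- all_orfs$end[ix] - all_orfs$start[ix]
    ix[which.max(w)]
  }), use.names = FALSE)
  out <- all_orfs[keep, c("start", "end", "strand", "aa")]
  w <- out$end - out$start
  nested <- vapply(seq_len(nrow(out)), function(i)
    any(out$strand == out$strand[i] & w > w[i] &
          out$start <= out$start[i] & out$end >= out$end[i]), logical(1))
  out <- out[!nested, , drop = FALSE]
  out <- out[order(out$start, out$end, out$strand), ]
  rownames(out) <- NULL
  out
}

# hypergeometric upper tail by explicit enumeration of all size-b draws
oracle_hypergeom <- function(a, b, c, n) {
  if (c == 0) return(1)
  if (b == 0) return(0)
  draws <- utils::combn(n, b)
  hit <- sum(apply(draws, 2, function(d) sum(d <= a) >= c))
  hit / ncol(draws)
}

random_dna_chr <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
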