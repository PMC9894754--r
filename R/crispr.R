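# CRISPR repeat-spacer array detection and the clade-trusted spacer
# catalogue.
#
# Detection is a seed-and-extend scan for tandem exact repeats: every
# k-mer (k = min_repeat) occurring >= min_copies times at spacings
# compatible with a repeat-spacer period seeds a candidate array, whose
# repeat is then extended in both directions while all copies stay
# identical and every spacer keeps its minimum length.  Repeat copies
# within an array are therefore exact duplicates of the consensus
# (trivially within the <= 2-substitution tolerance the array model
# allows).  Trust filters operate at the repeat level: a repeat is only
# believed to belong to the host clade when seen on >= 3 distinct contigs,
# and repeats shared with an off-target sister clade are discarded.

#' Detect CRISPR repeat-spacer arrays on contigs
#'
#' Scans each contig for tandem arrays of an exactly repeated unit of
#' `min_repeat`..`max_repeat` bp, separated by unique spacers of
#' `min_spacer`..`max_spacer` bp, with at least `min_copies` repeat copies.
#' Overlapping candidate arrays are resolved in favour of more repeat
#' copies, then longer span, then leftmost start.
#'
#' @param contigs Nucleotide sequences: FASTA path, named character vector
#'   or `DNAStringSet`.
#' @param min_repeat,max_repeat Repeat length bounds in bp.
#' @param min_spacer,max_spacer Spacer length bounds in bp.
#' @param min_copies Minimum number of repeat copies per array.
#' @return A data.frame with one row per array: `contig`, `start`, `end`
#'   (0-based, half-open), `n_copies`, `repeat_seq`, and a list-column
#'   `spacers` of per-spacer data.frames (`seq`, `start`, `end`).
#' @export
detect_arrays <- function(contigs, min_repeat = 20L, max_repeat = 50L,
                          min_spacer = 15L, max_spacer = 75L,
                          min_copies = 3L) {
  stopifnot(min_repeat >= 1, max_repeat >= min_repeat,
            min_spacer >= 1, max_spacer >= min_spacer, min_copies >= 2)
  seqs <- as_seq_chr(contigs, "DNA", "contigs")
  if (!length(seqs)) stop("no contigs supplied", call. = FALSE)
  rows <- lapply(seq_along(seqs), function(i) {
    arr <- detect_arrays_one(seqs[[i]], min_repeat, max_repeat,
                             min_spacer, max_spacer, min_copies)
    if (nrow(arr)) arr$contig <- names(seqs)[i]
    arr
  })
  out <- do.call(rbind, rows)
  if (is.null(out) || !nrow(out)) return(empty_arrays())
  out <- out[, c("contig", "start", "end", "n_copies", "repeat_seq",
                 "spacers")]
  rownames(out) <- NULL
  out
}

empty_arrays <- function() {
  data.frame(contig = character(0), start = integer(0), end = integer(0),
             n_copies = integer(0), repeat_seq = character(0),
             spacers = I(list()))
}

detect_arrays_one <- function(s, min_repeat, max_repeat, min_spacer,
                              max_spacer, min_copies) {
  n <- nchar(s)
  k <- min_repeat
  if (n < min_copies * min_repeat + (min_copies - 1L) * min_spacer)
    return(empty_arrays())
  kmers <- substring(s, 1:(n - k + 1L), k:n)
  by_kmer <- split(seq_len(n - k + 1L), kmers)
  by_kmer <- by_kmer[lengths(by_kmer) >= min_copies]
  by_kmer <- by_kmer[!grepl("[^ACGT]", names(by_kmer))]
  if (!length(by_kmer)) return(empty_arrays())

  cands <- list()
  seen <- character(0)
  for (P0 in by_kmer) {
    P0 <- sort(P0)
    diffs <- diff(P0)
    ok <- diffs >= k + min_spacer & diffs <= max_repeat + max_spacer
    # maximal runs of seed positions at array-compatible spacing
    run_id <- cumsum(c(TRUE, !ok))
    for (run in split(seq_along(P0), run_id)) {
      if (length(run) < min_copies) next
      ext <- extend_array(s, n, P0[run], k, max_repeat, min_spacer)
      for (cand in validate_array(ext$P, ext$L, min_copies, min_spacer,
                                  max_spacer)) {
        key <- paste(cand$P[1], cand$L, length(cand$P), sep = ":")
        if (key %in% seen) next
        seen <- c(seen, key)
        cands[[length(cands) + 1L]] <- cand
      }
    }
  }
  if (!length(cands)) return(empty_arrays())
  resolve_overlaps(s, cands)
}

# Grow the repeat while every copy stays an exact duplicate, the repeat
# stays within max_repeat and every spacer keeps >= min_spacer bp.
# Rightward first, then leftward; the right boundary is unaffected by
# later leftward growth, so the result is inextensible on both sides.
extend_array <- function(s, n, P, L, max_repeat, min_spacer) {
  gap_room <- function(L1) length(P) == 1L || min(diff(P)) - L1 >= min_spacer
  repeat {
    if (L >= max_repeat || P[length(P)] + L > n || !gap_room(L + 1L)) break
    ch <- substring(s, P + L, P + L)
    if (length(unique(ch)) != 1L) break
    L <- L + 1L
  }
  repeat {
    if (L >= max_repeat || P[1] <= 1L || !gap_room(L + 1L)) break
    ch <- substring(s, P - 1L, P - 1L)
    if (length(unique(ch)) != 1L) break
    P <- P - 1L
    L <- L + 1L
  }
  list(P = P, L = L)
}

# Enforce per-gap spacer bounds; a gap that grew past max_spacer splits
# the chain, and each surviving sub-chain must still have min_copies.
validate_array <- function(P, L, min_copies, min_spacer, max_spacer) {
  if (length(P) < min_copies) return(list())
  gaps <- diff(P) - L
  ok <- gaps >= min_spacer & gaps <= max_spacer
  run_id <- cumsum(c(TRUE, !ok))
  out <- list()
  for (run in split(seq_along(P), run_id)) {
    if (length(run) >= min_copies)
      out[[length(out) + 1L]] <- list(P = P[run], L = L)
  }
  out
}

resolve_overlaps <- function(s, cands) {
  meta <- data.frame(
    copies = vapply(cands, function(x) length(x$P), integer(1)),
    start = vapply(cands, function(x) x$P[1], numeric(1)),
    end = vapply(cands, function(x) x$P[length(x$P)] + x$L - 1, numeric(1)))
  meta$span <- meta$end - meta$start + 1
  ord <- order(-meta$copies, -meta$span, meta$start)
  kept <- integer(0)
  for (i in ord) {
    clash <- any(meta$start[kept] <= meta$end[i] &
                   meta$end[kept] >= meta$start[i])
    if (!clash) kept <- c(kept, i)
  }
  kept <- kept[order(meta$start[kept])]
  rows <- lapply(kept, function(i) {
    P <- cands[[i]]$P; L <- cands[[i]]$L; m <- length(P)
    sp <- data.frame(
      seq = substring(s, P[-m] + L, P[-1] - 1L),
      start = as.integer(P[-m] + L - 1L),       # 0-based half-open
      end = as.integer(P[-1] - 1L))
    data.frame(contig = NA_character_,
               start = as.integer(P[1] - 1L),
               end = as.integer(P[m] + L - 1L),
               n_copies = m,
               repeat_seq = substring(s, P[1], P[1] + L - 1L),
               spacers = I(list(sp)))
  })
  do.call(rbind, rows)
}

#' Cluster CRISPR repeats across contigs and flag clade-trusted ones
#'
#' Repeats are strand-canonicalized and greedily clustered: in a fixed
#' deterministic order each repeat joins the first cluster whose founder
#' consensus is within `max_len_diff` bp in length and at
#' `min_identity` identity (either orientation), else founds a new
#' cluster.  A cluster is `trusted` when its members come from at least
#' `min_contigs` distinct contigs — the conservative filter against
#' binning artefacts.
#'
#' @param arrays Output of [detect_arrays()].
#' @param min_contigs Distinct-contig threshold for trust (default 3).
#' @param min_identity Full-length identity threshold for "same repeat".
#' @param max_len_diff Maximum repeat length difference within a cluster.
#' @return data.frame: `cluster_id`, `consensus`, `n_members`,
#'   `n_distinct_contigs`, `trusted`, list-column `members` of row indices
#'   into `arrays`.
#' @export
cluster_repeats <- function(arrays, min_contigs = 3L, min_identity = 0.9,
                            max_len_diff = 2L) {
  if (!nrow(arrays)) return(empty_repeat_clusters())
  can <- canonical_seq(arrays$repeat_seq)
  ord <- order(can, arrays$contig, arrays$start)
  consensus <- character(0)
  members <- list()
  for (i in ord) {
    placed <- FALSE
    for (j in seq_along(consensus)) {
      if (abs(nchar(can[i]) - nchar(consensus[j])) > max_len_diff) next
      if (can[i] == consensus[j] ||
          seq_identity(can[i], consensus[j], both_strands = TRUE) >=
            min_identity) {
        members[[j]] <- c(members[[j]], i)
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      consensus <- c(consensus, can[i])
      members[[length(members) + 1L]] <- i
    }
  }
  n_contigs <- vapply(members, function(m)
    length(unique(arrays$contig[m])), integer(1))
  data.frame(cluster_id = seq_along(consensus),
             consensus = consensus,
             n_members = lengths(members),
             n_distinct_contigs = n_contigs,
             trusted = n_contigs >= min_contigs,
             members = I(members))
}

empty_repeat_clusters <- function() {
  data.frame(cluster_id = integer(0), consensus = character(0),
             n_members = integer(0), n_distinct_contigs = integer(0),
             trusted = logical(0), members = I(list()))
}

#' Remove repeat clusters shared with an off-target clade
#'
#' Drops every target cluster whose consensus matches any off-target
#' cluster consensus at or above the repeat-identity threshold (either
#' orientation).  Mirrors the cross-clade repeat exclusion used to keep
#' the spacer catalogue clade-specific.
#'
#' @param target,offtarget Outputs of [cluster_repeats()] for the clade of
#'   interest and the sister clade.
#' @inheritParams cluster_repeats
#' @return The filtered `target` data.frame.
#' @export
exclude_cross_clade <- function(target, offtarget, min_identity = 0.9,
                                max_len_diff = 2L) {
  if (!nrow(target) || !nrow(offtarget)) return(target)
  drop <- vapply(target$consensus, function(tc) {
    any(vapply(offtarget$consensus, function(oc) {
      abs(nchar(tc) - nchar(oc)) <= max_len_diff &&
        (tc == oc ||
           seq_identity(tc, oc, both_strands = TRUE) >= min_identity)
    }, logical(1)))
  }, logical(1))
  out <- target[!drop, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build the unique spacer catalogue from trusted arrays
#'
#' Collects spacers only from arrays whose repeat belongs to a trusted
#' cluster, canonicalizes each spacer to the lexicographic minimum of
#' itself and its reverse complement, and exact-deduplicates.  Provenance
#' (contig and 0-based coordinates of every source copy) is preserved.
#'
#' @param arrays Output of [detect_arrays()].
#' @param clusters Output of [cluster_repeats()] (possibly filtered by
#'   [exclude_cross_clade()]); only rows with `trusted == TRUE` donate
#'   spacers.
#' @return data.frame with `spacer_id`, `seq` (canonical), `n_copies`, and
#'   list-column `sources`; attributes `n_unique` (canonical) and
#'   `n_unique_stranded` (orientation-aware count, reported because the
#'   strand convention for "unique" spacers is a documented choice).
#' @export
build_spacer_catalogue <- function(arrays, clusters) {
  keep_arr <- sort(unique(unlist(clusters$members[clusters$trusted])))
  if (!length(keep_arr)) {
    out <- data.frame(spacer_id = character(0), seq = character(0),
                      n_copies = integer(0), sources = I(list()))
    attr(out, "n_unique") <- 0L
    attr(out, "n_unique_stranded") <- 0L
    return(out)
  }
  sp <- do.call(rbind, lapply(keep_arr, function(i) {
    d <- arrays$spacers[[i]]
    if (!nrow(d)) return(NULL)
    d$contig <- arrays$contig[i]
    d
  }))
  can <- canonical_seq(sp$seq)
  uniq <- sort(unique(can))
  src <- split(paste0(sp$contig, ":", sp$start, "-", sp$end), can)[uniq]
  out <- data.frame(
    spacer_id = sprintf("SP%06d", seq_along(uniq)),
    seq = uniq,
    n_copies = lengths(src),
    sources = I(unname(src)))
  attr(out, "n_unique") <- length(uniq)
  attr(out, "n_unique_stranded") <- length(unique(sp$seq))
  rownames(out) <- NULL
  out
}
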