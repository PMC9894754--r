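# Protospacer matching and the stringent MGE retention filters.
#
# The match model is deliberately strict: gap-free, full spacer length,
# at most `max_mismatch` substitutions (default 1), searched on both
# strands.  Matches falling inside CRISPR arrays detected on the target
# pool itself (padded by one repeat length) are suppressed, so that
# array-on-array matches never masquerade as host-MGE links.  An element
# is retained only with >= 3 distinct protospacer loci and > 10 kb of
# sequence.

#' Find protospacer matches of a spacer catalogue in a contig pool
#'
#' Reports every gap-free full-length occurrence of each spacer, on either
#' strand, with at most `max_mismatch` substitutions.  Each occurrence is
#' reported exactly once per (spacer, contig, start, strand).  Hits that
#' overlap a CRISPR array detected on the target contig (padded by one
#' repeat length on each side) are suppressed.
#'
#' @param catalogue Output of [build_spacer_catalogue()], or a named
#'   character vector of spacer sequences.
#' @param pool Candidate MGE contigs: FASTA path, named character vector or
#'   `DNAStringSet`.
#' @param max_mismatch Maximum substitutions per match (default 1).
#' @param suppress_arrays Mask hits inside arrays detected on the pool.
#' @return data.frame: `spacer_id`, `contig`, `start`, `end` (0-based,
#'   half-open, forward-strand frame), `strand` ("+"/"-"), `mismatches`.
#' @export
find_protospacers <- function(catalogue, pool, max_mismatch = 1L,
                              suppress_arrays = TRUE) {
  spacers <- if (is.data.frame(catalogue)) {
    stats::setNames(catalogue$seq, catalogue$spacer_id)
  } else {
    sp <- catalogue
    if (is.null(names(sp))) names(sp) <- sprintf("SP%06d", seq_along(sp))
    sp
  }
  if (!length(spacers)) stop("spacer catalogue is empty", call. = FALSE)
  short <- nchar(spacers) < 15L
  if (any(short)) {
    warning(sum(short), " spacer(s) shorter than 15 bp rejected")
    spacers <- spacers[!short]
  }
  seqs <- as_seq_chr(pool, "DNA", "pool contigs")
  if (!length(seqs) || !length(spacers)) return(empty_hits())
  subject <- DNAStringSet(seqs)

  rows <- list()
  for (i in seq_along(spacers)) {
    for (strand in c("+", "-")) {
      pat <- if (strand == "+") spacers[[i]] else revcomp(spacers[[i]])
      m <- Biostrings::vmatchPattern(pat, subject,
                                     max.mismatch = max_mismatch,
                                     with.indels = FALSE, fixed = TRUE)
      for (j in seq_along(seqs)) {
        st <- Biostrings::startIndex(m)[[j]]
        if (is.null(st) || !length(st)) next
        # edge matches hanging off the contig are not full-length
        st <- st[st >= 1L & st + nchar(pat) - 1L <= nchar(seqs[[j]])]
        if (!length(st)) next
        obs <- substring(seqs[[j]], st, st + nchar(pat) - 1L)
        mm <- vapply(obs, hamming, integer(1), b = pat, USE.NAMES = FALSE)
        rows[[length(rows) + 1L]] <- data.frame(
          spacer_id = names(spacers)[i], contig = names(seqs)[j],
          start = as.integer(st - 1L),
          end = as.integer(st - 1L + nchar(pat)),
          strand = strand, mismatches = mm)
      }
    }
  }
  hits <- if (length(rows)) do.call(rbind, rows) else empty_hits()
  if (!nrow(hits)) return(hits)
  # one report per occurrence: a palindromic spacer matches both strands
  # at the same locus; keep the "+" report
  hits <- hits[order(hits$spacer_id, hits$contig, hits$start,
                     hits$strand), ]
  dup <- duplicated(hits[, c("spacer_id", "contig", "start")])
  hits <- hits[!dup, , drop = FALSE]

  if (suppress_arrays) {
    arrs <- detect_arrays(seqs)
    if (nrow(arrs)) {
      pad <- nchar(arrs$repeat_seq)
      keep <- !vapply(seq_len(nrow(hits)), function(h) {
        on <- arrs$contig == hits$contig[h]
        any(on & (arrs$start - pad) < hits$end[h] &
              (arrs$end + pad) > hits$start[h])
      }, logical(1))
      hits <- hits[keep, , drop = FALSE]
    }
  }
  rownames(hits) <- NULL
  hits
}

empty_hits <- function() {
  data.frame(spacer_id = character(0), contig = character(0),
             start = integer(0), end = integer(0), strand = character(0),
             mismatches = integer(0))
}

#' Apply the stringent MGE retention filters to protospacer hits
#'
#' One candidate row per pool contig with at least one hit.  Distinct
#' protospacer loci are counted by (start, strand), so repeated targeting
#' of one locus by near-identical spacers counts once.  A candidate is
#' `retained` iff it carries at least `min_protospacers` distinct loci and
#' is longer than `min_len` bp.
#'
#' @param hits Output of [find_protospacers()].
#' @param pool The contig pool the hits refer to.
#' @param source_labels Optional named character vector mapping contig id
#'   to an assembly-of-origin label (default "pool").
#' @param min_protospacers Minimum distinct protospacer loci (default 3).
#' @param min_len Minimum contig length in bp, exclusive (default 10000).
#' @return data.frame: `contig`, `length`, `source`, `n_hits`,
#'   `n_protospacer_loci`, `retained`.
#' @export
link_mges <- function(hits, pool, source_labels = NULL,
                      min_protospacers = 3L, min_len = 10000L) {
  seqs <- as_seq_chr(pool, "DNA", "pool contigs")
  bad <- setdiff(hits$contig, names(seqs))
  if (length(bad))
    stop("hits refer to contigs absent from the pool: ",
         paste(utils::head(bad, 3), collapse = ", "), call. = FALSE)
  src <- stats::setNames(rep("pool", length(seqs)), names(seqs))
  if (!is.null(source_labels)) src[names(source_labels)] <- source_labels
  ids <- sort(unique(hits$contig))
  n_loci <- vapply(ids, function(id) {
    h <- hits[hits$contig == id, ]
    nrow(unique(h[, c("start", "strand")]))
  }, integer(1))
  n_hits <- vapply(ids, function(id) sum(hits$contig == id), integer(1))
  len <- nchar(seqs[ids])
  out <- data.frame(contig = ids, length = as.integer(len),
                    source = unname(src[ids]), n_hits = n_hits,
                    n_protospacer_loci = n_loci,
                    retained = n_loci >= min_protospacers & len > min_len)
  rownames(out) <- NULL
  out
}

#' Tally retained MGEs per source assembly
#'
#' @param mges Output of [link_mges()].
#' @return data.frame of `source`, `n_retained`, plus a `total` attribute;
#'   counts cover retained elements only.
#' @export
tally_by_source <- function(mges) {
  kept <- mges[mges$retained, , drop = FALSE]
  srcs <- sort(unique(mges$source))
  out <- data.frame(source = srcs,
                    n_retained = vapply(srcs, function(s)
                      sum(kept$source == s), integer(1)))
  rownames(out) <- NULL
  attr(out, "total") <- sum(out$n_retained)
  out
}
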