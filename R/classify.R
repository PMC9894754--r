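# Virus vs unclassified-MGE classification from hallmark genes, and the
# final integrated report.
#
# The classification rule mirrors the field's convention: an element with
# an identifiable viral structural protein (a major capsid protein class,
# portal, or large terminase) is a virus; replication-only hallmarks
# (protein-primed or RNA-primed family B polymerase) never confer virus
# status, so e.g. a circular element with only pPolB stays an
# unclassified MGE (plausibly a plasmid).

MARKER_CLASSES <- c("HK97-MCP", "portal", "TerL", "DJR-MCP", "SJR-MCP",
                    "alpha-helical-MCP", "spindle-MCP", "pPolB", "rPolB",
                    "other")
STRUCTURAL_CLASSES <- c("HK97-MCP", "portal", "TerL", "DJR-MCP",
                        "SJR-MCP", "alpha-helical-MCP", "spindle-MCP")

#' Scan MGE proteomes against hallmark marker proteins
#'
#' Marker FASTA headers must be `marker_id|class` with `class` drawn from
#' the controlled vocabulary (HK97-MCP, portal, TerL, DJR-MCP, SJR-MCP,
#' alpha-helical-MCP, spindle-MCP, pPolB, rPolB, other).  For each ORF the
#' best-scoring marker is reported when the local alignment reaches
#' `min_identity` over at least `min_coverage` of the marker length.
#'
#' @param orfs ORF table from [characterize_mges()] (columns `contig`,
#'   `orf_id`, `aa`), or a named character vector of proteins.
#' @param markers Marker proteins: FASTA path, named character vector or
#'   `AAStringSet`, headers `marker_id|class`.
#' @param min_identity Identity over aligned columns (default 0.3).
#' @param min_coverage Aligned fraction of the marker length (default 0.5).
#' @return data.frame: `mge_id`, `orf_id`, `marker_id`, `marker_class`,
#'   `identity`, `coverage`.
#' @export
scan_markers <- function(orfs, markers, min_identity = 0.3,
                         min_coverage = 0.5) {
  if (is.data.frame(orfs)) {
    prot <- stats::setNames(orfs$aa, orfs$orf_id)
    mge <- stats::setNames(orfs$contig, orfs$orf_id)
  } else {
    prot <- as_seq_chr(orfs, "AA", "proteins")
    mge <- stats::setNames(sub("\\|.*$", "", names(prot)), names(prot))
  }
  mk <- as_seq_chr(markers, "AA", "markers")
  if (!length(mk)) stop("no marker sequences supplied", call. = FALSE)
  parts <- strsplit(names(mk), "|", fixed = TRUE)
  if (any(lengths(parts) != 2L))
    stop("marker headers must be 'marker_id|class'", call. = FALSE)
  cls <- vapply(parts, `[`, character(1), 2L)
  bad <- setdiff(cls, MARKER_CLASSES)
  if (length(bad))
    stop("unknown marker class token(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  mk_id <- vapply(parts, `[`, character(1), 1L)
  if (!length(prot)) return(empty_marker_hits())

  pat <- Biostrings::AAStringSet(prot)
  best <- data.frame(orf = names(prot), score = -Inf,
                     marker_id = NA_character_, class = NA_character_,
                     identity = NA_real_, coverage = NA_real_)
  ord <- order(mk_id)
  for (m in ord) {
    al <- Biostrings::pairwiseAlignment(
      pattern = pat, subject = mk[[m]], type = "local",
      substitutionMatrix = blosum62(), gapOpening = 10, gapExtension = 0.5)
    ident <- Biostrings::pid(al, type = "PID1") / 100
    cov <- Biostrings::width(Biostrings::subject(al)) / nchar(mk[[m]])
    sc <- Biostrings::score(al)
    pass <- ident >= min_identity & cov >= min_coverage & sc > best$score
    best$score[pass] <- sc[pass]
    best$marker_id[pass] <- mk_id[m]
    best$class[pass] <- cls[m]
    best$identity[pass] <- ident[pass]
    best$coverage[pass] <- cov[pass]
  }
  hit <- !is.na(best$marker_id)
  out <- data.frame(mge_id = unname(mge[best$orf[hit]]),
                    orf_id = best$orf[hit],
                    marker_id = best$marker_id[hit],
                    marker_class = best$class[hit],
                    identity = best$identity[hit],
                    coverage = best$coverage[hit])
  rownames(out) <- NULL
  out
}

empty_marker_hits <- function() {
  data.frame(mge_id = character(0), orf_id = character(0),
             marker_id = character(0), marker_class = character(0),
             identity = numeric(0), coverage = numeric(0))
}

#' Assign virus / unclassified-MGE status and build report rows
#'
#' An element is a `virus` iff it carries at least one structural marker
#' class (any MCP variant, portal, or TerL); replication-only markers
#' never confer virus status.  Everything else is `unclassified-MGE`.
#'
#' @param mges Output of [link_mges()]; only retained elements are
#'   reported.
#' @param marker_hits Output of [scan_markers()].
#' @param characterization Optional output of [characterize_mges()] to
#'   fill topology/completeness.
#' @param network Optional output of [build_network()] to fill cluster
#'   ids.
#' @return data.frame with one row per retained MGE: `mge_id`, `length`,
#'   `source`, `topology`, `completeness`, `n_protospacer_loci`,
#'   `cluster`, `status`, `marker_classes`.
#' @export
assign_status <- function(mges, marker_hits,
                          characterization = NULL, network = NULL) {
  kept <- mges[mges$retained, , drop = FALSE]
  kept <- kept[order(kept$contig), , drop = FALSE]
  classes <- vapply(kept$contig, function(id) {
    cl <- sort(unique(marker_hits$marker_class[marker_hits$mge_id == id]))
    paste(cl, collapse = ",")
  }, character(1))
  is_virus <- vapply(kept$contig, function(id) {
    any(marker_hits$marker_class[marker_hits$mge_id == id] %in%
          STRUCTURAL_CLASSES)
  }, logical(1))
  topo <- rep(NA_character_, nrow(kept))
  compl <- rep(NA_character_, nrow(kept))
  if (!is.null(characterization)) {
    m <- match(kept$contig, characterization$summary$contig)
    topo <- characterization$summary$topology[m]
    compl <- characterization$summary$completeness[m]
  }
  clust <- rep(NA_integer_, nrow(kept))
  if (!is.null(network)) {
    m <- match(kept$contig, network$nodes$genome)
    clust <- network$nodes$cluster[m]
  }
  out <- data.frame(mge_id = kept$contig, length = kept$length,
                    source = kept$source, topology = topo,
                    completeness = compl,
                    n_protospacer_loci = kept$n_protospacer_loci,
                    cluster = clust,
                    status = ifelse(is_virus, "virus", "unclassified-MGE"),
                    marker_classes = unname(classes))
  rownames(out) <- NULL
  out
}

#' Write the integrated MGE report
#'
#' Deterministic, sorted TSV of report rows plus a JSON summary with
#' counts per status, topology, cluster and source.  Rows are sorted by
#' `mge_id`, so report generation is independent of input order.
#'
#' @param rows Output of [assign_status()].
#' @param tsv_path,json_path Output file paths.
#' @return Invisibly, the summary list written to JSON.
#' @export
write_report <- function(rows, tsv_path, json_path) {
  rows <- rows[order(rows$mge_id), , drop = FALSE]
  count_by <- function(x) {
    x <- x[!is.na(x)]
    tab <- table(x)
    as.list(stats::setNames(as.integer(tab), sort(names(tab))))
  }
  summary <- list(
    n_mges = nrow(rows),
    by_status = count_by(rows$status),
    by_topology = count_by(rows$topology),
    by_cluster = count_by(as.character(rows$cluster)),
    by_source = count_by(rows$source))
  utils::write.table(rows, tsv_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, eol = "\n")
  jsonlite::write_json(summary, json_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(summary)
}
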