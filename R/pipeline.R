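# End-to-end driver: from host contigs and a candidate pool to the
# integrated MGE report.  Each stage is an exported function; this
# wrapper only fixes their order and plumbs intermediate results.

#' Run the full spacer-based mobilome discovery pipeline
#'
#' Detects CRISPR arrays on the host contigs, builds the clade-trusted
#' spacer catalogue (with optional cross-clade repeat exclusion), maps
#' spacers onto the candidate pool, applies the >= 3-protospacer and
#' > 10 kb retention filters, characterizes retained elements (ORFs,
#' termini), builds the gene-sharing network and classifies elements as
#' viruses or unclassified MGEs.
#'
#' @param hosts Host-clade contigs (FASTA path, named character vector or
#'   `DNAStringSet`).
#' @param pool Candidate MGE contigs.
#' @param offtarget Optional off-target-clade contigs for cross-clade
#'   repeat exclusion.
#' @param markers Optional hallmark marker proteins (`marker_id|class`
#'   headers); without them every retained element stays
#'   "unclassified-MGE".
#' @param source_labels Optional named vector mapping pool contig ids to
#'   an assembly-of-origin label.
#' @param max_mismatch,min_protospacers,min_len Spacer-match and
#'   retention thresholds (defaults 1, 3, 10000).
#' @param min_contigs Distinct-contig trust threshold for repeats.
#' @param sig_threshold Gene-sharing edge significance threshold.
#' @return list: `arrays`, `repeat_clusters`, `catalogue`, `hits`,
#'   `mges`, `tally`, `characterization`, `families`, `network`,
#'   `marker_hits`, `report`.
#' @export
run_pipeline <- function(hosts, pool, offtarget = NULL, markers = NULL,
                         source_labels = NULL, max_mismatch = 1L,
                         min_protospacers = 3L, min_len = 10000L,
                         min_contigs = 3L, sig_threshold = 1) {
  arrays <- detect_arrays(hosts)
  clusters <- cluster_repeats(arrays, min_contigs = min_contigs)
  if (!is.null(offtarget)) {
    off_arrays <- detect_arrays(offtarget)
    off_clusters <- cluster_repeats(off_arrays, min_contigs = 1L)
    clusters <- exclude_cross_clade(clusters, off_clusters)
  }
  catalogue <- build_spacer_catalogue(arrays, clusters)
  empty <- list(arrays = arrays, repeat_clusters = clusters,
                catalogue = catalogue, hits = empty_hits(),
                mges = NULL, tally = NULL, characterization = NULL,
                families = NULL, network = NULL,
                marker_hits = empty_marker_hits(),
                report = assign_status(
                  data.frame(contig = character(0), length = integer(0),
                             source = character(0), n_hits = integer(0),
                             n_protospacer_loci = integer(0),
                             retained = logical(0)),
                  empty_marker_hits()))
  if (!nrow(catalogue)) return(empty)
  hits <- find_protospacers(catalogue, pool, max_mismatch = max_mismatch)
  mges <- link_mges(hits, pool, source_labels = source_labels,
                    min_protospacers = min_protospacers, min_len = min_len)
  tally <- tally_by_source(mges)
  retained_ids <- mges$contig[mges$retained]
  characterization <- NULL; families <- NULL; network <- NULL
  marker_hits <- empty_marker_hits()
  if (length(retained_ids)) {
    characterization <- characterize_mges(pool, ids = retained_ids)
    if (nrow(characterization$orfs)) {
      families <- cluster_proteins(
        stats::setNames(characterization$orfs$aa,
                        characterization$orfs$orf_id),
        genomes = characterization$orfs$contig)
      network <- build_network(families, sig_threshold = sig_threshold)
      if (!is.null(markers))
        marker_hits <- scan_markers(characterization$orfs, markers)
    }
  }
  report <- assign_status(mges, marker_hits,
                          characterization = characterization,
                          network = network)
  list(arrays = arrays, repeat_clusters = clusters, catalogue = catalogue,
       hits = hits, mges = mges, tally = tally,
       characterization = characterization, families = families,
       network = network, marker_hits = marker_hits, report = report)
}
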