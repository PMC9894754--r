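# Gene-sharing network over MGE proteomes: greedy protein-family
# clustering, hypergeometric edge significance, connected-component
# clusters.
#
# The edge statistic asks: given that genome A carries a protein
# families and genome B carries b, out of n families in the whole
# dataset, how surprising is an overlap of c or more?  The one-sided
# hypergeometric tail is Bonferroni-scaled by the number of genome pairs
# tested, and an edge is kept when -log10(p * n_pairs) reaches the
# significance threshold (default 1, the convention of gene-sharing
# network tools).

#' Greedy centroid clustering of proteins into families
#'
#' Proteins are sorted by decreasing length (ties by identifier) and each
#' joins the first existing centroid it matches at `min_identity` over at
#' least `min_coverage` of the shorter sequence (local alignment,
#' BLOSUM62), else founds a new family.  A shared-k-mer screen (one exact
#' 8-mer) preselects candidate centroids before alignment, as in standard
#' greedy clustering tools; unrelated proteins essentially never share an
#' 8-mer, so the screen does not affect the clustering of homologs at
#' these thresholds.
#'
#' @param proteins Amino-acid sequences: FASTA path, named character
#'   vector or `AAStringSet`; names are protein ids.
#' @param genomes Optional character vector (same order) giving the source
#'   genome of each protein; defaults to the prefix of the protein id
#'   before the first "|".
#' @param min_identity Fraction of identical positions over the aligned
#'   region (default 0.5).
#' @param min_coverage Minimum aligned fraction of the shorter sequence
#'   (default 0.8).
#' @return data.frame: `protein_id`, `genome`, `family_id`.
#' @export
cluster_proteins <- function(proteins, genomes = NULL, min_identity = 0.5,
                             min_coverage = 0.8) {
  prot <- as_seq_chr(proteins, "AA", "proteins")
  if (!length(prot)) stop("no proteins supplied", call. = FALSE)
  if (is.null(genomes)) genomes <- sub("\\|.*$", "", names(prot))
  stopifnot(length(genomes) == length(prot))
  ord <- order(-nchar(prot), names(prot))

  kmer_k <- 8L
  index <- new.env(parent = emptyenv())   # 8-mer -> centroid indices
  centroid_seq <- character(0)
  assign_to <- integer(length(prot))
  for (i in ord) {
    p <- prot[[i]]
    kms <- if (nchar(p) >= kmer_k)
      unique(substring(p, 1:(nchar(p) - kmer_k + 1L), kmer_k:nchar(p)))
    else character(0)
    cand <- sort(unique(unlist(
      lapply(kms, function(km) index[[km]]), use.names = FALSE)))
    placed <- 0L
    for (j in cand) {
      al <- align_pair(p, centroid_seq[j])
      if (al$identity >= min_identity && al$coverage >= min_coverage) {
        placed <- j
        break
      }
    }
    if (!placed) {
      centroid_seq <- c(centroid_seq, p)
      placed <- length(centroid_seq)
      for (km in kms) index[[km]] <- c(index[[km]], placed)
    }
    assign_to[i] <- placed
  }
  data.frame(protein_id = names(prot), genome = genomes,
             family_id = sprintf("F%06d", assign_to))
}

.pkg_cache <- new.env(parent = emptyenv())

blosum62 <- function() {
  if (is.null(.pkg_cache$BLOSUM62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .pkg_cache$BLOSUM62 <- e$BLOSUM62
  }
  .pkg_cache$BLOSUM62
}

# Local alignment of two proteins; identity over aligned columns and
# coverage of the shorter sequence.
align_pair <- function(a, b) {
  if (a == b) return(list(identity = 1, coverage = 1))
  al <- Biostrings::pairwiseAlignment(
    pattern = a, subject = b, type = "local",
    substitutionMatrix = blosum62(),
    gapOpening = 10, gapExtension = 0.5)
  ident <- Biostrings::pid(al, type = "PID1") / 100
  shorter <- min(nchar(a), nchar(b))
  span <- if (nchar(a) <= nchar(b)) {
    Biostrings::width(Biostrings::pattern(al))
  } else {
    Biostrings::width(Biostrings::subject(al))
  }
  list(identity = ident, coverage = span / shorter)
}

#' Hypergeometric significance of a shared-gene count
#'
#' Upper-tail probability `P(X >= c)` for `X` hypergeometric with
#' population `n` families, `a` successes (families of genome A) and `b`
#' draws (families of genome B), by exact summation of the density.
#'
#' @param a,b Family counts of the two genomes.
#' @param c Observed shared family count.
#' @param n Total number of distinct families in the dataset.
#' @return The p-value, in (0, 1].
#' @export
edge_significance <- function(a, b, c, n) {
  vals <- c(a = a, b = b, c = c, n = n)
  if (any(vals != floor(vals)) || any(vals < 0))
    stop("a, b, c, n must be non-negative integers", call. = FALSE)
  if (c > min(a, b) || max(a, b) > n)
    stop("require 0 <= c <= min(a, b) <= n and a, b <= n", call. = FALSE)
  if (c == 0) return(1)
  sum(stats::dhyper(c:min(a, b), m = a, n = n - a, k = b))
}

#' Build the gene-sharing network and extract family-level clusters
#'
#' For every genome pair sharing at least one protein family the
#' hypergeometric tail p-value is computed and converted to a
#' significance score `-log10(p * n_pairs)`, with `n_pairs` the total
#' number of genome pairs tested (all unordered pairs).  Edges at or
#' above `sig_threshold` are kept and clusters are the connected
#' components of the kept-edge graph; genomes without a kept edge are
#' singleton clusters.  Cluster ids are canonical (ranked by the
#' lexicographically smallest member), so the structure is invariant
#' under input order and relabelling.
#'
#' @param families Output of [cluster_proteins()] (columns `genome`,
#'   `family_id`), or a named list mapping genome id to a character
#'   vector of family ids.
#' @param sig_threshold Minimum significance score for an edge (default 1).
#' @return list: `nodes` (data.frame `genome`, `n_families`, `cluster`),
#'   `edges` (data.frame `genome_a`, `genome_b`, `shared`, `p`, `score`,
#'   `kept`), `n_total_families`, `n_pairs`.
#' @export
build_network <- function(families, sig_threshold = 1) {
  fam_sets <- if (is.data.frame(families)) {
    lapply(split(families$family_id, families$genome), unique)
  } else {
    lapply(families, unique)
  }
  genomes <- sort(names(fam_sets))
  fam_sets <- fam_sets[genomes]
  n_total <- length(unique(unlist(fam_sets, use.names = FALSE)))
  n_g <- length(genomes)
  n_pairs <- n_g * (n_g - 1) / 2

  edges <- data.frame(genome_a = character(0), genome_b = character(0),
                      shared = integer(0), p = numeric(0),
                      score = numeric(0), kept = logical(0))
  if (n_g >= 2) {
    rows <- list()
    for (i in 1:(n_g - 1)) {
      for (j in (i + 1):n_g) {
        c_ij <- length(intersect(fam_sets[[i]], fam_sets[[j]]))
        if (c_ij < 1) next
        p <- edge_significance(length(fam_sets[[i]]),
                               length(fam_sets[[j]]), c_ij, n_total)
        score <- -log10(p * n_pairs)
        rows[[length(rows) + 1L]] <- data.frame(
          genome_a = genomes[i], genome_b = genomes[j], shared = c_ij,
          p = p, score = score, kept = score >= sig_threshold)
      }
    }
    if (length(rows)) edges <- do.call(rbind, rows)
  }

  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, n_g, name = genomes)
  kept <- edges[edges$kept, , drop = FALSE]
  if (nrow(kept))
    g <- igraph::add_edges(g, rbind(kept$genome_a, kept$genome_b))
  comp <- igraph::components(g)$membership
  # canonical cluster ids: rank of the smallest member name
  smallest <- tapply(genomes, comp[genomes], min)
  relabel <- stats::setNames(rank(smallest), names(smallest))
  cluster <- as.integer(relabel[as.character(comp[genomes])])
  nodes <- data.frame(genome = genomes,
                      n_families = lengths(fam_sets)[genomes],
                      cluster = cluster)
  rownames(nodes) <- NULL
  rownames(edges) <- NULL
  list(nodes = nodes, edges = edges, n_total_families = n_total,
       n_pairs = n_pairs)
}
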