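# Seeded synthetic host-virus communities with a ground-truth table.
#
# The generator states a small but complete world with the statistical
# structure the pipeline assumes: host contigs carrying repeat-spacer
# arrays whose spacers have mutated protospacer copies planted in a
# subset of viruses; viruses with family-structured shared gene content,
# hallmark marker genes and DTR/ITR/blunt termini; decoy contigs with no
# linkage; and off-target-clade hosts whose repeats are far from the
# target-clade repeat.  Background sequence is i.i.d. uniform A/C/G/T and
# mutations are substitutions only, matching the gap-free match model of
# the spacer mapper.  All randomness flows from the single config seed.

#' Configuration for a synthetic community
#'
#' Defaults describe the stated world used throughout the test suite:
#' five hosts each carrying two eight-spacer arrays on a shared
#' clade-specific repeat, ten 12-16 kb viruses in three family groups
#' sharing 20 core genes, 80% of viruses targeted (about ten planted
#' protospacer loci each), five decoys and two off-target-clade hosts.
#'
#' @param n_hosts,n_viruses,n_decoys,n_offtarget_hosts Contig counts.
#' @param arrays_per_host,spacers_per_array CRISPR array geometry; at
#'   least two spacers per array are required so every array has >= 3
#'   repeat copies.
#' @param spacer_len_range Integer length-2 vector, within 15-80 bp.
#' @param repeat_len Repeat length in bp (20-50).
#' @param viral_len_range Integer length-2 vector of virus lengths in bp.
#' @param spacer_mutation_rate Per-base substitution probability applied
#'   to protospacer copies planted in viruses.
#' @param frac_viruses_targeted Fraction of viruses receiving planted
#'   protospacer loci.
#' @param topology_mix Named proportions over DTR, ITR, none.
#' @param n_protein_families_core Core genes shared within each family
#'   group.
#' @param n_family_groups Number of virus family groups.
#' @param marker_injection Plant one hallmark structural gene per virus
#'   (one marker protein/class per family group).
#' @param host_len Host contig background length in bp.
#' @param terminal_repeat_len Planted DTR/ITR length in bp.
#' @param seed Integer seed driving every random draw.
#' @return A validated list of class `community_config`.
#' @export
community_config <- function(n_hosts = 5L, n_viruses = 10L, n_decoys = 5L,
                             n_offtarget_hosts = 2L, arrays_per_host = 2L,
                             spacers_per_array = 8L,
                             spacer_len_range = c(30L, 40L),
                             repeat_len = 30L,
                             viral_len_range = c(12000L, 16000L),
                             spacer_mutation_rate = 0,
                             frac_viruses_targeted = 0.8,
                             topology_mix = c(DTR = 0.4, ITR = 0.4,
                                              none = 0.2),
                             n_protein_families_core = 20L,
                             n_family_groups = 3L,
                             marker_injection = TRUE,
                             host_len = 20000L,
                             terminal_repeat_len = 60L,
                             seed = 1L) {
  cfg <- list(n_hosts = as.integer(n_hosts),
              n_viruses = as.integer(n_viruses),
              n_decoys = as.integer(n_decoys),
              n_offtarget_hosts = as.integer(n_offtarget_hosts),
              arrays_per_host = as.integer(arrays_per_host),
              spacers_per_array = as.integer(spacers_per_array),
              spacer_len_range = as.integer(spacer_len_range),
              repeat_len = as.integer(repeat_len),
              viral_len_range = as.integer(viral_len_range),
              spacer_mutation_rate = as.numeric(spacer_mutation_rate),
              frac_viruses_targeted = as.numeric(frac_viruses_targeted),
              topology_mix = topology_mix,
              n_protein_families_core = as.integer(n_protein_families_core),
              n_family_groups = as.integer(n_family_groups),
              marker_injection = isTRUE(marker_injection),
              host_len = as.integer(host_len),
              terminal_repeat_len = as.integer(terminal_repeat_len),
              seed = as.integer(seed))
  validate_config(cfg)
  class(cfg) <- "community_config"
  cfg
}

validate_config <- function(cfg) {
  counts <- c("n_hosts", "n_viruses", "n_decoys", "n_offtarget_hosts",
              "arrays_per_host", "spacers_per_array",
              "n_protein_families_core", "n_family_groups")
  for (f in counts)
    if (is.na(cfg[[f]]) || cfg[[f]] < 0)
      stop("config field '", f, "' must be a non-negative count",
           call. = FALSE)
  if (cfg$spacer_mutation_rate < 0 || cfg$spacer_mutation_rate > 1 ||
      cfg$frac_viruses_targeted < 0 || cfg$frac_viruses_targeted > 1)
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  r <- cfg$spacer_len_range
  if (length(r) != 2L || r[1] > r[2] || r[1] < 15L || r[2] > 80L)
    stop("spacer_len_range must be increasing and within [15, 80] bp",
         call. = FALSE)
  if (cfg$repeat_len < 20L || cfg$repeat_len > 50L)
    stop("repeat_len must lie in [20, 50] bp", call. = FALSE)
  v <- cfg$viral_len_range
  if (length(v) != 2L || v[1] > v[2] || v[1] < 500L)
    stop("viral_len_range must be increasing and at least 500 bp",
         call. = FALSE)
  tm <- cfg$topology_mix
  if (!setequal(names(tm), c("DTR", "ITR", "none")) || any(tm < 0) ||
      sum(tm) <= 0)
    stop("topology_mix must be non-negative proportions over DTR, ITR, none",
         call. = FALSE)
  n_arrays <- cfg$n_hosts * cfg$arrays_per_host
  if (n_arrays > 0 && cfg$spacers_per_array < 2L)
    stop("config infeasible: at least 2 spacers per array are needed ",
         "for the 3-repeat-copy minimum", call. = FALSE)
  k_t <- round(cfg$frac_viruses_targeted * cfg$n_viruses)
  slots <- n_arrays * cfg$spacers_per_array
  if (k_t > 0 && slots < 3L * k_t)
    stop("config infeasible: ", slots, " spacer slots cannot donate at ",
         "least three protospacers to each of ", k_t, " targeted viruses",
         call. = FALSE)
  invisible(cfg)
}

# Fixed reverse-translation table; L, K and H codons are chosen so that a
# protein starting MLKHK yields early stop codons in both shifted frames
# of the same strand, which protects planted genes from suppression by
# chance overlapping ORFs.
codon_table <- function() {
  code <- Biostrings::GENETIC_CODE
  sense <- code[code != "*"]
  tab <- vapply(sort(unique(sense)), function(aa)
    sort(names(sense)[sense == aa])[1], character(1))
  tab["L"] <- "TTA"; tab["K"] <- "AAA"; tab["H"] <- "CAT"; tab["M"] <- "ATG"
  tab
}

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
          "P", "Q", "R", "S", "T", "V", "W", "Y")

random_protein <- function(n_aa) {
  paste(c("M", "L", "K", "H", "K",
          sample(AA20, n_aa - 5L, replace = TRUE)), collapse = "")
}

# TAA guard + ATG..stop coding sequence for a protein (first aa must be M)
gene_cassette <- function(protein, tab) {
  aa <- strsplit(protein, "")[[1]]
  paste(c("TAA", tab[aa], "TAA"), collapse = "")
}

#' Generate a seeded synthetic community
#'
#' @param config A [community_config()].
#' @return list with elements `hosts`, `offtarget`, `pool`, `markers`
#'   (named character vectors; `pool` is viruses then decoys), `truth`
#'   (list of data.frames: `linked_pairs`, `protospacers`, `topology`,
#'   `family_group`, `marker_class`, `genes`, `spacers`), and `config`.
#'   Identical config and seed reproduce identical output.
#' @export
generate_community <- function(config) {
  stopifnot(inherits(config, "community_config"))
  validate_config(config)
  with_seed(config$seed, generate_community_impl(config))
}

generate_community_impl <- function(cfg) {
  tab <- codon_table()
  tl <- cfg$terminal_repeat_len
  k_t <- as.integer(round(cfg$frac_viruses_targeted * cfg$n_viruses))
  virus_ids <- sprintf("VIRUS%03d", seq_len(cfg$n_viruses))
  targeted <- if (k_t > 0) sort(sample(cfg$n_viruses, k_t)) else integer(0)

  # family groups and their shared gene content
  group_of <- if (cfg$n_viruses > 0 && cfg$n_family_groups > 0)
    rep_len(seq_len(cfg$n_family_groups), cfg$n_viruses) else
    integer(cfg$n_viruses)
  core_prots <- lapply(seq_len(cfg$n_family_groups), function(g)
    vapply(seq_len(cfg$n_protein_families_core), function(i)
      random_protein(sample(80:120, 1L)), character(1)))
  marker_classes <- rep_len(STRUCTURAL_CLASSES,
                            max(cfg$n_family_groups, 1L))
  marker_prots <- vapply(seq_len(cfg$n_family_groups), function(g)
    random_protein(150L), character(1))

  # spacer slots: host-major order, targeted viruses served round-robin
  n_slots <- cfg$n_hosts * cfg$arrays_per_host * cfg$spacers_per_array
  slot_host <- if (n_slots > 0)
    rep(seq_len(cfg$n_hosts),
        each = cfg$arrays_per_host * cfg$spacers_per_array) else integer(0)
  slot_array <- if (n_slots > 0)
    rep(rep(seq_len(cfg$arrays_per_host), each = cfg$spacers_per_array),
        cfg$n_hosts) else integer(0)
  slot_virus <- if (k_t > 0 && n_slots > 0)
    targeted[(seq_len(n_slots) - 1L) %% k_t + 1L] else
    rep(NA_integer_, n_slots)
  spacer_len <- if (n_slots > 0)
    sample(cfg$spacer_len_range[1]:cfg$spacer_len_range[2], n_slots,
           replace = TRUE) else integer(0)
  spacer_seq <- vapply(spacer_len, random_dna, character(1))
  spacer_id <- sprintf("HSP%05d", seq_len(n_slots))

  # viruses: plant family genes, marker gene, protospacer loci, termini
  pool <- character(0)
  truth_ps <- list(); truth_genes <- list()
  topo <- character(cfg$n_viruses)
  for (v in seq_len(cfg$n_viruses)) {
    lv <- sample(cfg$viral_len_range[1]:cfg$viral_len_range[2], 1L)
    vec <- sample(DNA_BASES, lv, replace = TRUE)
    g <- group_of[v]
    prots <- if (g > 0) core_prots[[g]] else character(0)
    names(prots) <- if (g > 0)
      sprintf("G%d_CORE%03d", g, seq_along(prots)) else character(0)
    if (cfg$marker_injection && g > 0) {
      mk <- stats::setNames(marker_prots[g], sprintf("G%d_MARKER", g))
      prots <- c(prots, mk)
    }
    cur <- 100L + sample(0:50, 1L)
    loci <- which(slot_virus == v)
    reserve <- length(loci) * (cfg$spacer_len_range[2] + 50L) + tl + 10L
    for (p in seq_along(prots)) {
      cass <- gene_cassette(prots[[p]], tab)
      start <- cur + sample(20:100, 1L)
      end <- start + nchar(cass) - 1L
      if (end > lv - reserve)
        stop("config infeasible: virus ", virus_ids[v], " of ", lv,
             " bp cannot hold its planted genes and protospacers",
             call. = FALSE)
      strand <- sample(c("+", "-"), 1L)
      ins <- if (strand == "+") cass else revcomp(cass)
      vec[start:end] <- strsplit(ins, "")[[1]]
      # coding region excludes the leading TAA guard (3 nt on the
      # cassette's own strand)
      if (strand == "+") {
        g_start <- start + 3L; g_end <- end
      } else {
        g_start <- start; g_end <- end - 3L
      }
      truth_genes[[length(truth_genes) + 1L]] <- data.frame(
        virus_id = virus_ids[v], gene_id = names(prots)[p],
        strand = strand, start = g_start - 1L, end = g_end,
        protein = prots[[p]])
      cur <- end
    }
    for (sl in loci) {
      start <- cur + sample(10:50, 1L)
      end <- start + spacer_len[sl] - 1L
      if (end > lv - tl - 5L)
        stop("config infeasible: virus ", virus_ids[v],
             " cannot hold all planted protospacer loci", call. = FALSE)
      strand <- sample(c("+", "-"), 1L)
      mut <- mutate_dna(spacer_seq[sl], cfg$spacer_mutation_rate)
      ins <- if (strand == "+") mut else revcomp(mut)
      vec[start:end] <- strsplit(ins, "")[[1]]
      truth_ps[[length(truth_ps) + 1L]] <- data.frame(
        virus_id = virus_ids[v], start = start - 1L, end = end,
        strand = strand, spacer_id = spacer_id[sl],
        host_id = sprintf("HOST%03d", slot_host[sl]))
      cur <- end
    }
    mix <- cfg$topology_mix[c("DTR", "ITR", "none")]
    topo[v] <- sample(c("DTR", "ITR", "none"), 1L, prob = mix)
    if (topo[v] == "DTR") {
      vec[(lv - tl + 1L):lv] <- vec[1:tl]
    } else if (topo[v] == "ITR") {
      vec[(lv - tl + 1L):lv] <-
        strsplit(revcomp(paste(vec[1:tl], collapse = "")), "")[[1]]
    }
    pool[virus_ids[v]] <- paste(vec, collapse = "")
  }
  for (d in seq_len(cfg$n_decoys)) {
    ld <- sample(cfg$viral_len_range[1]:cfg$viral_len_range[2], 1L)
    pool[sprintf("DECOY%03d", d)] <- random_dna(ld)
  }

  # hosts: shared clade repeat, planted arrays
  clade_repeat <- random_dna(cfg$repeat_len)
  hosts <- character(0)
  for (h in seq_len(cfg$n_hosts)) {
    vec <- sample(DNA_BASES, cfg$host_len, replace = TRUE)
    cur <- sample(200:800, 1L)
    for (a in seq_len(cfg$arrays_per_host)) {
      sl <- which(slot_host == h & slot_array == a)
      arr <- paste0(clade_repeat,
                    paste0(spacer_seq[sl], clade_repeat, collapse = ""))
      start <- cur + sample(200:600, 1L)
      end <- start + nchar(arr) - 1L
      if (end > cfg$host_len - 100L)
        stop("config infeasible: host contig of ", cfg$host_len,
             " bp cannot hold ", cfg$arrays_per_host, " arrays",
             call. = FALSE)
      vec[start:end] <- strsplit(arr, "")[[1]]
      cur <- end
    }
    hosts[sprintf("HOST%03d", h)] <- paste(vec, collapse = "")
  }

  # off-target clade: distinct repeat (>= 10 substitutions away), own
  # spacers, never planted anywhere
  offtarget <- character(0)
  if (cfg$n_offtarget_hosts > 0) {
    repeat {
      off_repeat <- random_dna(cfg$repeat_len)
      if (hamming(off_repeat, clade_repeat) >= 10L) break
    }
    for (h in seq_len(cfg$n_offtarget_hosts)) {
      vec <- sample(DNA_BASES, cfg$host_len, replace = TRUE)
      cur <- sample(200:800, 1L)
      for (a in seq_len(cfg$arrays_per_host)) {
        sp <- vapply(sample(cfg$spacer_len_range[1]:cfg$spacer_len_range[2],
                            cfg$spacers_per_array, replace = TRUE),
                     random_dna, character(1))
        arr <- paste0(off_repeat, paste0(sp, off_repeat, collapse = ""))
        start <- cur + sample(200:600, 1L)
        end <- start + nchar(arr) - 1L
        if (end > cfg$host_len - 100L)
          stop("config infeasible: off-target host cannot hold its arrays",
               call. = FALSE)
        vec[start:end] <- strsplit(arr, "")[[1]]
        cur <- end
      }
      offtarget[sprintf("OFFT%03d", h)] <- paste(vec, collapse = "")
    }
  }

  markers <- character(0)
  if (cfg$marker_injection && cfg$n_family_groups > 0 && cfg$n_viruses > 0) {
    markers <- stats::setNames(
      marker_prots,
      sprintf("MARKER_G%d|%s", seq_len(cfg$n_family_groups),
              marker_classes[seq_len(cfg$n_family_groups)]))
  }

  ps <- if (length(truth_ps)) do.call(rbind, truth_ps) else
    data.frame(virus_id = character(0), start = integer(0),
               end = integer(0), strand = character(0),
               spacer_id = character(0), host_id = character(0))
  linked <- unique(ps[, c("host_id", "virus_id")])
  linked <- linked[order(linked$host_id, linked$virus_id), , drop = FALSE]
  rownames(linked) <- NULL
  genes <- if (length(truth_genes)) do.call(rbind, truth_genes) else
    data.frame(virus_id = character(0), gene_id = character(0),
               strand = character(0), start = integer(0), end = integer(0),
               protein = character(0))
  truth <- list(
    linked_pairs = linked,
    protospacers = ps,
    topology = data.frame(virus_id = virus_ids, topology = topo),
    family_group = data.frame(virus_id = virus_ids, group = group_of),
    marker_class = data.frame(
      virus_id = virus_ids,
      marker_class = {
        mc <- rep(NA_character_, cfg$n_viruses)
        if (cfg$marker_injection && any(group_of > 0))
          mc[group_of > 0] <- marker_classes[group_of[group_of > 0]]
        mc
      }),
    genes = genes,
    spacers = data.frame(spacer_id = spacer_id,
                         host_id = sprintf("HOST%03d", slot_host),
                         array = slot_array, seq = spacer_seq,
                         virus_id = ifelse(is.na(slot_virus), NA_character_,
                                           virus_ids[slot_virus])))
  list(hosts = hosts, offtarget = offtarget, pool = pool,
       markers = markers, truth = truth, config = cfg)
}

#' Write a synthetic community to disk
#'
#' Writes `hosts.fna`, `offtarget.fna`, `pool.fna`, `markers.faa`, a flat
#' `config.txt` (key=value) and one TSV per truth-table component
#' (`truth_<name>.tsv`).
#'
#' @param community Output of [generate_community()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
write_community <- function(community, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta_chr(community$hosts, file.path(dir, "hosts.fna"))
  write_fasta_chr(community$offtarget, file.path(dir, "offtarget.fna"))
  write_fasta_chr(community$pool, file.path(dir, "pool.fna"))
  write_fasta_chr(community$markers, file.path(dir, "markers.faa"))
  cfg <- community$config
  keys <- setdiff(names(cfg), "topology_mix")
  lines <- c(vapply(keys, function(k)
    paste0(k, "=", paste(cfg[[k]], collapse = ",")), character(1)),
    paste0("topology_mix=",
           paste(names(cfg$topology_mix), cfg$topology_mix,
                 sep = ":", collapse = ",")))
  writeLines(lines, file.path(dir, "config.txt"))
  for (nm in names(community$truth)) {
    utils::write.table(community$truth[[nm]],
                       file.path(dir, paste0("truth_", nm, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       eol = "\n")
  }
  invisible(dir)
}

#' Precision and recall of predicted host-linked MGEs against truth
#'
#' Conventions: precision is 1 when nothing is predicted; recall is 1
#' when the truth set is empty.
#'
#' @param predicted Character vector of predicted MGE ids (e.g. retained
#'   contigs from [link_mges()]), or a data.frame whose rows are
#'   (clade, mge) pairs.
#' @param truth A community `truth` list (the targeted virus ids are
#'   used), or a character vector / pair data.frame of true ids.
#' @return Named numeric vector `c(precision, recall)`.
#' @export
evaluate_predictions <- function(predicted, truth) {
  as_ids <- function(x) {
    if (is.data.frame(x)) {
      unique(apply(x, 1L, paste, collapse = "\r"))
    } else unique(as.character(x))
  }
  truth_ids <- if (is.list(truth) && !is.data.frame(truth) &&
                   !is.null(truth$linked_pairs)) {
    unique(truth$linked_pairs$virus_id)
  } else as_ids(truth)
  pred_ids <- as_ids(predicted)
  tp <- length(intersect(pred_ids, truth_ids))
  c(precision = if (length(pred_ids)) tp / length(pred_ids) else 1,
    recall = if (length(truth_ids)) tp / length(truth_ids) else 1)
}
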