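# ORF calling and terminal-repeat topology.

# reverse-translate a protein with random synonymous codons (test-local,
# independent of the generator's table; draws from the ambient RNG)
encode_protein <- function(protein) {
  code <- Biostrings::GENETIC_CODE
  sense <- code[code != "*"]
  codons <- vapply(strsplit(protein, "")[[1]], function(aa) {
    opts <- names(sense)[sense == aa]
    opts[sample.int(length(opts), 1L)]
  }, character(1))
  codons[1] <- "ATG"
  paste(c(codons, "TAA"), collapse = "")
}

test_that("a single planted reverse-strand ORF is called exactly", {
  # barrier with stop codons in all three frames on both strands and no
  # start codons on the gene's strand, so no ORF reads through it
  barrier <- "TAACTAACTAACTAA"
  aa_pool <- setdiff(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "M")
  # A/C-only flanks have no start codon on the forward strand and no stop
  # on the reverse; any reverse ORF entering a flank dies in the barrier,
  # and 120 bp flanks are too short to host a >= 50 aa ORF on their own.
  # The gene body can still contain chance ORFs on the opposite strand,
  # so candidate fixtures are certified single-ORF by the independent
  # brute-force scan before use.
  ctg <- NULL
  for (try in 1:100) {
    set.seed(3100 + try)
    protein <- paste(c("M", sample(aa_pool, 149L, replace = TRUE)),
                     collapse = "")
    gene <- encode_protein(protein)        # 150 codons + stop = 453 nt
    flank <- function(n) paste(sample(c("A", "C"), n, replace = TRUE),
                               collapse = "")
    cand <- paste0(flank(120L), barrier, oracle_revcomp(gene), barrier,
                   flank(120L))
    if (nrow(oracle_orfs(cand, 50L)) == 1L) {
      ctg <- cand
      break
    }
  }
  expect_false(is.null(ctg))
  orfs <- call_orfs(ctg, min_len_aa = 50L)
  expect_equal(nrow(orfs), 1)
  expect_identical(orfs$strand, "-")
  expect_identical(orfs$aa, protein)
  expect_equal(nchar(orfs$aa), 150L)
  # revcomp(gene) occupies forward positions 136..588
  expect_equal(orfs$start, 135L)
  expect_equal(orfs$end, 135L + nchar(gene))
})

test_that("degenerate sequences are handled", {
  expect_equal(nrow(call_orfs(strrep("N", 600L))), 0)
  expect_error(call_orfs("ACGTXACGT"), "position 5")
  expect_error(call_orfs("AC"), "shorter")
})

test_that("all planted genes of a synthetic virus are recovered exactly", {
  cfg <- community_config(n_hosts = 3L, n_viruses = 2L, n_decoys = 0L,
                          n_family_groups = 1L,
                          n_protein_families_core = 7L,
                          marker_injection = TRUE, seed = 9L)
  comm <- generate_community(cfg)
  genes <- comm$truth$genes
  for (v in unique(genes$virus_id)) {
    orfs <- call_orfs(comm$pool[[v]])
    gv <- genes[genes$virus_id == v, ]
    expect_equal(nrow(gv), 8L)   # 7 core + 1 marker
    for (i in seq_len(nrow(gv))) {
      hit <- orfs$start == gv$start[i] & orfs$end == gv$end[i] &
        orfs$strand == gv$strand[i]
      expect_equal(sum(hit), 1L, label = paste(v, gv$gene_id[i]))
      expect_identical(orfs$aa[hit], gv$protein[i])
    }
  }
})

test_that("ORF calling matches the brute-force six-frame scan", {
  for (seed in 1:6) {
    set.seed(400 + seed)
    s <- random_dna_chr(3000L)
    if (seed > 3) {      # plant a gene to guarantee non-trivial content
      gene <- encode_protein(paste(c("M", sample(c("A", "G", "L", "S"),
                                                 80L, TRUE)),
                                   collapse = ""))
      substr(s, 501L, 500L + nchar(gene)) <- gene
    }
    got <- call_orfs(s, min_len_aa = 50L)
    exp <- oracle_orfs(s, min_len_aa = 50L)
    expect_equal(got[, c("start", "end", "strand", "aa")], exp,
                 label = paste("seed", seed))
  }
})

test_that("constructed termini are classified with their repeat length", {
  set.seed(32)
  core <- random_dna_chr(15000L)
  tr <- substr(core, 1, 45)
  dtr <- paste0(core, tr)
  got <- detect_termini(dtr)
  expect_identical(got$topology, "circular-DTR")
  expect_gte(got$tr_len, 45L)
  itr <- paste0(core, oracle_revcomp(tr))
  got2 <- detect_termini(itr)
  expect_identical(got2$topology, "linear-ITR")
  expect_gte(got2$tr_len, 45L)
  expect_error(detect_termini(random_dna_chr(30L), min_tr = 20L),
               "shorter")
})

test_that("random sequences are unresolved", {
  hits <- vapply(1:100, function(seed) {
    set.seed(500 + seed)
    detect_termini(random_dna_chr(15000L))$topology
  }, character(1))
  expect_true(all(hits == "unresolved"))
})

test_that("appending a prefix to the end always produces a DTR", {
  for (seed in 1:20) {
    set.seed(600 + seed)
    s <- random_dna_chr(sample(2000:8000, 1))
    k <- sample(20:200, 1)
    got <- detect_termini(paste0(s, substr(s, 1, k)))
    expect_identical(got$topology, "circular-DTR")
    expect_gte(got$tr_len, k)
  }
})

test_that("topology calls are invariant under reverse complementation", {
  for (seed in 1:20) {
    set.seed(700 + seed)
    core <- random_dna_chr(5000L)
    k <- sample(20:100, 1)
    s <- if (seed %% 2 == 0) paste0(core, substr(core, 1, k)) else
      paste0(core, oracle_revcomp(substr(core, 1, k)))
    a <- detect_termini(s)
    b <- detect_termini(oracle_revcomp(s))
    expect_identical(a$topology, b$topology)
    expect_equal(a$tr_len, b$tr_len)
  }
})

test_that("characterize_mges summarizes length, GC, ORFs and topology", {
  comm <- default_community()
  res <- default_pipeline()
  ch <- res$characterization
  expect_setequal(ch$summary$contig, res$mges$contig[res$mges$retained])
  expect_true(all(ch$summary$length ==
                    nchar(comm$pool[ch$summary$contig])))
  expect_true(all(ch$summary$completeness ==
                    ifelse(ch$summary$topology == "unresolved",
                           "unknown", "complete")))
  expect_true(all(ch$summary$n_orfs > 0))
})
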