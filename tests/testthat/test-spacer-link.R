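# Protospacer matching and the stringent retention filters.

test_that("planted spacers are found at the exact locus and strand", {
  set.seed(21)
  spacer <- random_dna_chr(34L)
  bg <- random_dna_chr(20000L)
  pos <- 7001L
  fwd <- bg
  substr(fwd, pos, pos + 33L) <- spacer
  hits <- find_protospacers(c(SP1 = spacer), c(ctg = fwd),
                            suppress_arrays = FALSE)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$start, pos - 1L)
  expect_equal(hits$end, pos - 1L + 34L)
  expect_identical(hits$strand, "+")
  expect_equal(hits$mismatches, 0L)
  expect_identical(hits[, names(hits)],
                   oracle_hamming_hits(c(SP1 = spacer), c(ctg = fwd)))

  # reverse-strand plant: strand "-", coordinates on the forward frame
  rev <- bg
  substr(rev, pos, pos + 33L) <- oracle_revcomp(spacer)
  h2 <- find_protospacers(c(SP1 = spacer), c(ctg = rev),
                          suppress_arrays = FALSE)
  expect_equal(nrow(h2), 1)
  expect_identical(h2$strand, "-")
  expect_equal(h2$start, pos - 1L)
  expect_identical(h2[, names(h2)],
                   oracle_hamming_hits(c(SP1 = spacer), c(ctg = rev)))
})

test_that("the mismatch threshold is sharp", {
  set.seed(22)
  spacer <- random_dna_chr(34L)
  mut2 <- spacer
  for (p in c(5L, 20L)) substr(mut2, p, p) <-
      setdiff(c("A", "C", "G", "T"), substr(spacer, p, p))[1]
  ctg <- paste0(random_dna_chr(500L), mut2, random_dna_chr(500L))
  expect_equal(nrow(find_protospacers(c(S = spacer), c(c = ctg),
                                      max_mismatch = 1L,
                                      suppress_arrays = FALSE)), 0)
  expect_equal(nrow(find_protospacers(c(S = spacer), c(c = ctg),
                                      max_mismatch = 2L,
                                      suppress_arrays = FALSE)), 1)
})

test_that("hits inside CRISPR arrays on the target are suppressed", {
  set.seed(23)
  px <- planted_array_contig(flank = 6000L)
  spacers <- stats::setNames(px$spacers, paste0("S", 1:3))
  raw <- find_protospacers(spacers, c(tgt = px$contig),
                           suppress_arrays = FALSE)
  expect_equal(nrow(raw), 3)
  masked <- find_protospacers(spacers, c(tgt = px$contig),
                              suppress_arrays = TRUE)
  expect_equal(nrow(masked), 0)
})

test_that("short spacers are rejected with a warning", {
  set.seed(24)
  expect_warning(
    h <- find_protospacers(c(A = "ACGTACGTACGT", B = random_dna_chr(30L)),
                           c(c = random_dna_chr(1000L))),
    "shorter than 15")
  expect_true(all(h$spacer_id == "B"))
})

test_that("retention needs >= 3 distinct loci and > 10 kb", {
  set.seed(25)
  pool <- c(a = random_dna_chr(12400L), b = random_dna_chr(45000L),
            c = random_dna_chr(9800L))
  mk_hits <- function(ctg, starts) data.frame(
    spacer_id = sprintf("S%d", seq_along(starts)), contig = ctg,
    start = starts, end = starts + 34L, strand = "+", mismatches = 0L)
  hits <- rbind(mk_hits("a", c(100L, 500L, 900L)),
                mk_hits("b", c(100L, 500L)),
                mk_hits("c", c(100L, 400L, 700L, 1000L, 1300L)))
  mges <- link_mges(hits, pool)
  expect_identical(mges$retained,
                   c(TRUE, FALSE, FALSE))  # a: 3 loci/12.4 kb passes
  # repeated targeting of one locus counts once
  dup <- rbind(mk_hits("b", c(100L, 500L)),
               data.frame(spacer_id = "S9", contig = "b", start = 100L,
                          end = 134L, strand = "+", mismatches = 1L))
  expect_equal(link_mges(dup, pool)$n_protospacer_loci, 2L)
  expect_error(link_mges(mk_hits("zzz", 1L), pool), "absent from the pool")
})

test_that("per-source tallies count retained elements only", {
  mges <- data.frame(contig = c("m1", "m2", "m3", "m4"),
                     length = c(12000L, 15000L, 20000L, 11000L),
                     source = c("P", "P", "G", "G"),
                     n_hits = c(4L, 3L, 5L, 1L),
                     n_protospacer_loci = c(4L, 3L, 5L, 1L),
                     retained = c(TRUE, TRUE, TRUE, FALSE))
  tal <- tally_by_source(mges)
  expect_equal(tal$n_retained[tal$source == "P"], 2L)
  expect_equal(tal$n_retained[tal$source == "G"], 1L)
  expect_equal(attr(tal, "total"), 3L)
  none <- mges; none$retained <- FALSE
  expect_equal(attr(tally_by_source(none), "total"), 0L)
})

test_that("a fully targeted synthetic community is fully retained", {
  cfg <- community_config(n_hosts = 3L, n_viruses = 5L, n_decoys = 2L,
                          frac_viruses_targeted = 1.0,
                          spacer_mutation_rate = 0, seed = 7L)
  comm <- generate_community(cfg)
  res <- run_pipeline(comm$hosts, comm$pool, offtarget = comm$offtarget)
  expect_equal(attr(res$tally, "total"), 5L)
  expect_setequal(res$mges$contig[res$mges$retained],
                  unique(comm$truth$linked_pairs$virus_id))
})

test_that("hit and retention counts are monotone in their thresholds", {
  for (seed in 1:6) {
    set.seed(300 + seed)
    spacer <- random_dna_chr(35L)
    ctg <- random_dna_chr(30000L)
    for (k in 0:3) {           # plant copies with 0..3 substitutions
      mut <- spacer
      if (k > 0) for (p in sample(35L, k)) substr(mut, p, p) <-
          setdiff(c("A", "C", "G", "T"), substr(spacer, p, p))[1]
      pos <- 2000L + k * 5000L
      substr(ctg, pos, pos + 34L) <- mut
    }
    counts <- vapply(0:3, function(mm)
      nrow(find_protospacers(c(S = spacer), c(c = ctg), max_mismatch = mm,
                             suppress_arrays = FALSE)), integer(1))
    expect_true(all(diff(counts) >= 0), label = paste("seed", seed))

    hits <- find_protospacers(c(S = spacer), c(c = ctg), max_mismatch = 3L,
                              suppress_arrays = FALSE)
    retained <- vapply(1:5, function(mp)
      sum(link_mges(hits, c(c = ctg), min_protospacers = mp)$retained),
      integer(1))
    expect_true(all(diff(retained) <= 0))
    by_len <- vapply(c(10000L, 20000L, 40000L), function(ml)
      sum(link_mges(hits, c(c = ctg), min_len = ml)$retained), integer(1))
    expect_true(all(diff(by_len) <= 0))
  }
})
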