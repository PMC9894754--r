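# Array detection, repeat trust filters, and the spacer catalogue.

test_that("a planted repeat-spacer array is recovered exactly", {
  set.seed(11)
  px <- planted_array_contig(flank = 500L, repeat_len = 30L,
                             n_spacers = 3L, spacer_len = 34L)
  arr <- detect_arrays(c(ctg = px$contig))
  expect_equal(nrow(arr), 1)
  expect_equal(arr$n_copies, 4L)
  expect_identical(arr$repeat_seq, px$repeat_seq)
  expect_equal(arr$start, px$start)
  expect_equal(arr$end, px$end)
  sp <- arr$spacers[[1]]
  expect_identical(sp$seq, px$spacers)
  # spacer coordinates: repeat at start, then alternating
  expect_equal(sp$start[1], px$start + 30L)
  expect_equal(sp$end[1], px$start + 30L + 34L)
})

test_that("contigs without tandem repeats yield no arrays", {
  set.seed(12)
  expect_equal(nrow(detect_arrays(c(r = random_dna_chr(10000L)))), 0)
  # two copies only: below the 3-copy minimum
  R <- random_dna_chr(30L)
  two <- paste0(random_dna_chr(400L), R, random_dna_chr(40L), R,
                random_dna_chr(400L))
  expect_equal(nrow(detect_arrays(c(two = two))), 0)
})

test_that("repeat trust requires three distinct contigs", {
  set.seed(13)
  R <- random_dna_chr(30L)
  mk <- function() paste0(random_dna_chr(300L), R, random_dna_chr(34L), R,
                          random_dna_chr(36L), R, random_dna_chr(300L))
  three <- c(c1 = mk(), c2 = mk(), c3 = mk())
  cl3 <- cluster_repeats(detect_arrays(three))
  expect_equal(nrow(cl3), 1)
  expect_true(cl3$trusted)
  expect_equal(cl3$n_distinct_contigs, 3L)

  cl2 <- cluster_repeats(detect_arrays(three[1:2]))
  expect_false(cl2$trusted)

  # three arrays all on one contig count as one contig
  one <- c(c1 = paste0(mk(), random_dna_chr(200L), mk(),
                       random_dna_chr(200L), mk()))
  cl1 <- cluster_repeats(detect_arrays(one))
  expect_equal(nrow(cl1), 1)
  expect_equal(cl1$n_distinct_contigs, 1L)
  expect_false(cl1$trusted)
})

test_that("cross-clade repeat exclusion removes only matching clusters", {
  set.seed(14)
  R1 <- random_dna_chr(30L)
  R2 <- random_dna_chr(30L)
  target <- data.frame(cluster_id = 1:2,
                       consensus = canon_chr(c(R1, R2)),
                       n_members = c(3L, 3L), n_distinct_contigs = c(3L, 3L),
                       trusted = TRUE, members = I(list(1:3, 4:6)))
  expect_identical(exclude_cross_clade(target, target[0, ]), target)

  off <- data.frame(cluster_id = 1L, consensus = canon_chr(R1),
                    n_members = 1L, n_distinct_contigs = 1L,
                    trusted = FALSE, members = I(list(7L)))
  kept <- exclude_cross_clade(target, off)
  expect_equal(nrow(kept), 1)
  expect_identical(kept$consensus, canon_chr(R2))

  # Hamming distance 12 on length 30 is 60% identity: retained
  R1_far <- R1
  pos <- sample(30L, 12L)
  for (p in pos) substr(R1_far, p, p) <- setdiff(c("A", "C", "G", "T"),
                                                 substr(R1, p, p))[1]
  off_far <- off
  off_far$consensus <- canon_chr(R1_far)
  expect_equal(nrow(exclude_cross_clade(target["2", , drop = FALSE],
                                        off_far)), 1)
})

test_that("spacer catalogue canonicalizes, deduplicates and is idempotent", {
  set.seed(15)
  s1 <- "ACGTACGTACGTACGTAC"
  arrs <- fake_arrays(list(c1 = list(s1, random_dna_chr(20L)),
                           c2 = list(oracle_revcomp(s1)),
                           c3 = list(random_dna_chr(22L))))
  cl <- data.frame(cluster_id = 1L, consensus = "X", n_members = 3L,
                   n_distinct_contigs = 3L, trusted = TRUE,
                   members = I(list(seq_len(nrow(arrs)))))
  cat1 <- build_spacer_catalogue(arrs, cl)
  # s1 and its reverse complement collapse to one entry
  expect_equal(attr(cat1, "n_unique"), 3L)
  expect_equal(sum(cat1$n_copies), 4L)
  expect_identical(cat1$seq, sort(unique(canon_chr(cat1$seq))))
  # untrusted clusters donate nothing
  cl$trusted <- FALSE
  expect_equal(attr(build_spacer_catalogue(arrs, cl), "n_unique"), 0L)
})

test_that("the catalogue is invariant under reverse-complementing contigs", {
  for (seed in 1:5) {
    set.seed(100 + seed)
    ctgs <- c(a = planted_array_contig()$contig,
              b = planted_array_contig(n_spacers = 4L)$contig)
    fwd <- detect_arrays(ctgs)
    rev <- detect_arrays(stats::setNames(oracle_revcomp(ctgs),
                                         names(ctgs)))
    trust_all <- function(arr) {
      cl <- cluster_repeats(arr, min_contigs = 1L)
      build_spacer_catalogue(arr, cl)
    }
    c_f <- trust_all(fwd)
    c_r <- trust_all(rev)
    expect_identical(c_f$seq, c_r$seq)
    expect_identical(attr(c_f, "n_unique"), attr(c_r, "n_unique"))
  }
})

test_that("detection matches the exhaustive tandem scan on small contigs", {
  for (seed in 1:8) {
    set.seed(200 + seed)
    ctg <- if (seed <= 2) {
      random_dna_chr(4000L)                       # no planted array
    } else if (seed <= 6) {
      planted_array_contig(flank = 1200L,
                           repeat_len = sample(20:45, 1),
                           n_spacers = sample(2:5, 1),
                           spacer_len = sample(16:70, 1))$contig
    } else {
      paste0(planted_array_contig(flank = 400L)$contig,
             planted_array_contig(flank = 400L, n_spacers = 4L)$contig)
    }
    got <- detect_arrays(c(x = ctg))
    exp <- oracle_detect_arrays(ctg)
    expect_equal(nrow(got), nrow(exp), label = paste("seed", seed))
    if (nrow(got)) {
      expect_equal(got$start, exp$start)
      expect_equal(got$end, exp$end)
      expect_equal(got$n_copies, exp$n_copies)
      expect_identical(got$repeat_seq, exp$repeat_seq)
    }
  }
})

test_that("planted arrays are fully recovered in the default community", {
  comm <- default_community()
  res <- default_pipeline()
  planted <- sort(unique(canon_chr(comm$truth$spacers$seq)))
  expect_identical(res$catalogue$seq, planted)
  expect_equal(attr(res$catalogue, "n_unique"), length(planted))
})
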