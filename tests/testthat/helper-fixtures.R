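# In-code fixtures shared across test files.  Heavier objects are built
# once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

# the default stated-world community at seed 7, reused by several files
default_community <- function() {
  if (is.null(.fixtures$comm7))
    .fixtures$comm7 <- generate_community(community_config(seed = 7L))
  .fixtures$comm7
}

default_pipeline <- function() {
  if (is.null(.fixtures$pipe7)) {
    comm <- default_community()
    .fixtures$pipe7 <- run_pipeline(comm$hosts, comm$pool,
                                    offtarget = comm$offtarget,
                                    markers = comm$markers)
  }
  .fixtures$pipe7
}

# a smaller, faster community for parameterised loops
small_config <- function(seed, ...) {
  community_config(n_hosts = 3L, n_viruses = 4L, n_decoys = 2L,
                   n_offtarget_hosts = 1L, arrays_per_host = 1L,
                   spacers_per_array = 6L,
                   viral_len_range = c(10500L, 12500L),
                   n_protein_families_core = 6L, n_family_groups = 2L,
                   seed = seed, ...)
}

canon_chr <- function(x) {
  rc <- oracle_revcomp(x)
  ifelse(x <= rc, x, rc)
}

# hand-built arrays table in the detect_arrays() schema: one array per
# contig entry, each a list of spacer sequences; coordinates are synthetic
fake_arrays <- function(spec) {
  rows <- lapply(seq_along(spec), function(i) {
    sp <- unlist(spec[[i]])
    pos <- cumsum(c(100L, nchar(sp) + 30L))
    data.frame(contig = names(spec)[i], start = 100L,
               end = as.integer(100L + sum(nchar(sp)) + 30L * (length(sp) + 1L)),
               n_copies = length(sp) + 1L,
               repeat_seq = strrep("A", 30L),
               spacers = I(list(data.frame(
                 seq = sp, start = pos[seq_along(sp)],
                 end = pos[seq_along(sp)] + nchar(sp)))))
  })
  do.call(rbind, rows)
}

# a contig with one planted exact-repeat array; boundary characters are
# forced to differ across copies so the array cannot extend by chance
planted_array_contig <- function(flank = 500L, repeat_len = 30L,
                                 n_spacers = 3L, spacer_len = 34L) {
  R <- random_dna_chr(repeat_len)
  spacers <- vapply(seq_len(n_spacers), function(i) {
    s <- random_dna_chr(spacer_len)
    # distinct first/last characters block repeat extension
    bases <- c("A", "C", "G", "T")
    substr(s, 1, 1) <- bases[(i - 1L) %% 4L + 1L]
    substr(s, spacer_len, spacer_len) <- bases[i %% 4L + 1L]
    s
  }, character(1))
  left <- random_dna_chr(flank)
  right <- random_dna_chr(flank)
  substr(left, flank, flank) <- "A"
  substr(right, 1, 1) <- "C"
  # ensure the flanks do not extend the array: spacer boundary chars
  # already differ, so any shared char across all copies is impossible
  arr <- paste0(R, paste0(spacers, R, collapse = ""))
  list(contig = paste0(left, arr, right),
       repeat_seq = R, spacers = spacers,
       start = flank, end = flank + nchar(arr))  # 0-based half-open
}
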