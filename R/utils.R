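# Shared low-level helpers: sequence containers, strings, seeded RNG.

DNA_BASES <- c("A", "C", "G", "T")

#' @importFrom Biostrings DNAStringSet AAStringSet readDNAStringSet
#'   readAAStringSet reverseComplement writeXStringSet
NULL

# Coerce FASTA-ish input to a named uppercase character vector.
# Accepts a file path, a (named) character vector, or an XStringSet.
# Headers are tokenized at the first whitespace.
as_seq_chr <- function(x, type = c("DNA", "AA"), what = "sequences") {
  type <- match.arg(type)
  if (methods::is(x, "XStringSet")) {
    out <- as.character(x)
  } else if (is.character(x) && length(x) == 1L && !grepl("[^ -~]", x) &&
             file.exists(x) && !dir.exists(x)) {
    set <- tryCatch(
      if (type == "DNA") readDNAStringSet(x) else readAAStringSet(x),
      error = function(e) stop("failed to parse FASTA '", x, "': ",
                               conditionMessage(e), call. = FALSE))
    out <- as.character(set)
  } else if (is.character(x)) {
    out <- x
  } else {
    stop("cannot interpret ", what, ": supply a FASTA path, ",
         "a named character vector or an XStringSet", call. = FALSE)
  }
  if (length(out) && (is.null(names(out)) || any(!nzchar(names(out)))))
    stop("all ", what, " must be named (FASTA headers)", call. = FALSE)
  names(out) <- sub("\\s.*$", "", names(out))
  toupper(out)
}

revcomp <- function(x) {
  if (!length(x)) return(character(0))
  as.character(reverseComplement(DNAStringSet(x)))
}

# Strand-canonical form: lexicographic minimum of a sequence and its
# reverse complement.
canonical_seq <- function(x) {
  rc <- revcomp(x)
  ifelse(x <= rc, x, rc)
}

hamming <- function(a, b) {
  stopifnot(nchar(a) == nchar(b))
  sum(utf8ToInt(a) != utf8ToInt(b))
}

# Identity between two sequences allowing for small length differences:
# 1 - levenshtein/max(len). `both_strands` also tries the reverse
# complement of `b` and keeps the better orientation.
seq_identity <- function(a, b, both_strands = FALSE) {
  d <- utils::adist(a, b)[1, 1]
  id <- 1 - d / max(nchar(a), nchar(b))
  if (both_strands) {
    d2 <- utils::adist(a, revcomp(b))[1, 1]
    id <- max(id, 1 - d2 / max(nchar(a), nchar(b)))
  }
  id
}

random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

# Per-base substitution at rate `rate`; substitutions only, never to the
# same base, no indels.
mutate_dna <- function(x, rate) {
  if (rate <= 0 || !nchar(x)) return(x)
  chars <- strsplit(x, "")[[1]]
  hit <- which(stats::runif(length(chars)) < rate)
  for (i in hit) chars[i] <- sample(setdiff(DNA_BASES, chars[i]), 1L)
  paste(chars, collapse = "")
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Deterministic multi-FASTA writer (60-column wrap).
write_fasta_chr <- function(seqs, path, width = 60L) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    n <- nchar(s)
    if (n == 0L) next
    starts <- seq(1L, n, by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, n)), con)
  }
  invisible(path)
}

gc_fraction <- function(x) {
  if (!nchar(x)) return(NA_real_)
  chars <- strsplit(x, "")[[1]]
  mean(chars %in% c("G", "C"))
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labellings of the same items;
#' 1 means identical partitions, 0 is the expected value for unrelated ones.
#' Used to score recovery of planted virus family groups by the gene-sharing
#' network.
#'
#' @param a,b Vectors of cluster labels, equal length, aligned by item.
#' @return A single numeric value.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  if (!length(a)) return(1)
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(length(a))
  expected <- sum_a * sum_b / n2
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == expected) return(1)
  (sum_ij - expected) / (max_idx - expected)
}
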