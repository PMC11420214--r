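# Shared fixtures and independent oracles used across test files.

RNA <- c("A", "C", "G", "U")

random_rna <- function(L, seed = NULL) {
  draw <- function() paste(sample(RNA, L, replace = TRUE), collapse = "")
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

# Substitute exactly n distinct positions of s (seeded).
mutate_n <- function(s, n, seed) {
  withr::with_seed(seed, {
    ch <- strsplit(s, "", fixed = TRUE)[[1]]
    for (i in sample(length(ch), n)) ch[i] <- sample(setdiff(RNA, ch[i]), 1)
    paste(ch, collapse = "")
  })
}

# Independent position-wise Hamming distance (loop, no vectorization).
hamming_oracle <- function(a, b) {
  d <- 0L
  for (i in seq_len(nchar(a))) {
    if (substr(a, i, i) != substr(b, i, i)) d <- d + 1L
  }
  d
}

# Brute-force all-pairs Hamming-1 neighbor lists for a sequence set.
neighbors_oracle <- function(seqs) {
  out <- lapply(seqs, function(a) {
    sort(seqs[vapply(seqs, hamming_oracle, integer(1), a = a) == 1L])
  })
  names(out) <- seqs
  out
}

# Exhaustive enumeration of all secondary structures (WC + GU, min_loop)
# of a short sequence; returns the maximum pair count. Independent of the
# dynamic program: plain recursion over "first position unpaired or paired
# with each admissible partner".
pairable <- function(a, b) {
  paste0(a, b) %in% c("AU", "UA", "GC", "CG", "GU", "UG")
}

max_pairs_oracle <- function(sequence, min_loop = 3L) {
  ch <- strsplit(sequence, "", fixed = TRUE)[[1]]
  rec <- function(idx) {
    if (length(idx) == 0) return(0L)
    i <- idx[1]
    best <- rec(idx[-1])
    for (pos in seq_along(idx)[-1]) {
      j <- idx[pos]
      if (j - i > min_loop && pairable(ch[i], ch[j])) {
        inside <- idx[idx > i & idx < j]
        outside <- idx[idx > j]
        best <- max(best, 1L + rec(inside) + rec(outside))
      }
    }
    best
  }
  rec(seq_along(ch))
}

# Random balanced dot-bracket string (non-crossing) for round-trip tests.
random_dotbracket <- function(L, p_open = 0.3, seed) {
  withr::with_seed(seed, {
    chars <- rep(".", L)
    open <- integer(0)
    for (i in seq_len(L)) {
      r <- runif(1)
      if (r < p_open && i < L) {
        chars[i] <- "("; open <- c(open, i)
      } else if (r < 2 * p_open && length(open) && i - open[length(open)] > 3) {
        chars[i] <- ")"; open <- open[-length(open)]
      }
    }
    for (i in open) chars[i] <- "."
    paste(chars, collapse = "")
  })
}

table1_path <- function() {
  system.file("extdata", "peak_sequence_table.tsv", package = "ribolandscape")
}
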