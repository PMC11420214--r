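#' @keywords internal
"_PACKAGE"

RNA_ALPHABET <- c("A", "C", "G", "U")

#' Normalize RNA sequences
#'
#' Uppercases and transliterates T to U (with a warning, since input is
#' expected to be RNA). Errors on characters outside A/C/G/U after
#' transliteration.
#'
#' @param x character vector of sequences.
#' @return character vector of uppercase RNA sequences.
#' @export
normalize_rna <- function(x) {
  x <- toupper(as.character(x))
  if (any(grepl("T", x, fixed = TRUE))) {
    warning("DNA-style 'T' found; transliterating to 'U'")
    x <- chartr("T", "U", x)
  }
  bad <- grepl("[^ACGU]", x)
  if (any(bad)) {
    stop("invalid RNA characters in sequence(s): ",
         paste(utils::head(x[bad], 3), collapse = ", "))
  }
  x
}

#' Hamming distance between two equal-length sequences
#'
#' Number of positions at which the two strings differ. This is the distance
#' metric used throughout: mutational distances between ribozyme variants are
#' substitution counts over the fixed-length variable region.
#'
#' @param a,b character scalars of equal nchar.
#' @return integer distance.
#' @examples
#' hamming_distance("ACGU", "ACGA")
#' @export
hamming_distance <- function(a, b) {
  if (nchar(a) != nchar(b)) {
    stop("sequences must have equal length (", nchar(a), " vs ", nchar(b), ")")
  }
  sum(utf8ToInt(a) != utf8ToInt(b))
}

# Character matrix (n x L) from a vector of equal-length sequences; rows keep
# names. Used for vectorized distance computations over whole populations.
seq_char_matrix <- function(seqs) {
  L <- unique(nchar(seqs))
  if (length(L) != 1) stop("sequences must all have the same length")
  m <- matrix(unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE),
              nrow = length(seqs), ncol = L, byrow = TRUE)
  rownames(m) <- seqs
  m
}

# Hamming distance from every row of a sequence vector to one reference.
hamming_to_reference <- function(seqs, reference) {
  if (!length(seqs)) return(integer(0))
  m <- seq_char_matrix(seqs)
  if (ncol(m) != nchar(reference)) stop("reference length mismatch")
  ref <- strsplit(reference, "", fixed = TRUE)[[1]]
  as.integer(rowSums(m != matrix(ref, nrow(m), ncol(m), byrow = TRUE)))
}
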