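#' Per-round sequence count table
#'
#' Container for round-by-round high-throughput sequencing counts of the
#' variable region: a long data frame with columns `round` (integer label,
#' 0 = starting library), `sequence` (uppercase RNA, all the same length) and
#' `count` (reads, >= 1).
#'
#' @param df data frame with columns `round`, `sequence`, `count`.
#' @return object of class `seq_count_table` (a data frame).
#' @export
seq_count_table <- function(df) {
  stopifnot(is.data.frame(df), all(c("round", "sequence", "count") %in% names(df)))
  df <- data.frame(round = as.integer(df$round),
                   sequence = normalize_rna(df$sequence),
                   count = as.numeric(df$count),
                   stringsAsFactors = FALSE)
  if (any(df$count < 1)) stop("counts must be >= 1")
  if (length(unique(nchar(df$sequence))) > 1) {
    stop("all sequences in a count table must have equal length")
  }
  if (anyDuplicated(df[c("round", "sequence")])) {
    stop("duplicate (round, sequence) entries")
  }
  df <- df[order(df$round, -df$count, df$sequence), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("seq_count_table", "data.frame")
  df
}

#' @export
print.seq_count_table <- function(x, ...) {
  cat(sprintf("Sequence count table: %d rounds (%s), %d distinct sequences, %d nt\n",
              length(unique(x$round)),
              paste(range(x$round), collapse = "-"),
              length(unique(x$sequence)), nchar(x$sequence[1])))
  NextMethod()
}

#' @describeIn seq_count_table rounds present in the table, sorted.
#' @param table a `seq_count_table`.
#' @export
table_rounds <- function(table) sort(unique(table$round))

# Named count vector for one round, error if the round is absent.
round_counts <- function(table, round) {
  stopifnot(inherits(table, "seq_count_table"))
  sel <- table$round == round
  if (!any(sel)) stop("round ", round, " not present in table")
  stats::setNames(table$count[sel], table$sequence[sel])
}

#' Fractional abundance of a sequence in a round
#'
#' Read count of `sequence` divided by the total reads in `round`; 0 if the
#' sequence was not observed in that round.
#'
#' @param table a [seq_count_table()].
#' @param round round label.
#' @param sequence character scalar.
#' @return fraction in \[0, 1\].
#' @export
fractional_abundance <- function(table, round, sequence) {
  counts <- round_counts(table, round)
  n <- counts[sequence]
  if (is.na(n)) n <- 0
  unname(n / sum(counts))
}

#' Read a pre-tabulated count table from TSV
#'
#' Expects columns `round`, `sequence`, `count` (any order, header required).
#'
#' @param path file path.
#' @return a [seq_count_table()].
#' @export
read_count_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  seq_count_table(df)
}

#' Write a count table to TSV
#'
#' @param table a [seq_count_table()].
#' @param path file path.
#' @export
write_count_tsv <- function(table, path) {
  utils::write.table(as.data.frame(table), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Build a count table from per-round FASTA/FASTQ files
#'
#' Each file holds the (already trimmed) variable-region reads of one round;
#' identical reads are tallied. Files are parsed with Biostrings.
#'
#' @param paths character vector of FASTA/FASTQ paths.
#' @param rounds integer round labels, same length as `paths`.
#' @param format "fasta" or "fastq".
#' @return a [seq_count_table()].
#' @export
read_round_reads <- function(paths, rounds, format = c("fasta", "fastq")) {
  format <- match.arg(format)
  stopifnot(length(paths) == length(rounds))
  pieces <- lapply(seq_along(paths), function(i) {
    reads <- as.character(Biostrings::readBStringSet(paths[i], format = format))
    tab <- table(chartr("T", "U", toupper(reads)))
    data.frame(round = rounds[i], sequence = names(tab),
               count = as.integer(tab), stringsAsFactors = FALSE)
  })
  seq_count_table(do.call(rbind, pieces))
}

#' Trim constant flanks from full-length reads
#'
#' Extracts the variable region between two constant anchor sequences
#' (exact match); reads where either anchor is missing are dropped.
#'
#' @param reads character vector of full-length reads.
#' @param anchor5,anchor3 constant sequences flanking the variable region.
#' @return character vector of variable-region sequences.
#' @export
trim_variable_region <- function(reads, anchor5, anchor3) {
  s <- regexpr(anchor5, reads, fixed = TRUE)
  e <- regexpr(anchor3, reads, fixed = TRUE)
  keep <- s > 0 & e > 0 & e > s + nchar(anchor5) - 1
  substr(reads[keep], s[keep] + nchar(anchor5), e[keep] - 1)
}
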