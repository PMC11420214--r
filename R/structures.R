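#' Parse a dot-bracket secondary structure
#'
#' Standard Vienna dialect: `.` unpaired, matched `()` base pairs (optionally
#' `[]`/`{}` for extended pairs when `allow_pseudoknots = TRUE`). Pairing is
#' extracted with a stack per bracket type; round-trips through
#' [format_dotbracket()] reproduce the input text exactly.
#'
#' @param dotbracket dot-bracket string.
#' @param sequence optional RNA sequence of equal length.
#' @param allow_pseudoknots accept `[]`/`{}` bracket layers.
#' @return object of class `secondary_structure`: `sequence`, `dotbracket`,
#'   `pairs` (2-column matrix of 1-based positions, i < j).
#' @export
parse_dotbracket <- function(dotbracket, sequence = NULL,
                             allow_pseudoknots = FALSE) {
  chars <- strsplit(dotbracket, "", fixed = TRUE)[[1]]
  openers <- c("(", if (allow_pseudoknots) c("[", "{"))
  closers <- c(")", if (allow_pseudoknots) c("]", "}"))
  bad <- !(chars %in% c(".", openers, closers))
  if (any(bad)) stop("invalid dot-bracket character: ", chars[which(bad)[1]])
  if (!is.null(sequence)) {
    sequence <- normalize_rna(sequence)
    if (nchar(sequence) != length(chars)) {
      stop("sequence and structure lengths differ")
    }
  }
  pairs <- matrix(integer(0), ncol = 2)
  for (layer in seq_along(openers)) {
    stack <- integer(0)
    for (i in seq_along(chars)) {
      if (chars[i] == openers[layer]) {
        stack <- c(stack, i)
      } else if (chars[i] == closers[layer]) {
        if (!length(stack)) stop("unbalanced brackets at position ", i)
        pairs <- rbind(pairs, c(stack[length(stack)], i))
        stack <- stack[-length(stack)]
      }
    }
    if (length(stack)) stop("unbalanced brackets: unclosed '", openers[layer], "'")
  }
  if (nrow(pairs)) pairs <- pairs[order(pairs[, 1]), , drop = FALSE]
  colnames(pairs) <- c("i", "j")
  structure(list(sequence = sequence, dotbracket = dotbracket, pairs = pairs),
            class = "secondary_structure")
}

#' Serialize a secondary structure back to dot-bracket text
#'
#' Rebuilds the string from the base-pair set (not from the stored text):
#' non-crossing pairs use `()`, and crossing pairs are pushed to `[]`/`{}`
#' layers in order of first fit. For structures parsed from standard input
#' this reproduces the original text exactly.
#'
#' @param structure a `secondary_structure`.
#' @return dot-bracket string.
#' @export
format_dotbracket <- function(structure) {
  L <- nchar(structure$dotbracket)
  p <- structure$pairs
  chars <- rep(".", L)
  openers <- c("(", "[", "{"); closers <- c(")", "]", "}")
  layers <- list(matrix(numeric(0), ncol = 2),
                 matrix(numeric(0), ncol = 2),
                 matrix(numeric(0), ncol = 2))
  crosses <- function(pair, mat) {
    if (!nrow(mat)) return(FALSE)
    any((mat[, 1] < pair[1] & pair[1] < mat[, 2] & mat[, 2] < pair[2]) |
          (pair[1] < mat[, 1] & mat[, 1] < pair[2] & pair[2] < mat[, 2]))
  }
  for (r in seq_len(nrow(p))) {
    for (l in 1:3) {
      if (!crosses(p[r, ], layers[[l]])) {
        layers[[l]] <- rbind(layers[[l]], p[r, ])
        chars[p[r, 1]] <- openers[l]
        chars[p[r, 2]] <- closers[l]
        break
      }
    }
  }
  paste(chars, collapse = "")
}

#' @export
print.secondary_structure <- function(x, ...) {
  if (!is.null(x$sequence)) cat(x$sequence, "\n")
  cat(x$dotbracket, " (", nrow(x$pairs), " pairs)\n", sep = "")
  invisible(x)
}

pair_keys <- function(structure) {
  p <- structure$pairs
  if (!nrow(p)) return(character(0))
  paste(p[, 1], p[, 2], sep = ":")
}

#' Base-pair distance between two structures
#'
#' Size of the symmetric difference between the two base-pair sets — the
#' number of pairs present in one structure but not the other. Symmetric and
#' satisfies the triangle inequality, making it a metric on structures of a
#' given length.
#'
#' @param s1,s2 `secondary_structure` objects of equal length.
#' @return integer distance.
#' @export
bp_distance <- function(s1, s2) {
  if (nchar(s1$dotbracket) != nchar(s2$dotbracket)) {
    stop("structures must have equal length")
  }
  k1 <- pair_keys(s1); k2 <- pair_keys(s2)
  length(setdiff(k1, k2)) + length(setdiff(k2, k1))
}

WC_WOBBLE <- c(AU = TRUE, UA = TRUE, GC = TRUE, CG = TRUE, GU = TRUE, UG = TRUE)

can_pair <- function(a, b) isTRUE(WC_WOBBLE[paste0(a, b)])

#' Maximum base-pairing structure (Nussinov dynamic programming)
#'
#' Baseline secondary-structure predictor: maximizes the number of
#' Watson-Crick + G·U wobble pairs with a minimum hairpin loop of `min_loop`
#' unpaired nucleotides, by the classic O(L^3) dynamic program. Traceback is
#' deterministic — position i pairs with the smallest j that achieves the
#' optimum — so identical inputs always give identical structures. Intended
#' as a self-contained baseline; structures from thermodynamic engines can be
#' supplied as dot-bracket input instead.
#'
#' @param sequence RNA string, length >= min_loop + 2.
#' @param min_loop minimum unpaired nucleotides in a hairpin loop.
#' @return a `secondary_structure`.
#' @examples
#' nussinov_fold("GGGAAAACCC")$dotbracket
#' @export
nussinov_fold <- function(sequence, min_loop = 3L) {
  sequence <- normalize_rna(sequence)
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  L <- length(chars)
  if (L < min_loop + 2L) stop("sequence shorter than min_loop + 2")
  M <- matrix(0L, L, L)
  for (span in (min_loop + 1L):(L - 1L)) {
    for (i in seq_len(L - span)) {
      j <- i + span
      best <- M[i + 1L, j]  # i unpaired
      # i paired with some k in (i+min_loop, j]
      for (k in (i + min_loop + 1L):j) {
        if (can_pair(chars[i], chars[k])) {
          left <- if (k > i + 1L) M[i + 1L, k - 1L] else 0L
          right <- if (k < j) M[k + 1L, j] else 0L
          best <- max(best, 1L + left + right)
        }
      }
      M[i, j] <- best
    }
  }
  db <- rep(".", L)
  pairs <- list()
  traceback <- function(i, j) {
    while (i < j) {
      if (j - i < min_loop + 1L) return(invisible())
      if (M[i, j] == M[i + 1L, j]) { i <- i + 1L; next }
      for (k in (i + min_loop + 1L):j) {
        if (!can_pair(chars[i], chars[k])) next
        left <- if (k > i + 1L) M[i + 1L, k - 1L] else 0L
        right <- if (k < j) M[k + 1L, j] else 0L
        if (M[i, j] == 1L + left + right) {
          db[i] <<- "("; db[k] <<- ")"
          pairs[[length(pairs) + 1L]] <<- c(i, k)
          if (k > i + 1L) traceback(i + 1L, k - 1L)
          i <- k + 1L
          break
        }
      }
    }
  }
  traceback(1L, L)
  parse_dotbracket(paste(db, collapse = ""), sequence)
}

#' Group structures along a path into folds
#'
#' Single left-to-right pass over an ordered series of structures (e.g. the
#' predicted structures of consecutive mutational intermediates): a new fold
#' label opens whenever the base-pair distance from the current fold's
#' representative (its first member) exceeds `threshold`. Records where each
#' new fold first appears, capturing abrupt structural transitions along the
#' path.
#'
#' @param structures list of `secondary_structure` objects, equal lengths.
#' @param threshold base-pair distance above which a structure starts a new
#'   fold (default 8 pairs).
#' @return list of class `fold_series`: `fold_labels` (integers from 1),
#'   `jump_indices` (1-based positions where each label after the first
#'   begins), `n_folds`, `representatives` (index of each fold's first
#'   member), `dist_to_prev` (base-pair distance to the preceding structure).
#' @export
group_folds <- function(structures, threshold = 8) {
  stopifnot(length(structures) >= 1, threshold >= 0)
  labels <- integer(length(structures))
  labels[1] <- 1L
  reps <- 1L
  jumps <- integer(0)
  for (i in seq_along(structures)[-1]) {
    rep_idx <- reps[length(reps)]
    if (bp_distance(structures[[i]], structures[[rep_idx]]) > threshold) {
      labels[i] <- labels[i - 1L] + 1L
      reps <- c(reps, i)
      jumps <- c(jumps, i)
    } else {
      labels[i] <- labels[i - 1L]
    }
  }
  dprev <- c(NA_integer_,
             vapply(seq_along(structures)[-1], function(i) {
               bp_distance(structures[[i]], structures[[i - 1L]])
             }, integer(1)))
  structure(list(fold_labels = labels, jump_indices = jumps,
                 n_folds = length(reps), representatives = reps,
                 dist_to_prev = dprev),
            class = "fold_series")
}

#' Read a FASTA-like multi-record dot-bracket file
#'
#' Records of the form header line (`>name`), sequence line, structure line.
#'
#' @param path file path.
#' @return named list of `secondary_structure` objects.
#' @export
read_dotbracket_file <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  hdr <- grep("^>", lines)
  if (!length(hdr) || any(diff(hdr) != 3)) {
    stop("expected repeating 3-line records: >name / sequence / structure")
  }
  out <- lapply(hdr, function(h) {
    parse_dotbracket(lines[h + 2L], lines[h + 1L])
  })
  names(out) <- sub("^>\\s*", "", lines[hdr])
  out
}

#' Write a fold-series report as TSV
#'
#' @param folds a [group_folds()] result.
#' @param path file path.
#' @return the path, invisibly.
#' @export
write_fold_tsv <- function(folds, path) {
  df <- data.frame(index = seq_along(folds$fold_labels),
                   fold_label = folds$fold_labels,
                   bp_distance_to_prev = folds$dist_to_prev,
                   is_jump = seq_along(folds$fold_labels) %in% folds$jump_indices)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
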