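#' Doped-library model
#'
#' Describes a partially randomized ("doped") library of variants of a parent
#' sequence: each of `length` positions mutates independently with probability
#' `mutation_rate`, choosing uniformly among the `alphabet_size - 1` non-parent
#' bases (so each specific non-parent base appears with probability
#' `mutation_rate / (alphabet_size - 1)` per position). `library_size` is the
#' number of molecules in the synthesized pool, kept as a double so values
#' around 1e15 are representable.
#'
#' Defaults describe a 40-nt catalytic domain doped at 21% per position (7%
#' each non-parent base) in a pool of ~1e15 molecules.
#'
#' @param length positive integer, number of mutagenized positions (nt).
#' @param mutation_rate per-position mutation probability in \[0, 1\].
#' @param alphabet_size integer >= 2, nucleotide alphabet size.
#' @param library_size positive number of molecules in the pool.
#' @return an object of class `doped_library_model`.
#' @examples
#' m <- doped_library_model()
#' parent_probability(m)
#' @export
doped_library_model <- function(length = 40L, mutation_rate = 0.21,
                                alphabet_size = 4L, library_size = 1e15) {
  length <- as.integer(length)
  stopifnot(length >= 1L, alphabet_size >= 2L, library_size > 0)
  if (mutation_rate < 0 || mutation_rate > 1) {
    stop("mutation_rate must be in [0, 1]")
  }
  structure(
    list(length = length, mutation_rate = mutation_rate,
         alphabet_size = as.integer(alphabet_size),
         library_size = as.numeric(library_size)),
    class = "doped_library_model"
  )
}

#' @export
print.doped_library_model <- function(x, ...) {
  cat(sprintf(
    "Doped library: %d nt at %.3g%% per-position mutation (%.3g%% per base), %.3g molecules\n",
    x$length, 100 * x$mutation_rate,
    100 * x$mutation_rate / (x$alphabet_size - 1), x$library_size))
  invisible(x)
}

#' Probability that a library member is the unmutated parent
#'
#' Closed form `(1 - mutation_rate)^length`. For the default 40-nt / 21%
#' library this is 8.04e-5, i.e. 0.008% of the pool is wild type.
#'
#' @param model a [doped_library_model()].
#' @return probability (numeric scalar).
#' @export
parent_probability <- function(model) {
  stopifnot(inherits(model, "doped_library_model"))
  (1 - model$mutation_rate)^model$length
}

#' Probability mass function of the mutation count
#'
#' The number of mutated positions in a library member is
#' Binomial(length, mutation_rate).
#'
#' @param model a [doped_library_model()].
#' @param k integer vector of mutation counts.
#' @return numeric vector of probabilities.
#' @export
mutation_count_pmf <- function(model, k = 0:model$length) {
  stopifnot(inherits(model, "doped_library_model"))
  stats::dbinom(k, size = model$length, prob = model$mutation_rate)
}

#' Upper-tail probability of the mutation count
#'
#' P(number of mutations >= k_min) for a library member, evaluated via the
#' log-space binomial survival function so that tails as small as 1e-11 (the
#' fraction of the default library carrying 28+ mutations) do not underflow.
#'
#' @param model a [doped_library_model()].
#' @param k_min integer in \[0, length\].
#' @return probability (numeric scalar).
#' @examples
#' mutation_count_tail(doped_library_model(), 28)  # ~3.9e-11
#' @export
mutation_count_tail <- function(model, k_min) {
  stopifnot(inherits(model, "doped_library_model"))
  k_min <- as.integer(k_min)
  if (k_min < 0 || k_min > model$length) {
    stop("k_min must be in [0, length]")
  }
  if (k_min == 0L) return(1)
  exp(stats::pbinom(k_min - 1L, size = model$length,
                    prob = model$mutation_rate,
                    lower.tail = FALSE, log.p = TRUE))
}

#' Expected number of molecules with at least k_min mutations
#'
#' `library_size * mutation_count_tail(model, k_min)`; for the default library
#' roughly 4e4 molecules carry 28+ mutations and under 2e7 carry 25+.
#'
#' @inheritParams mutation_count_tail
#' @return expected molecule count (numeric scalar).
#' @export
expected_pool_size <- function(model, k_min) {
  stopifnot(inherits(model, "doped_library_model"))
  if (k_min > model$length) return(0)
  model$library_size * mutation_count_tail(model, k_min)
}

AVOGADRO <- 6.02214076e23

#' Molecule count of an amount of substance
#'
#' @param amount_mol amount in moles (>= 0).
#' @return number of molecules.
#' @examples
#' molecule_count(3e-9)  # 3 nmol of library RNA, ~1.8e15 molecules
#' @export
molecule_count <- function(amount_mol) {
  if (any(amount_mol < 0)) stop("amount must be >= 0")
  amount_mol * AVOGADRO
}

#' Nearest order of magnitude
#'
#' Rounds to the nearest power of ten on the log scale, the granularity at
#' which pool complexities are usually quoted (e.g. 1.8e15 -> 1e15).
#'
#' @param x positive numeric vector.
#' @return numeric vector of powers of ten (0 maps to 0).
#' @export
nearest_order_of_magnitude <- function(x) {
  ifelse(x == 0, 0, 10^round(log10(x)))
}

#' Round to one significant figure
#'
#' Reporting helper matching the precision at which library statistics are
#' usually printed; full-precision values are always available from the
#' underlying functions.
#'
#' @param x numeric vector.
#' @return numeric vector rounded to one significant figure.
#' @export
signif1 <- function(x) signif(x, 1)

#' One-call doped-library report
#'
#' @param model a [doped_library_model()].
#' @param k_min tail threshold (mutation count).
#' @return list with `parent_probability`, `tail`, `expected_count`, at full
#'   precision, plus one-significant-figure versions.
#' @export
library_report <- function(model, k_min) {
  p <- parent_probability(model)
  tail <- mutation_count_tail(model, k_min)
  n <- expected_pool_size(model, k_min)
  list(parent_probability = p, tail = tail, expected_count = n,
       rounded = list(parent_probability = signif1(p), tail = signif1(tail),
                      expected_count = signif1(n)))
}
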