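#' Greedy abundance-ranked Hamming clustering of one selection round
#'
#' Sorts sequences into clusters of closely related variants around "peak
#' sequences". Sequences are visited in descending read count (ties broken by
#' lexicographic sequence order); each unassigned sequence eligible to be a
#' peak opens a new cluster and absorbs every still-unassigned sequence within
#' `radius` substitutions of it. The procedure is fully determined by the
#' counts and the tie-break, so clustering is invariant to input order.
#'
#' The default radius of 10 suits selections whose dominant clusters sit 13+
#' mutations apart, so that clusters are well separated and membership is
#' unambiguous.
#'
#' @param table a [seq_count_table()].
#' @param round round label to cluster.
#' @param radius maximum Hamming distance of a member to its peak (>= 0).
#' @param min_reads sequences with fewer reads than this cannot seed a cluster
#'   (they can still join one as members).
#' @return list of clusters, each a list with `peak`, `members` (character
#'   vector including the peak), `radius`, `reads` (summed member reads),
#'   `peak_reads`.
#' @export
greedy_cluster <- function(table, round, radius = 10L, min_reads = 1L) {
  stopifnot(radius >= 0)
  counts <- round_counts(table, round)
  if (!length(counts)) stop("empty round")
  ord <- order(-counts, names(counts))
  seqs <- names(counts)[ord]
  counts <- counts[ord]
  m <- seq_char_matrix(seqs)
  assigned <- rep(FALSE, length(seqs))
  clusters <- list()
  for (i in seq_along(seqs)) {
    if (assigned[i] || counts[i] < min_reads) next
    cand <- which(!assigned)
    d <- rowSums(m[cand, , drop = FALSE] !=
                   matrix(m[i, ], length(cand), ncol(m), byrow = TRUE))
    members <- cand[d <= radius]
    assigned[members] <- TRUE
    clusters[[length(clusters) + 1L]] <- list(
      peak = seqs[i],
      members = seqs[members],
      radius = as.integer(radius),
      reads = sum(counts[members]),
      peak_reads = unname(counts[i])
    )
  }
  clusters
}

#' Cluster abundance report
#'
#' Summarizes a clustering as the familiar peak-sequence table: per cluster,
#' the peak sequence, its overall fractional abundance (% of all reads in the
#' round), the whole cluster's overall abundance, and the peak's share within
#' its cluster.
#'
#' @param clusters result of [greedy_cluster()].
#' @param table,round the clustered table and round (for the read total).
#' @return data frame with columns `peak`, `n_members`,
#'   `pct_peak_within_cluster`, `pct_peak_overall`, `pct_cluster_overall`.
#' @export
cluster_report <- function(clusters, table, round) {
  total <- sum(round_counts(table, round))
  df <- do.call(rbind, lapply(clusters, function(cl) {
    data.frame(peak = cl$peak,
               n_members = length(cl$members),
               pct_peak_within_cluster = 100 * cl$peak_reads / cl$reads,
               pct_peak_overall = 100 * cl$peak_reads / total,
               pct_cluster_overall = 100 * cl$reads / total,
               stringsAsFactors = FALSE)
  }))
  rownames(df) <- NULL
  df
}

#' Peak share within its cluster from printed overall percentages
#'
#' Recovers the "% of peak within cluster" column from the two overall
#' percentage columns of a peak-sequence abundance table:
#' `100 * peak_overall / cluster_overall`.
#'
#' @param peak_overall overall \% abundance of the peak sequence.
#' @param cluster_overall overall \% abundance of its whole cluster (> 0).
#' @return percentage in (0, 100\].
#' @examples
#' within_cluster_share(20.59, 25.23)  # 81.61
#' @export
within_cluster_share <- function(peak_overall, cluster_overall) {
  if (any(cluster_overall <= 0)) stop("cluster_overall must be > 0")
  if (any(peak_overall > cluster_overall + 1e-9)) {
    stop("peak_overall cannot exceed cluster_overall")
  }
  100 * peak_overall / cluster_overall
}

#' Merge clusters by peak sequence
#'
#' Some published cluster tallies merge related clusters (e.g. counting two
#' peaks as one subpopulation); this merges the named clusters into one,
#' keeping the more abundant peak.
#'
#' @param clusters result of [greedy_cluster()].
#' @param peaks character vector of peak sequences to merge.
#' @return updated cluster list.
#' @export
merge_clusters <- function(clusters, peaks) {
  idx <- which(vapply(clusters, function(cl) cl$peak %in% peaks, logical(1)))
  if (length(idx) < 2) return(clusters)
  parts <- clusters[idx]
  lead <- parts[[which.max(vapply(parts, `[[`, numeric(1), "peak_reads"))]]
  merged <- list(peak = lead$peak,
                 members = unique(unlist(lapply(parts, `[[`, "members"))),
                 radius = max(vapply(parts, `[[`, integer(1), "radius")),
                 reads = sum(vapply(parts, `[[`, numeric(1), "reads")),
                 peak_reads = lead$peak_reads)
  out <- clusters[-idx]
  out[[length(out) + 1L]] <- merged
  out
}

#' Distance-from-reference abundance spectrum
#'
#' For one round, sums fractional abundance over all sequences at each Hamming
#' distance from a reference (typically the parent ribozyme), i.e. the
#' marginal distribution of mutational distance in the population. Values sum
#' to 1 over distances.
#'
#' @param table a [seq_count_table()].
#' @param round round label.
#' @param reference reference sequence, same length as the table's sequences.
#' @return named numeric vector; names are distances "0".."L" (all distances
#'   up to the sequence length, including zeros).
#' @export
distance_spectrum <- function(table, round, reference) {
  reference <- normalize_rna(reference)
  counts <- round_counts(table, round)
  if (nchar(names(counts)[1]) != nchar(reference)) {
    stop("reference length does not match table sequences")
  }
  d <- hamming_to_reference(names(counts), reference)
  L <- nchar(reference)
  spec <- vapply(0:L, function(k) sum(counts[d == k]), numeric(1))
  stats::setNames(spec / sum(counts), 0:L)
}

#' Round-by-distance spectrum matrix
#'
#' @param table a [seq_count_table()].
#' @param reference reference sequence.
#' @return matrix (rounds x distances) of fractional abundances.
#' @export
spectrum_matrix <- function(table, reference) {
  rounds <- table_rounds(table)
  t(vapply(rounds, function(r) distance_spectrum(table, r, reference),
           numeric(nchar(normalize_rna(reference)) + 1L)))
}

#' Abundance trajectories with read-threshold censoring
#'
#' Tracks each sequence's raw count and fractional abundance across all
#' rounds. A round is censored when the sequence has `min_reads` reads or
#' fewer (the conventional display rule "only sequences with >100 reads are
#' shown" corresponds to the default `min_reads = 100`). A reemergence is a
#' censored-to-uncensored transition after the sequence had already been above
#' threshold once, i.e. number of uncensored runs minus one.
#'
#' @param table a [seq_count_table()].
#' @param sequences character vector of sequences to track.
#' @param min_reads censoring threshold (count <= min_reads is censored).
#' @return list of per-sequence trajectories: `sequence`, `rounds`, `counts`,
#'   `abundance`, `censored` (logical), `n_reemergences`.
#' @export
trajectory <- function(table, sequences, min_reads = 100L) {
  rounds <- table_rounds(table)
  totals <- vapply(rounds, function(r) sum(round_counts(table, r)), numeric(1))
  present <- unique(table$sequence)
  lapply(normalize_rna(sequences), function(s) {
    if (!s %in% present) {
      warning("sequence not observed in any round: ", s)
    }
    counts <- vapply(rounds, function(r) {
      n <- round_counts(table, r)[s]
      if (is.na(n)) 0 else unname(n)
    }, numeric(1))
    censored <- counts <= min_reads
    runs <- rle(!censored)
    n_up <- sum(runs$values)
    list(sequence = s, rounds = rounds, counts = counts,
         abundance = counts / totals, censored = censored,
         n_reemergences = max(0L, n_up - 1L))
  })
}
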