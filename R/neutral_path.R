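#' All single-substitution mutants of a sequence
#'
#' Every sequence at Hamming distance exactly 1 from the input (3 per
#' position for the RNA alphabet), excluding the input itself.
#'
#' @param sequence RNA string.
#' @return character vector of length `3 * nchar(sequence)`.
#' @export
single_mutants <- function(sequence) {
  sequence <- normalize_rna(sequence)
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  out <- character(3L * length(chars))
  k <- 0L
  for (i in seq_along(chars)) {
    for (b in setdiff(RNA_ALPHABET, chars[i])) {
      k <- k + 1L
      tmp <- chars
      tmp[i] <- b
      out[k] <- paste(tmp, collapse = "")
    }
  }
  out
}

#' Hamming-1 mutational graph over observed sequences
#'
#' Implicit graph whose nodes are the (equal-length) sequences observed in
#' sequencing data and whose edges connect pairs at Hamming distance 1.
#' Neighbor queries enumerate the 3L single mutants of a node and test
#' membership in a hash index — never an all-pairs distance scan — so the
#' graph scales to large observed sets.
#'
#' @param observed character vector of equal-length sequences.
#' @return object of class `mutational_graph` with `nodes` (sorted unique
#'   sequences) and an internal hash index.
#' @export
build_graph <- function(observed) {
  nodes <- sort(unique(normalize_rna(observed)))
  if (length(unique(nchar(nodes))) > 1) stop("mixed sequence lengths")
  idx <- new.env(hash = TRUE, parent = emptyenv(), size = length(nodes))
  for (s in nodes) assign(s, TRUE, envir = idx)
  structure(list(nodes = nodes, index = idx), class = "mutational_graph")
}

#' @export
print.mutational_graph <- function(x, ...) {
  cat(sprintf("Mutational graph: %d nodes (%d nt), Hamming-1 adjacency\n",
              length(x$nodes), nchar(x$nodes[1])))
  invisible(x)
}

#' @describeIn build_graph membership test for one sequence.
#' @param graph a `mutational_graph`.
#' @param sequence character scalar.
#' @export
has_node <- function(graph, sequence) {
  exists(sequence, envir = graph$index, inherits = FALSE)
}

#' @describeIn build_graph sorted neighbor list (observed single mutants).
#' @export
graph_neighbors <- function(graph, sequence) {
  mut <- single_mutants(sequence)
  mut[vapply(mut, has_node, logical(1), graph = graph)]
}

# Breadth-first search from `source` over the Hamming-1 graph; neighbors are
# expanded in lexicographic order so parent pointers (and hence reconstructed
# paths) are deterministic. Returns distances and parents for reachable nodes.
bfs_from <- function(graph, source) {
  dist <- new.env(hash = TRUE, parent = emptyenv())
  parent <- new.env(hash = TRUE, parent = emptyenv())
  assign(source, 0L, envir = dist)
  frontier <- source
  while (length(frontier)) {
    nxt <- character(0)
    for (u in frontier) {
      for (v in graph_neighbors(graph, u)) {
        if (!exists(v, envir = dist, inherits = FALSE)) {
          assign(v, get(u, envir = dist) + 1L, envir = dist)
          assign(v, u, envir = parent)
          nxt <- c(nxt, v)
        }
      }
    }
    frontier <- sort(unique(nxt))
  }
  list(dist = dist, parent = parent)
}

reconstruct_path <- function(bfs, terminal) {
  path <- terminal
  while (exists(terminal, envir = bfs$parent, inherits = FALSE)) {
    terminal <- get(terminal, envir = bfs$parent)
    path <- c(terminal, path)
  }
  path
}

#' Shortest mutational path toward a target sequence
#'
#' Single-source shortest paths (unit edge weights, so Dijkstra reduces to
#' breadth-first search) from `source` over the observed-sequence graph.
#' Among all reachable nodes the terminal is the one closest in Hamming
#' distance to `final_target`; ties are broken by shorter path, then
#' lexicographically, so the result is deterministic. This realizes the
#' search for the observed path that "most closely resembles" a target that
#' may itself be absent from the data.
#'
#' @param graph a [build_graph()] result.
#' @param source sequence in the graph.
#' @param final_target target sequence (need not be in the graph).
#' @return list with `path` (consecutive Hamming distance 1), `terminal`,
#'   `terminal_gap` (Hamming distance terminal -> target), `reached_target`
#'   (TRUE iff the terminal is the target or one of its single mutants) and
#'   `path_length` (edges).
#' @export
shortest_path_toward <- function(graph, source, final_target) {
  source <- normalize_rna(source)
  final_target <- normalize_rna(final_target)
  if (!has_node(graph, source)) stop("source is not a node of the graph")
  bfs <- bfs_from(graph, source)
  reach <- ls(bfs$dist)
  gap <- hamming_to_reference(reach, final_target)
  plen <- vapply(reach, get, integer(1), envir = bfs$dist)
  ord <- order(gap, plen, reach)
  terminal <- reach[ord[1]]
  list(path = reconstruct_path(bfs, terminal),
       terminal = terminal,
       terminal_gap = gap[ord[1]],
       reached_target = gap[ord[1]] <= 1L,
       path_length = unname(plen[ord[1]]))
}

#' Bidirectional endpoint refinement between two sequences
#'
#' Alternately runs [shortest_path_toward()] from each endpoint toward the
#' other side's current frontier, accumulating intermediates from both sides
#' (a-side first, then b-side, mirroring a search that walks in from both
#' ends of a long mutational gap). A side's frontier only moves when it
#' strictly reduces the Hamming gap between the frontiers, so the residual
#' gap never increases; the procedure stops when the frontiers meet, no
#' progress is made, or `max_iterations` is exhausted.
#'
#' Endpoints absent from the graph are added as virtual nodes.
#'
#' @param graph a [build_graph()] result.
#' @param end_a,end_b endpoint sequences.
#' @param max_iterations maximum alternation rounds.
#' @return list with `a_side` and `b_side` paths (from each endpoint to its
#'   frontier terminal), `frontier_a`, `frontier_b`, `gap` (residual Hamming
#'   distance between frontiers) and `converged` (gap == 0).
#' @export
bidirectional_refine <- function(graph, end_a, end_b, max_iterations = 10L) {
  end_a <- normalize_rna(end_a); end_b <- normalize_rna(end_b)
  if (!has_node(graph, end_a) || !has_node(graph, end_b)) {
    graph <- build_graph(c(graph$nodes, end_a, end_b))
  }
  path_a <- end_a; path_b <- end_b
  frontier_a <- end_a; frontier_b <- end_b
  gap <- hamming_distance(frontier_a, frontier_b)
  for (it in seq_len(max_iterations)) {
    if (gap == 0L) break
    progressed <- FALSE
    res_a <- shortest_path_toward(graph, end_a, frontier_b)
    gap_a <- hamming_distance(res_a$terminal, frontier_b)
    if (gap_a < gap) {
      path_a <- res_a$path; frontier_a <- res_a$terminal
      gap <- gap_a; progressed <- TRUE
    }
    if (gap == 0L) break
    res_b <- shortest_path_toward(graph, end_b, frontier_a)
    gap_b <- hamming_distance(res_b$terminal, frontier_a)
    if (gap_b < gap) {
      path_b <- res_b$path; frontier_b <- res_b$terminal
      gap <- gap_b; progressed <- TRUE
    }
    if (!progressed) break
  }
  list(a_side = path_a, b_side = path_b,
       frontier_a = frontier_a, frontier_b = frontier_b,
       gap = gap, converged = gap == 0L)
}

#' Single-step bridge path between two sequences
#'
#' Deterministic mutational path from `a` to `b` applying one substitution at
#' a time at the positions where they differ, in the order given by
#' `order_spec` (default 5'-to-3' position order). The path has exactly
#' `hamming(a, b)` steps and `hamming(a, b) - 1` strict intermediates.
#'
#' @param a,b equal-length RNA sequences.
#' @param order_spec permutation of the differing positions (1-based indices
#'   into the sequence); default sorted ascending.
#' @return character vector `c(a, ..., b)`.
#' @export
bridge_single_step_path <- function(a, b, order_spec = NULL) {
  a <- normalize_rna(a); b <- normalize_rna(b)
  if (nchar(a) != nchar(b)) stop("sequences must have equal length")
  ca <- strsplit(a, "", fixed = TRUE)[[1]]
  cb <- strsplit(b, "", fixed = TRUE)[[1]]
  diff_pos <- which(ca != cb)
  if (is.null(order_spec)) order_spec <- diff_pos
  if (!setequal(order_spec, diff_pos) || length(order_spec) != length(diff_pos)) {
    stop("order_spec must be a permutation of the differing positions: ",
         paste(diff_pos, collapse = ","))
  }
  path <- character(length(diff_pos) + 1L)
  path[1] <- a
  cur <- ca
  for (i in seq_along(order_spec)) {
    cur[order_spec[i]] <- cb[order_spec[i]]
    path[i + 1L] <- paste(cur, collapse = "")
  }
  path
}
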