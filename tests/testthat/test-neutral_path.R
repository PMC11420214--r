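test_that("single mutants enumerate exactly the Hamming-1 shell", {
  expect_setequal(single_mutants("A"), c("C", "G", "U"))
  s <- random_rna(40, seed = 3)
  mut <- single_mutants(s)
  expect_length(mut, 120)
  expect_false(anyDuplicated(mut) > 0)
  expect_true(all(vapply(mut, hamming_distance, integer(1), b = s) == 1L))
  expect_error(single_mutants("ACGX"), "invalid RNA")
})

test_that("graph neighbor queries match a brute-force all-pairs scan", {
  expect_length(graph_neighbors(build_graph("ACGU"), "ACGU"), 0)
  g2 <- build_graph(c("ACGU", "ACGA"))
  expect_identical(graph_neighbors(g2, "ACGU"), "ACGA")
  expect_identical(graph_neighbors(g2, "ACGA"), "ACGU")
  # random set dense enough to contain many Hamming-1 pairs
  withr::with_seed(8, {
    seqs <- unique(replicate(300, random_rna(4)))
  })
  g <- build_graph(seqs)
  oracle <- neighbors_oracle(seqs)
  for (s in seqs) {
    expect_identical(sort(graph_neighbors(g, s)), oracle[[s]])
  }
})

test_that("path search equals BFS/igraph geodesics on unit-weight graphs", {
  skip_if_not_installed("igraph")
  # random connected-ish graphs: mutant clouds around a seed sequence
  withr::with_seed(21, {
    base <- random_rna(8)
    nodes <- unique(c(base, unlist(lapply(1:120, function(i) {
      mutate_n(base, sample(1:3, 1), seed = sample.int(1e6, 1))
    }))))
  })
  g <- build_graph(nodes)
  # build the same graph in igraph from the package's neighbor lists? No:
  # from an independent quadratic Hamming scan.
  oracle_nb <- neighbors_oracle(nodes)
  edges <- do.call(rbind, lapply(nodes, function(a) {
    nb <- oracle_nb[[a]]
    nb <- nb[nb > a]
    if (length(nb)) cbind(a, nb) else NULL
  }))
  ig <- igraph::graph_from_edgelist(edges, directed = FALSE)
  ig <- ig + igraph::vertices(setdiff(nodes, igraph::V(ig)$name))
  target <- mutate_n(base, 6, seed = 99)
  res <- shortest_path_toward(g, base, target)
  # path validity
  expect_identical(res$path[1], base)
  if (length(res$path) > 1) {
    steps <- vapply(seq_len(length(res$path) - 1L), function(i) {
      hamming_distance(res$path[i], res$path[i + 1L])
    }, integer(1))
    expect_true(all(steps == 1L))
  }
  expect_identical(res$terminal_gap, hamming_distance(res$terminal, target))
  # the path length equals the igraph geodesic to the terminal
  d_ig <- igraph::distances(ig, v = base)[1, ]
  expect_identical(res$path_length, unname(as.integer(d_ig[res$terminal])))
  # no reachable node is closer to the target than the chosen terminal
  reach <- names(d_ig)[is.finite(d_ig)]
  gaps <- vapply(reach, hamming_distance, integer(1), b = target)
  expect_identical(res$terminal_gap, min(gaps))
})

test_that("trivial path searches behave as defined", {
  g <- build_graph(c("AAAA", "CCCC"))
  res <- shortest_path_toward(g, "AAAA", "AAAA")
  expect_identical(res$path, "AAAA")
  expect_identical(res$terminal_gap, 0L)
  expect_true(res$reached_target)
  # isolated source: path is just the source
  res2 <- shortest_path_toward(g, "AAAA", "CCCC")
  expect_identical(res2$path, "AAAA")
  expect_identical(res2$terminal_gap, 4L)
  expect_false(res2$reached_target)
  expect_error(shortest_path_toward(g, "GGGG", "AAAA"), "not a node")
})

test_that("bidirectional refinement mirrors a two-sided search with a gap", {
  # plant the scenario: a-side chain reaches 2 mutations beyond end_a,
  # b-side chain reaches 3 beyond end_b, large residual gap in between
  end_a <- paste(rep("A", 30), collapse = "")
  end_b <- paste(rep("U", 30), collapse = "")
  a_chain <- bridge_single_step_path(end_a, end_b)[1:3]    # end_a + 2 steps
  # b_chain: end_b and 3 steps toward end_a (mutating positions 30,29,28)
  b_chain <- bridge_single_step_path(end_b, end_a, order_spec = 30:1)[1:4]
  g <- build_graph(c(a_chain, b_chain))
  res <- bidirectional_refine(g, end_a, end_b)
  expect_identical(res$frontier_a, a_chain[3])
  expect_identical(res$frontier_b, b_chain[4])
  expect_identical(res$gap, hamming_distance(a_chain[3], b_chain[4]))
  expect_identical(res$gap, 25L)
  expect_false(res$converged)
  # adjacent endpoints converge with a single-edge path
  g2 <- build_graph(c("AAAA", "AAAC"))
  res2 <- bidirectional_refine(g2, "AAAA", "AAAC")
  expect_true(res2$converged)
  expect_identical(res2$gap, 0L)
})

test_that("bridge paths take hamming(a,b) unit steps in the given order", {
  a <- random_rna(40, seed = 31)
  b <- mutate_n(a, 24, seed = 32)
  path <- bridge_single_step_path(a, b)
  expect_length(path, 25)           # 24 steps -> 23 strict intermediates
  expect_identical(path[1], a)
  expect_identical(path[25], b)
  for (i in 1:24) expect_identical(hamming_distance(path[i], path[i + 1]), 1L)
  # property over random pairs and random orders
  withr::with_seed(33, {
    for (rep in 1:10) {
      x <- random_rna(12); y <- random_rna(12)
      d <- hamming_distance(x, y)
      if (d == 0) next
      diffs <- which(strsplit(x, "")[[1]] != strsplit(y, "")[[1]])
      ord <- sample(diffs)
      p <- bridge_single_step_path(x, y, order_spec = ord)
      expect_length(p, d + 1)
      expect_identical(p[length(p)], y)
      expect_true(all(vapply(seq_len(d), function(i) {
        hamming_distance(p[i], p[i + 1])
      }, integer(1)) == 1L))
    }
  })
  expect_identical(bridge_single_step_path("AAAA", "AAAC"), c("AAAA", "AAAC"))
  expect_error(bridge_single_step_path("AAAA", "AACC", order_spec = c(1, 2)),
               "permutation")
})

test_that("quasi-neutrality thresholds derive from the reference enhancements", {
  crit <- quasi_neutral_criterion()
  expect_equal(unname(crit$thresholds), c(10, 100))
  # thresholds scale linearly with the reference
  crit2 <- quasi_neutral_criterion(500, 2000, fraction = 0.2)
  expect_equal(unname(crit2$thresholds), c(100, 400))

  rec <- activity_records("AAAA", "AIP", k_obs = 12e-4, k_background = 1e-4)
  expect_true(is_quasi_neutral(rec, crit)$quasi_neutral)
  rec2 <- activity_records(c("AAAA", "AAAA"), c("AIP", "PPP"),
                           k_obs = c(9e-4, 50e-5), k_background = c(1e-4, 1e-5))
  res2 <- is_quasi_neutral(rec2, crit)
  expect_false(res2$quasi_neutral)
  # inclusive boundary: exactly 100-fold PPP passes
  rec3 <- activity_records("AAAA", "PPP", k_obs = 100e-5, k_background = 1e-5)
  expect_true(is_quasi_neutral(rec3, crit)$quasi_neutral)
  expect_identical(is_quasi_neutral(rec3, crit)$passing_chemistries, "PPP")
  expect_error(is_quasi_neutral(
    activity_records("AAAA", "MeIP", 1e-3, 1e-4), crit), "no AIP or PPP")
})

test_that("path annotation labels chemistries and finds PPP emergence", {
  path <- bridge_single_step_path(random_rna(10, seed = 41),
                                  mutate_n(random_rna(10, seed = 41), 6, seed = 42))
  n <- length(path)
  k_emergence <- 5L
  recs <- activity_records(
    sequence = rep(path, each = 2),
    chemistry = rep(c("AIP", "PPP"), n),
    k_obs = as.vector(vapply(seq_len(n), function(i) {
      c(20e-4, if (i >= k_emergence) 150e-5 else 10e-5)
    }, numeric(2))),
    k_background = rep(c(1e-4, 1e-5), n))
  ann <- annotate_path(path, recs)
  expect_identical(ann$ppp_emergence_index, k_emergence)
  expect_identical(ann$labels[k_emergence - 1], "AIP-only")
  expect_identical(ann$labels[k_emergence], "AIP+PPP")
  expect_length(ann$break_indices, 0)
  # a step failing both chemistries is flagged as a break
  recs$rate_enhancement[recs$sequence == path[2]] <- 1
  ann2 <- annotate_path(path, recs)
  expect_identical(ann2$break_indices, 2L)
  # missing records are listed, not guessed
  ann3 <- annotate_path(c(path, "GGGGGGGGGG"), recs)
  expect_identical(ann3$missing, "GGGGGGGGGG")
  expect_true(is.na(ann3$labels[n + 1]))
})
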