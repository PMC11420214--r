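make_table <- function(...) {
  seq_count_table(data.frame(...))
}

test_that("hamming distance is a metric and matches an independent loop", {
  x <- random_rna(40, seed = 1)
  y <- mutate_n(x, 1, seed = 2)
  expect_identical(hamming_distance(x, x), 0L)
  expect_identical(hamming_distance(x, y), 1L)
  expect_error(hamming_distance("ACGU", "ACG"), "equal length")
  withr::with_seed(42, {
    for (i in 1:20) {
      a <- random_rna(25); b <- random_rna(25); c <- random_rna(25)
      expect_identical(hamming_distance(a, b), hamming_oracle(a, b))
      expect_identical(hamming_distance(a, b), hamming_distance(b, a))
      expect_lte(hamming_distance(a, c),
                 hamming_distance(a, b) + hamming_distance(b, c))
    }
  })
})

test_that("the CS1 and CS2 peak sequences differ at 15 positions", {
  tab1 <- read.delim(table1_path())
  # frozen from an independent position-wise comparison of the printed strings
  expect_identical(
    hamming_distance(tab1$sequence[tab1$name == "CS1"],
                     tab1$sequence[tab1$name == "CS2"]),
    15L)
})

test_that("fractional abundance is count over round total", {
  tab <- make_table(round = c(1, 1), sequence = c("AAAA", "CCCC"),
                    count = c(20, 80))
  expect_equal(fractional_abundance(tab, 1, "AAAA"), 0.20)
  expect_equal(fractional_abundance(tab, 1, "GGGG"), 0)
  expect_error(fractional_abundance(tab, 2, "AAAA"), "round")
  solo <- make_table(round = 0, sequence = "AAAA", count = 7)
  expect_equal(fractional_abundance(solo, 0, "AAAA"), 1)
})

test_that("greedy clustering recovers planted centroids and is order-invariant", {
  L <- 40
  centroids <- c(random_rna(L, seed = 10))
  centroids <- c(centroids,
                 mutate_n(centroids[1], 17, seed = 11),
                 mutate_n(centroids[1], 34, seed = 12))
  # oracle check on the construction: centroids pairwise >= 15 apart
  for (i in 1:2) for (j in (i + 1):3) {
    expect_gte(hamming_oracle(centroids[i], centroids[j]), 15)
  }
  members <- withr::with_seed(13, {
    unlist(lapply(centroids, function(cen) {
      vapply(1:15, function(i) mutate_n(cen, sample(0:5, 1), seed = sample.int(1e6, 1)),
             character(1))
    }))
  })
  counts <- withr::with_seed(14, sample(1:50, length(members), replace = TRUE))
  df <- aggregate(counts, list(sequence = members), sum)
  # give centroids top counts so they are the peaks
  df$x[df$sequence %in% centroids] <- df$x[df$sequence %in% centroids] + 1000
  tab <- make_table(round = 6, sequence = df$sequence, count = df$x)
  cl <- greedy_cluster(tab, 6, radius = 5)
  expect_length(cl, 3)
  expect_setequal(vapply(cl, `[[`, character(1), "peak"), centroids)
  # exhaustive distance oracle: each member within radius of its peak
  for (c_ in cl) {
    for (s in c_$members) expect_lte(hamming_oracle(s, c_$peak), 5)
  }
  # order invariance: shuffle the table rows
  tab2 <- make_table(round = 6, sequence = rev(df$sequence), count = rev(df$x))
  cl2 <- greedy_cluster(tab2, 6, radius = 5)
  expect_identical(lapply(cl, function(x) sort(x$members)),
                   lapply(cl2, function(x) sort(x$members)))
  # report abundances: clusters + remainder account for all reads
  rep_ <- cluster_report(cl, tab, 6)
  expect_lte(sum(rep_$pct_cluster_overall), 100 + 1e-9)
})

test_that("degenerate clustering cases behave as defined", {
  one <- make_table(round = 1, sequence = rep("ACGUACGU", 1), count = 50)
  cl <- greedy_cluster(one, 1, radius = 3)
  expect_length(cl, 1)
  expect_equal(cluster_report(cl, one, 1)$pct_cluster_overall, 100)
  two <- make_table(round = 1, sequence = c("AAAAAAAA", "UUUUUUUU"),
                    count = c(30, 60))
  cl2 <- greedy_cluster(two, 1, radius = 3)
  expect_length(cl2, 2)
  expect_identical(cl2[[1]]$peak, "UUUUUUUU")  # higher count seeds first
})

test_that("within-cluster share reproduces the printed peak-sequence table", {
  tab1 <- read.delim(table1_path())
  got <- within_cluster_share(tab1$pct_peak_overall, tab1$pct_cluster_overall)
  cs <- function(n) which(tab1$name == n)
  expect_equal(round(got[cs("CS2")], 2), 81.61)
  expect_equal(round(got[cs("CS3")], 2), 49.97)
  expect_lte(abs(got[cs("CS1")] - tab1$pct_within_cluster[cs("CS1")]), 0.02)
  expect_equal(within_cluster_share(12.5, 12.5), 100)
  expect_error(within_cluster_share(1, 0), "> 0")
  # top three peak abundances sum to ~60% of the pool
  top3 <- sum(sort(tab1$pct_peak_overall, decreasing = TRUE)[1:3])
  expect_equal(top3, 59.82)
})

test_that("distance spectrum sums to 1 and matches the doped-library pmf", {
  ref <- random_rna(40, seed = 77)
  solo <- make_table(round = 0, sequence = mutate_n(ref, 9, seed = 78),
                     count = 12)
  spec <- distance_spectrum(solo, 0, ref)
  expect_equal(unname(spec["9"]), 1)
  expect_equal(sum(spec), 1)
  self <- make_table(round = 0, sequence = ref, count = 3)
  expect_equal(unname(distance_spectrum(self, 0, ref)["0"]), 1)

  # simulated round-0 pool: spectrum ~ Binomial(40, 0.21) within 3 sigma
  m <- doped_library_model()
  n <- 1e5
  draws <- sample_doped_library(m, ref, n, seed = 500)
  tab <- table(draws)
  pool <- seq_count_table(data.frame(round = 0, sequence = names(tab),
                                     count = as.integer(tab)))
  spec <- distance_spectrum(pool, 0, ref)
  p <- mutation_count_pmf(m, 0:40)
  keep <- n * p >= 5
  sigma <- sqrt(n * p[keep] * (1 - p[keep])) / n
  expect_true(all(abs(spec[keep] - p[keep]) <= 3 * sigma))
})

test_that("trajectories censor at the read threshold and count reemergences", {
  tab <- make_table(round = rep(1:4, each = 2),
                    sequence = rep(c("AAAA", "CCCC"), 4),
                    count = c(50, 1000, 150, 1000, 80, 1000, 200, 1000))
  tr <- trajectory(tab, "AAAA", min_reads = 100)[[1]]
  expect_identical(tr$censored, c(TRUE, FALSE, TRUE, FALSE))
  expect_identical(tr$n_reemergences, 1L)
  tr2 <- trajectory(tab, "CCCC", min_reads = 100)[[1]]
  expect_identical(tr2$n_reemergences, 0L)
  expect_false(any(tr2$censored))
  # a count of exactly min_reads is censored (">100 reads" means >= 101)
  edge <- make_table(round = 1:2, sequence = c("AAAA", "AAAA"),
                     count = c(100, 101))
  tre <- trajectory(edge, "AAAA", min_reads = 100)[[1]]
  expect_identical(tre$censored, c(TRUE, FALSE))
})

test_that("count tables validate input and round-trip through TSV", {
  expect_error(seq_count_table(data.frame(round = 1, sequence = "ACGU",
                                          count = 0)), ">= 1")
  expect_error(seq_count_table(data.frame(round = 1,
                                          sequence = c("ACGU", "ACGUA"),
                                          count = c(1, 1))), "equal length")
  expect_warning(seq_count_table(data.frame(round = 1, sequence = "ACGT",
                                            count = 5)), "transliterating")
  tab <- make_table(round = c(0, 0, 1), sequence = c("AAAA", "ACCA", "AAAA"),
                    count = c(5, 2, 9))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_count_tsv(tab, path)
  expect_identical(as.data.frame(read_count_tsv(path)), as.data.frame(tab))
})
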