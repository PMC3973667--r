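test_that("two-hop counts match hand enumerations and the BFS oracle", {
  expect_equal(two_hop_count(p4(), "b"), 3L)
  expect_equal(two_hop_count(k3(), "a"), 2L)
  iso <- graph_from_edges(matrix(character(), 0, 2), nodes = "u")
  expect_equal(two_hop_count(iso, "u"), 0L)
  set.seed(11)
  for (i in 1:30) {
    g <- rand_er(sample(5:30, 1), runif(1, 0.05, 0.5), seed = 200 + i)
    v <- sample(igraph::V(g)$name, 1)
    expect_equal(two_hop_count(g, v), oracle_two_hop(g, v))
  }
})

test_that("precomputed tables match per-node recomputation", {
  tb <- precompute_tables(p4())
  expect_equal(unname(tb$N[c("a", "b", "c", "d")]), c(2, 3, 3, 2))
  expect_equal(unname(tb$Q[c("a", "b", "c", "d")]), c(3, 5, 5, 3))
  tb13 <- precompute_tables(k13())
  expect_true(all(tb13$N == 3))
  expect_equal(unname(tb13$Q["c"]), 9)
  expect_equal(unname(tb13$Q["l1"]), 3)
  empty <- graph_from_edges(matrix(character(), 0, 2), nodes = c("u", "w"))
  expect_true(all(precompute_tables(empty)$N == 0))
  expect_true(all(precompute_tables(empty)$Q == 0))
  # Q is recomputable from N over neighbors, and N is bounded
  for (seed in 1:10) {
    g <- rand_er(25, 0.15, seed = seed)
    tb <- precompute_tables(g)
    nm <- igraph::V(g)$name
    n <- length(nm)
    expect_true(all(tb$N >= igraph::degree(g)[nm]))
    expect_true(all(tb$N <= n - 1))
    for (v in nm) {
      nb <- frontier(g, v)
      expect_equal(unname(tb$Q[v]), sum(tb$N[nb]))
      expect_equal(unname(tb$N[v]), two_hop_count(g, v))
    }
  }
})

test_that("local centrality and its set extension match hand fixtures", {
  g <- p4()
  expect_equal(local_centrality(g, "a"), 5)
  expect_equal(local_centrality(g, "b"), 8)
  expect_equal(combinatorial_local_centrality(g, c("b", "c")), 16)
  expect_equal(combinatorial_local_centrality(g, character()), 0)
  star <- k13()
  for (v in igraph::V(star)$name) {
    expect_equal(local_centrality(star, v), 9)
  }
  expect_equal(combinatorial_local_centrality(star, c("l1", "l2")), 9)
  expect_equal(combinatorial_local_centrality(star, c("c", "l1")), 18)
  iso <- graph_from_edges(matrix(character(), 0, 2), nodes = "u")
  expect_equal(local_centrality(iso, "u"), 0)
})

test_that("frontier fast path equals the direct set-definition evaluation", {
  expect_equal(clc_from_frontier(character(), precompute_tables(p4())), 0)
  tb <- precompute_tables(p4())
  expect_equal(clc_from_frontier(c("b", "c"), tb), 10)
  expect_error(clc_from_frontier("zz", tb), "zz")
  set.seed(77)
  for (i in 1:200) {
    g <- rand_er(sample(5:40, 1), runif(1, 0.05, 0.4), seed = 3000 + i)
    tb <- precompute_tables(g)
    S <- rand_subset(g, sample(0:5, 1))
    expect_equal(clc_from_frontier(frontier(g, S), tb),
                 combinatorial_local_centrality(g, S, tb))
  }
})

test_that("singleton consistency, monotonicity, submodularity, additivity", {
  set.seed(42)
  for (i in 1:40) {
    g <- rand_er(sample(6:50, 1), runif(1, 0.05, 0.3), seed = 500 + i)
    tb <- precompute_tables(g)
    nm <- igraph::V(g)$name
    for (v in sample(nm, min(5, length(nm)))) {
      expect_equal(combinatorial_local_centrality(g, v, tb),
                   local_centrality(g, v, tb))
    }
    # nested pair
    Tset <- rand_subset(g, sample(2:min(6, length(nm)), 1))
    Sset <- sample(Tset, sample(seq_len(length(Tset) - 1), 1))
    expect_lte(combinatorial_local_centrality(g, Sset, tb),
               combinatorial_local_centrality(g, Tset, tb))
    # submodular triple
    rest <- setdiff(nm, Tset)
    if (length(rest) > 0) {
      v <- sample(rest, 1)
      gainA <- combinatorial_local_centrality(g, c(Sset, v), tb) -
        combinatorial_local_centrality(g, Sset, tb)
      gainB <- combinatorial_local_centrality(g, c(Tset, v), tb) -
        combinatorial_local_centrality(g, Tset, tb)
      expect_gte(gainA, gainB)
    }
    # bounds
    expect_lte(combinatorial_local_centrality(g, nm, tb), sum(tb$Q))
  }
  # disjoint frontiers add exactly
  two <- load_edge_list(text = c("a x", "x w", "b y", "y z"))
  expect_equal(length(intersect(frontier(two, "a"), frontier(two, "b"))), 0L)
  expect_equal(combinatorial_local_centrality(two, c("a", "b")),
               local_centrality(two, "a") + local_centrality(two, "b"))
})

test_that("per-node centrality CSV export round-trips", {
  path <- withr::local_tempfile(fileext = ".csv")
  df <- export_centrality_csv(p4(), path)
  back <- utils::read.csv(path, colClasses = c(node = "character"))
  expect_equal(back$node, c("a", "b", "c", "d"))
  expect_equal(back$C_L, c(5, 8, 8, 5))
  expect_equal(back$degree, c(1, 2, 2, 1))
  expect_equal(back, df)
})
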