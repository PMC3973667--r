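# Small named graphs used throughout; all built in code.

p4 <- function() load_edge_list(text = c("a b", "b c", "c d"))
k3 <- function() load_edge_list(text = c("a b", "b c", "a c"))
k13 <- function() load_edge_list(text = c("c l1", "c l2", "c l3"))
k15 <- function() load_edge_list(text = paste("s", paste0("l", 1:5)))
p3 <- function() load_edge_list(text = c("a b", "b c"))

# Seeded Erdos-Renyi graph with integer labels.
rand_er <- function(n, p, seed) random_graph("erdos-renyi", n = n, p = p,
                                             seed = seed)

# Draw a random node subset of size k (possibly 0).
rand_subset <- function(g, k) {
  nm <- igraph::V(g)$name
  if (k == 0L) character() else sample(nm, k)
}

# Brute-force frontier: union of per-node neighborhoods via igraph, used as an
# independent oracle for the incremental frontier code.
oracle_frontier <- function(g, S) {
  if (length(S) == 0L) return(character())
  out <- unique(unlist(lapply(S, function(v) {
    names(igraph::neighbors(g, v, mode = "all"))
  })))
  canonical_order(out)
}

# BFS-depth-2 oracle for the two-hop count.
oracle_two_hop <- function(g, v) {
  d <- igraph::distances(g, v = v,
                         mode = if (neighbor_mode(g) == "directed-out") "out"
                                else "all")
  sum(is.finite(d) & d >= 1 & d <= 2)
}
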