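# Local centrality and its set extension.
#
# Three nested quantities, all integer-valued on unweighted graphs:
#   N(v)    -- number of nearest plus next-nearest neighbors of v
#              (nodes at distance 1 or 2; v itself excluded)
#   Q(v)    -- sum of N(u) over the neighbors u of v (the precomputed table
#              that makes the lazy greedy fast)
#   C_L(v)  -- local centrality: sum of Q(u) over the neighbors u of v
#   C_LC(S) -- combinatorial local centrality of a node set: Q summed once per
#              *distinct* first neighbor of S, so overlapping neighborhoods
#              are not double counted.

# N over all vertices, from an integer adjacency list.
two_hop_all <- function(adj) {
  vapply(seq_along(adj), function(i) {
    nb <- adj[[i]]
    u <- unique(c(nb, unlist(adj[nb], use.names = FALSE)))
    length(u[u != i])
  }, integer(1))
}

#' Number of nearest plus next-nearest neighbors
#'
#' Counts the nodes at distance 1 or 2 from `v` (under the graph's neighbor
#' mode); `v` itself is excluded.
#'
#' @param g Graph.
#' @param v A single node label.
#' @return A non-negative integer count.
#' @export
two_hop_count <- function(g, v) {
  stopifnot(length(v) == 1L)
  check_nodes(g, v)
  adj <- adjacency_index(g)
  i <- match(as.character(v), node_names(g))
  nb <- adj[[i]]
  u <- unique(c(nb, unlist(adj[nb], use.names = FALSE)))
  length(u[u != i])
}

#' Precompute the per-node centrality tables
#'
#' Builds the two tables every fast path relies on: `N[v]`, the two-hop
#' neighborhood count, and `Q[v] = sum(N[u]) over neighbors u of v`.
#'
#' @param g Graph.
#' @return An object of class `clc_tables`: a list with named numeric vectors
#'   `N` and `Q` in canonical node order.
#' @export
precompute_tables <- function(g) {
  adj <- adjacency_index(g)
  nm <- node_names(g)
  N <- two_hop_all(adj)
  Q <- vapply(seq_along(adj), function(i) sum(N[adj[[i]]]), numeric(1))
  structure(list(N = stats::setNames(as.numeric(N), nm),
                 Q = stats::setNames(Q, nm)),
            class = "clc_tables")
}

#' @export
print.clc_tables <- function(x, ...) {
  cat(sprintf("centrality tables for %d nodes\n", length(x$N)))
  print(utils::head(data.frame(node = names(x$N), N = unname(x$N),
                               Q = unname(x$Q)), 10L))
  if (length(x$N) > 10L) cat(sprintf("... and %d more\n", length(x$N) - 10L))
  invisible(x)
}

tables_for <- function(g, tables) {
  if (is.null(tables)) precompute_tables(g) else tables
}

q_lookup <- function(tables, nodes) {
  q <- tables$Q[nodes]
  if (anyNA(q)) {
    stop(sprintf("stale tables: node(s) absent: %s",
                 paste(nodes[is.na(q)], collapse = ", ")))
  }
  q
}

#' Local centrality of a node
#'
#' `C_L(v) = sum(Q(u))` over the neighbors `u` of `v`; identifies influential
#' individual spreaders at two-hop resolution.
#'
#' @param g Graph.
#' @param v A single node label.
#' @param tables Optional precomputed [precompute_tables()] result.
#' @return A non-negative number.
#' @export
local_centrality <- function(g, v, tables = NULL) {
  stopifnot(length(v) == 1L)
  check_nodes(g, v)
  tables <- tables_for(g, tables)
  nb <- frontier(g, v)
  if (length(nb) == 0L) return(0)
  sum(q_lookup(tables, nb))
}

#' Combinatorial local centrality of a node set
#'
#' The set extension of local centrality: `Q` summed once per distinct first
#' neighbor of `S`. For a singleton it reduces to [local_centrality()]. With
#' `exclude_seeds = TRUE` the sum instead runs over the frontier with members
#' of `S` removed (this breaks singleton consistency and is off by default).
#'
#' @param g Graph.
#' @param S Character vector of node labels.
#' @param tables Optional precomputed tables.
#' @param exclude_seeds Drop members of `S` from the frontier before summing?
#' @return A non-negative number; 0 for the empty set.
#' @export
combinatorial_local_centrality <- function(g, S, tables = NULL,
                                           exclude_seeds = FALSE) {
  S <- unique(as.character(S))
  check_nodes(g, S)
  if (length(S) == 0L) return(0)
  tables <- tables_for(g, tables)
  f <- frontier(g, S, exclude_seeds = exclude_seeds)
  if (length(f) == 0L) return(0)
  sum(q_lookup(tables, f))
}

#' Combinatorial local centrality from a precomputed frontier
#'
#' The fast path used by the lazy greedy: given `F = frontier(g, S)`, returns
#' `sum(Q[F])`, identical to evaluating the set definition on `S` directly.
#'
#' @param F Character vector, a frontier.
#' @param tables Precomputed tables of the originating graph.
#' @return A non-negative number; 0 for an empty frontier.
#' @export
clc_from_frontier <- function(F, tables) {
  stopifnot(inherits(tables, "clc_tables"))
  F <- unique(as.character(F))
  if (length(F) == 0L) return(0)
  sum(q_lookup(tables, F))
}

#' Export per-node centrality values as CSV
#'
#' Writes columns `node, degree, N, Q, C_L` in canonical node order.
#'
#' @param g Graph.
#' @param path Output CSV path.
#' @param tables Optional precomputed tables.
#' @return The data frame written, invisibly.
#' @export
export_centrality_csv <- function(g, path, tables = NULL) {
  tables <- tables_for(g, tables)
  nm <- node_names(g)
  adj <- adjacency_index(g)
  cl <- vapply(seq_along(adj), function(i) sum(tables$Q[adj[[i]]]), numeric(1))
  df <- data.frame(node = nm,
                   degree = unname(lengths(adj)),
                   N = unname(tables$N[nm]),
                   Q = unname(tables$Q[nm]),
                   C_L = cl,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}
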