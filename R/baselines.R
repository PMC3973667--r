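# Top-K seed selection by seven standard centrality measures, used as
# comparison baselines for the greedy optimizer. Standard measures delegate to
# igraph; closeness is computed per component so disconnected graphs score
# every node finitely.

#' Baseline centrality measures
#'
#' @format Character vector of the supported `measure` values for
#'   [centrality_scores()].
#' @export
BASELINE_MEASURES <- c("degree", "shell", "betweenness", "closeness",
                       "eigenvector", "pagerank", "top_lc")

#' Score every node under a baseline centrality measure
#'
#' Measures: `degree`; `shell` (core number: the greatest k-core containing
#' the node); `betweenness` (unnormalized, endpoints excluded); `closeness`
#' (per component: `(c - 1) / sum of distances` within the node's component of
#' size `c`; isolated nodes score 0); `eigenvector` (scaled to max 1);
#' `pagerank` (damping 0.85); `top_lc` (the node's local centrality).
#'
#' @param g Graph (undirected mode).
#' @param measure One of [BASELINE_MEASURES].
#' @param tables Optional precomputed tables (used by `top_lc`).
#' @return An object of class `score_table`: list with `measure` and `scores`
#'   (named numeric over all nodes, canonical order; all finite).
#' @export
centrality_scores <- function(g, measure, tables = NULL) {
  if (length(measure) != 1L || !measure %in% BASELINE_MEASURES) {
    stop(sprintf("unknown measure %s; choose one of: %s",
                 deparse(substitute(measure)),
                 paste(BASELINE_MEASURES, collapse = ", ")))
  }
  nm <- node_names(g)
  scores <- switch(measure,
    degree = igraph::degree(g),
    shell = igraph::coreness(g),
    betweenness = igraph::betweenness(g, normalized = FALSE),
    closeness = closeness_by_component(g),
    eigenvector = igraph::eigen_centrality(g)$vector,  # scaled to max 1
    pagerank = igraph::page_rank(g, damping = 0.85)$vector,
    top_lc = {
      tables <- tables_for(g, tables)
      adj <- adjacency_index(g)
      vapply(seq_along(adj), function(i) sum(tables$Q[adj[[i]]]), numeric(1))
    })
  scores <- stats::setNames(as.numeric(scores), nm)
  stopifnot(all(is.finite(scores)))
  structure(list(measure = measure, scores = scores), class = "score_table")
}

closeness_by_component <- function(g) {
  nm <- node_names(g)
  comp <- igraph::components(g)
  d <- igraph::distances(g)
  vapply(seq_along(nm), function(i) {
    members <- which(comp$membership == comp$membership[i])
    if (length(members) == 1L) return(0)
    (length(members) - 1) / sum(d[i, members])
  }, numeric(1))
}

#' @export
print.score_table <- function(x, ...) {
  cat(sprintf("%s scores for %d nodes\n", x$measure, length(x$scores)))
  print(utils::head(sort(x$scores, decreasing = TRUE), 10L))
  invisible(x)
}

#' Top-K nodes of a score table
#'
#' Returns the `K` highest-scoring nodes; ties are broken by canonical node
#' order, so the result is deterministic.
#'
#' @param table A [centrality_scores()] result (or any list with a named
#'   `scores` vector).
#' @param K Number of nodes, `0 <= K <= n`.
#' @return Character vector of length `K`, highest score first.
#' @export
top_k <- function(table, K) {
  scores <- table$scores
  n <- length(scores)
  if (K > n || K < 0) stop(sprintf("K must be in [0, %d], got %s", n, K))
  if (K == 0L) return(character())
  ord <- canonical_index(names(scores))
  s <- scores[ord]
  names(s)[order(-s)[seq_len(K)]]  # stable sort keeps canonical ties
}

#' Select a seed set by any supported method
#'
#' Dispatch shared by the experiment harness and the command-line interface:
#' `greedy` and `greedy2` maximize combinatorial local centrality (and may
#' saturate early, returning fewer than `K` nodes), `brute` enumerates
#' exhaustively, and the seven baseline measures pick their top-K nodes.
#'
#' @param g Graph.
#' @param method `"greedy"`, `"greedy2"`, `"brute"`, or a baseline measure.
#' @param K Requested seed-set size.
#' @return Character vector of selected nodes in selection order.
#' @export
select_seeds <- function(g, method, K) {
  methods <- c("greedy", "greedy2", "brute", BASELINE_MEASURES)
  if (length(method) != 1L || !method %in% methods) {
    stop(sprintf("unknown method; choose one of: %s",
                 paste(methods, collapse = ", ")))
  }
  switch(method,
    greedy = greedy_clc(g, K)$selected,
    greedy2 = greedy_clc2(g, K)$selected,
    brute = brute_force_max_clc(g, K)$set,
    top_k(centrality_scores(g, method), K))
}
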