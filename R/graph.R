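# Graph representation, edge-list I/O, and neighborhood primitives shared by
# every other module. Graphs are igraph objects whose vertices carry character
# name labels; a graph attribute "neighbor_mode" distinguishes the ordinary
# undirected case from the directed-out mode used only by the max-k-cover
# hardness embedding.

integer_like <- function(x) grepl("^[+-]?[0-9]+$", x)

#' Canonical node order
#'
#' All deterministic iteration and tie-breaking in the package scans nodes in
#' canonical order: numeric ascending when every label parses as an integer,
#' otherwise lexicographic (byte order, locale-independent).
#'
#' @param labels Character vector of node labels.
#' @return The labels, reordered canonically.
#' @export
canonical_order <- function(labels) {
  labels <- as.character(labels)
  if (length(labels) == 0L) return(labels)
  if (all(integer_like(labels))) {
    labels[order(as.numeric(labels))]
  } else {
    sort(labels, method = "radix")
  }
}

# Permutation that puts `labels` into canonical order.
canonical_index <- function(labels) {
  if (length(labels) && all(integer_like(labels))) {
    order(as.numeric(labels))
  } else {
    order(labels, method = "radix")
  }
}

#' Neighbor mode of a graph
#'
#' @param g An igraph object produced by this package.
#' @return `"undirected"` or `"directed-out"`.
#' @export
neighbor_mode <- function(g) {
  m <- igraph::graph_attr(g, "neighbor_mode")
  if (is.null(m)) {
    if (igraph::is_directed(g)) "directed-out" else "undirected"
  } else {
    m
  }
}

node_names <- function(g) {
  nm <- igraph::vertex_attr(g, "name")
  if (is.null(nm)) as.character(seq_len(igraph::gorder(g))) else nm
}

# Integer adjacency list under the graph's neighbor mode ("all" for
# undirected, "out" for directed-out). Used by every hot loop.
adjacency_index <- function(g) {
  mode <- if (neighbor_mode(g) == "directed-out") "out" else "all"
  lapply(igraph::as_adj_list(g, mode = mode), as.integer)
}

#' Normalize an igraph object for use with this package
#'
#' Ensures vertex names exist, drops self-loops and duplicate edges, reorders
#' vertices canonically, and stamps the neighbor mode.
#'
#' @param g An igraph object.
#' @param mode `"undirected"` (default) or `"directed-out"`.
#' @return A normalized igraph object.
#' @export
as_network_graph <- function(g, mode = c("undirected", "directed-out")) {
  mode <- match.arg(mode)
  stopifnot(igraph::is_igraph(g))
  if (mode == "undirected" && igraph::is_directed(g)) {
    g <- igraph::as_undirected(g, mode = "collapse")
  }
  if (is.null(igraph::vertex_attr(g, "name"))) {
    g <- igraph::set_vertex_attr(g, "name",
                                 value = as.character(seq_len(igraph::gorder(g))))
  }
  g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
  perm <- canonical_index(node_names(g))
  # igraph::permute wants, for each vertex, its new position
  g <- igraph::permute(g, order(perm))
  igraph::graph_attr(g, "neighbor_mode") <- mode
  g
}

#' Build a graph from an edge matrix
#'
#' @param edges Two-column character matrix (or data frame) of endpoints;
#'   may be empty.
#' @param nodes Optional extra node labels (isolated vertices).
#' @param mode `"undirected"` or `"directed-out"`.
#' @return A normalized igraph object.
#' @export
graph_from_edges <- function(edges, nodes = NULL,
                             mode = c("undirected", "directed-out")) {
  mode <- match.arg(mode)
  edges <- as.matrix(edges)
  storage.mode(edges) <- "character"
  labels <- canonical_order(unique(c(nodes, as.vector(edges))))
  g <- igraph::make_empty_graph(n = 0, directed = mode == "directed-out")
  g <- igraph::add_vertices(g, length(labels), name = labels)
  if (nrow(edges) > 0L) {
    g <- igraph::add_edges(g, as.vector(t(edges)))
  }
  as_network_graph(g, mode = mode)
}

#' Read a whitespace-delimited edge list
#'
#' One edge per line as two whitespace-separated node labels; blank lines and
#' lines starting with `#` are ignored. Duplicate edges are collapsed and
#' self-loops dropped with a warning. Labels are kept as opaque strings;
#' integer-like labels sort numerically in the canonical order.
#'
#' @param path File path, or a character vector of lines via `text =`.
#' @param mode `"undirected"` (default) or `"directed-out"`.
#' @param text Optional character vector of lines, used instead of `path`.
#' @return A normalized igraph object.
#' @export
load_edge_list <- function(path = NULL, mode = c("undirected", "directed-out"),
                           text = NULL) {
  mode <- match.arg(mode)
  lines <- if (is.null(text)) readLines(path, warn = FALSE) else text
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  if (length(idx) == 0L) {
    warning("edge list is empty; returning an empty graph")
    return(graph_from_edges(matrix(character(), 0, 2), mode = mode))
  }
  toks <- strsplit(trimws(lines[idx]), "\\s+")
  bad <- which(lengths(toks) != 2L)
  if (length(bad) > 0L) {
    stop(sprintf("edge list line %d: expected 2 tokens, got %d",
                 idx[bad[1L]], lengths(toks)[bad[1L]]))
  }
  em <- do.call(rbind, toks)
  loops <- em[, 1L] == em[, 2L]
  if (any(loops)) {
    warning(sprintf("dropped %d self-loop(s)", sum(loops)))
  }
  # keep loop endpoints as (possibly isolated) vertices
  graph_from_edges(em[!loops, , drop = FALSE], nodes = unique(as.vector(em)),
                   mode = mode)
}

#' Read a GML graph file
#'
#' Thin wrapper over [igraph::read_graph()] that normalizes the result.
#'
#' @inheritParams load_edge_list
#' @export
load_gml <- function(path, mode = c("undirected", "directed-out")) {
  mode <- match.arg(mode)
  as_network_graph(igraph::read_graph(path, format = "gml"), mode = mode)
}

#' Write a graph as an edge list
#'
#' Edges are written in canonical node order (both within each line, for
#' undirected graphs, and across lines) with a trailing newline. Isolated
#' vertices cannot be represented in the two-token format and are omitted.
#'
#' @param g Graph.
#' @param path Output file path.
#' @export
write_edge_list <- function(g, path) {
  em <- igraph::as_edgelist(g, names = TRUE)
  if (nrow(em) > 0L) {
    labs <- canonical_order(node_names(g))
    r1 <- match(em[, 1L], labs)
    r2 <- match(em[, 2L], labs)
    if (neighbor_mode(g) != "directed-out") {
      flip <- r2 < r1
      em[flip, ] <- em[flip, c(2L, 1L), drop = FALSE]
      tmp <- r1[flip]
      r1[flip] <- r2[flip]
      r2[flip] <- tmp
    }
    em <- em[order(r1, r2), , drop = FALSE]
  }
  writeLines(if (nrow(em) > 0L) paste(em[, 1L], em[, 2L]) else character(),
             con = path)
  invisible(path)
}

check_nodes <- function(g, S) {
  missing <- setdiff(S, node_names(g))
  if (length(missing) > 0L) {
    stop(sprintf("node(s) not in graph: %s", paste(missing, collapse = ", ")))
  }
}

#' First-neighbor frontier of a node set
#'
#' Returns the union of the neighborhoods of the members of `S`. By default
#' this is the plain union (members of `S` appear when adjacent to another
#' member), which preserves the identity between the set centrality of a
#' singleton and the node's local centrality. Set `exclude_seeds = TRUE` to
#' remove members of `S` from the result.
#'
#' @param g Graph.
#' @param S Character vector of node labels (a set; duplicates ignored).
#' @param exclude_seeds Drop members of `S` from the frontier?
#' @return Character vector of frontier nodes in canonical order.
#' @export
frontier <- function(g, S, exclude_seeds = FALSE) {
  S <- unique(as.character(S))
  check_nodes(g, S)
  if (length(S) == 0L) return(character())
  adj <- adjacency_index(g)
  nm <- node_names(g)
  f <- unique(unlist(adj[match(S, nm)], use.names = FALSE))
  out <- nm[f]
  if (exclude_seeds) out <- setdiff(out, S)
  canonical_order(out)
}

#' Incrementally extend a frontier with one node's neighbors
#'
#' Given `F = frontier(g, S)`, returns `frontier(g, union(S, v))` without
#' recomputing the union from scratch.
#'
#' @param g Graph.
#' @param F Character vector, the current frontier.
#' @param v A single node label.
#' @inheritParams frontier
#' @export
update_frontier <- function(g, F, v, exclude_seeds = FALSE) {
  stopifnot(length(v) == 1L)
  check_nodes(g, c(F, v))
  nb <- frontier(g, v, exclude_seeds = FALSE)
  out <- union(F, nb)
  if (exclude_seeds) out <- setdiff(out, v)
  canonical_order(out)
}

#' Sample a node-induced subgraph
#'
#' Draws `n_target` nodes either uniformly at random or by a breadth-first
#' snowball from a random start (restarting from a random unvisited node when
#' a component is exhausted), and returns the induced subgraph. Reproducible
#' for a fixed `seed`.
#'
#' @param g Graph.
#' @param n_target Number of nodes to keep, `1 <= n_target <= n`.
#' @param method `"uniform"` (default) or `"bfs-snowball"`.
#' @param seed Optional integer seed; when `NULL` the current RNG stream is
#'   used.
#' @return The induced subgraph, normalized.
#' @export
induced_subgraph_sample <- function(g, n_target,
                                    method = c("uniform", "bfs-snowball"),
                                    seed = NULL) {
  method <- match.arg(method)
  n <- igraph::gorder(g)
  if (n_target < 1L || n_target > n) {
    stop(sprintf("n_target must be in [1, %d], got %s", n, n_target))
  }
  if (!is.null(seed)) withr::local_seed(seed)
  nm <- node_names(g)
  keep <- if (method == "uniform") {
    sample(nm, n_target)
  } else {
    adj <- adjacency_index(g)
    visited <- logical(n)
    out <- integer(0)
    queue <- integer(0)
    while (length(out) < n_target) {
      if (length(queue) == 0L) {
        pool <- which(!visited)
        queue <- pool[sample.int(length(pool), 1L)]
        visited[queue] <- TRUE
      }
      cur <- queue[1L]
      queue <- queue[-1L]
      out <- c(out, cur)
      nxt <- adj[[cur]][!visited[adj[[cur]]]]
      visited[nxt] <- TRUE
      queue <- c(queue, nxt)
    }
    nm[out[seq_len(n_target)]]
  }
  as_network_graph(igraph::induced_subgraph(g, keep),
                   mode = neighbor_mode(g))
}
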