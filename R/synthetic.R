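# Synthetic instance generators: random graphs (stand-ins for real contact
# networks), max-k-cover instances, the directed embedding that reduces
# max-k-cover to combinatorial-local-centrality maximization, and a small
# deterministic fixture demonstrating why overlapping neighborhoods make
# individually strong nodes poor partners.

#' Generate a simple random graph
#'
#' Wraps the igraph samplers and normalizes the result (simple, undirected,
#' canonical integer labels). Reproducible for a fixed seed.
#'
#' @param kind One of `"erdos-renyi"` (params `n`, `p`), `"barabasi-albert"`
#'   (`n`, `m` edges per new node), `"watts-strogatz"` (`n`, `nei`, `p`), or
#'   `"random-bipartite"` (`n1`, `n2`, `p`) -- the bipartite model mirrors
#'   two-mode contact structures such as heterosexual interaction networks.
#'   (Named `kind` rather than `model` so the Barabasi-Albert `m` parameter
#'   cannot partially match it.)
#' @param ... Model parameters as named arguments.
#' @param seed Optional integer seed.
#' @return A normalized igraph object with labels `"1"..."n"`.
#' @export
random_graph <- function(kind = c("erdos-renyi", "barabasi-albert",
                                  "watts-strogatz", "random-bipartite"),
                         ..., seed = NULL) {
  model <- match.arg(kind)
  if (!is.null(seed)) withr::local_seed(seed)
  p <- list(...)
  need <- function(keys) {
    miss <- setdiff(keys, names(p))
    if (length(miss)) {
      stop(sprintf("model %s requires parameter(s): %s",
                   model, paste(miss, collapse = ", ")))
    }
  }
  g <- switch(model,
    "erdos-renyi" = {
      need(c("n", "p"))
      stopifnot(p$n >= 1, p$p >= 0, p$p <= 1)
      igraph::sample_gnp(p$n, p$p)
    },
    "barabasi-albert" = {
      need(c("n", "m"))
      stopifnot(p$n >= 1, p$m >= 1)
      igraph::sample_pa(p$n, m = p$m, directed = FALSE)
    },
    "watts-strogatz" = {
      need(c("n", "nei", "p"))
      igraph::sample_smallworld(1, p$n, p$nei, p$p)
    },
    "random-bipartite" = {
      need(c("n1", "n2", "p"))
      igraph::sample_bipartite(p$n1, p$n2, type = "gnp", p = p$p)
    })
  if ("name" %in% igraph::vertex_attr_names(g)) {
    g <- igraph::delete_vertex_attr(g, "name")
  }
  g <- igraph::set_vertex_attr(g, "name",
                               value = as.character(seq_len(igraph::gorder(g))))
  as_network_graph(g, mode = "undirected")
}

#' Max-k-cover instance
#'
#' @param universe Character vector of element labels.
#' @param subsets Named list of character vectors, each a subset of
#'   `universe`.
#' @param K Number of subsets to pick, `K <=` number of subsets.
#' @return A validated list of class `max_k_cover`.
#' @export
max_k_cover_instance <- function(universe, subsets, K) {
  universe <- unique(as.character(universe))
  if (length(universe) == 0L) stop("universe must be nonempty")
  subsets <- lapply(subsets, function(s) unique(as.character(s)))
  if (is.null(names(subsets)) || any(names(subsets) == "")) {
    names(subsets) <- paste0("S", seq_along(subsets))
  }
  bad <- vapply(subsets, function(s) length(setdiff(s, universe)) > 0,
                logical(1))
  if (any(bad)) stop("every subset must be contained in the universe")
  stopifnot(K >= 1, K <= length(subsets))
  structure(list(universe = universe, subsets = subsets, K = as.integer(K)),
            class = "max_k_cover")
}

#' Random max-k-cover instance
#'
#' Each subset draws every element independently with probability
#' `p_member`; empty draws are topped up with one uniform element so every
#' subset-vertex of the embedding has an outgoing path.
#'
#' @param n_universe,n_subsets,K Instance dimensions.
#' @param p_member Membership probability (default 0.4).
#' @param seed Optional integer seed.
#' @export
random_max_k_cover <- function(n_universe, n_subsets, K, p_member = 0.4,
                               seed = NULL) {
  if (!is.null(seed)) withr::local_seed(seed)
  universe <- paste0("e", seq_len(n_universe))
  subsets <- lapply(seq_len(n_subsets), function(i) {
    s <- universe[stats::runif(n_universe) < p_member]
    if (length(s) == 0L) s <- sample(universe, 1L)
    s
  })
  max_k_cover_instance(universe, subsets, K)
}

#' Exact max-k-cover optimum (test oracle)
#'
#' Exhaustively enumerates all K-subsets of the family and returns the largest
#' number of covered elements. Guarded to small instances.
#'
#' @param inst A [max_k_cover_instance()].
#' @return List with `chosen` (subset names) and `covered` (count).
#' @export
max_k_cover_optimum <- function(inst) {
  stopifnot(inherits(inst, "max_k_cover"))
  p <- length(inst$subsets)
  if (choose(p, inst$K) > 1e6) stop("instance too large to enumerate")
  combos <- utils::combn(p, inst$K)
  best <- -1L
  best_idx <- NULL
  for (j in seq_len(ncol(combos))) {
    cov <- length(unique(unlist(inst$subsets[combos[, j]], use.names = FALSE)))
    if (cov > best) {
      best <- cov
      best_idx <- combos[, j]
    }
  }
  list(chosen = names(inst$subsets)[best_idx], covered = best)
}

#' Embed a max-k-cover instance as a directed seed-selection graph
#'
#' Builds the directed-out graph of the hardness reduction: one vertex per
#' subset and per element, a directed edge subset -> element for membership,
#' and for each element a two-edge tail element -> y -> z. Under out-neighbor
#' semantics every element vertex then has `Q = 1` (its single two-hop
#' successor is the z vertex), so the combinatorial local centrality of any
#' set of subset-vertices equals the number of distinctly covered elements --
#' maximizing it solves the cover instance.
#'
#' @param inst A [max_k_cover_instance()].
#' @return An object of class `embedding_map`: `graph` (directed-out mode),
#'   `roles` (named character vector: `subset`, `element`, `y`, `z`), and
#'   `back_map` (subset-vertex name -> original subset).
#' @export
embed_max_k_cover <- function(inst) {
  stopifnot(inherits(inst, "max_k_cover"))
  subs <- names(inst$subsets)
  sv <- paste0("s:", subs)
  ev <- paste0("e:", inst$universe)
  yv <- paste0("y:", inst$universe)
  zv <- paste0("z:", inst$universe)
  member_edges <- do.call(rbind, lapply(seq_along(subs), function(i) {
    if (length(inst$subsets[[i]]) == 0L) return(NULL)
    cbind(sv[i], paste0("e:", inst$subsets[[i]]))
  }))
  edges <- rbind(member_edges, cbind(ev, yv), cbind(yv, zv))
  g <- graph_from_edges(edges, nodes = c(sv, ev, yv, zv),
                        mode = "directed-out")
  roles <- stats::setNames(
    rep(c("subset", "element", "y", "z"),
        c(length(sv), length(ev), length(yv), length(zv))),
    c(sv, ev, yv, zv))
  back_map <- stats::setNames(inst$subsets, sv)
  structure(list(graph = g, roles = roles, back_map = back_map,
                 instance = inst),
            class = "embedding_map")
}

#' @export
print.embedding_map <- function(x, ...) {
  cat(sprintf(
    "max-k-cover embedding: %d subsets, %d elements -> %d vertices, %d edges\n",
    length(x$back_map), length(x$instance$universe),
    igraph::gorder(x$graph), igraph::gsize(x$graph)))
  invisible(x)
}

#' Deterministic overlap demonstration fixture
#'
#' A small graph with three marked nodes `a`, `b`, `c` such that `b` has the
#' higher local centrality (`C_L(b) > C_L(c)`) yet pairs worse with `a`
#' (`C_LC({a, c}) > C_LC({a, b})`): `b`'s neighborhood coincides with `a`'s,
#' while `c` lives in a region `a` does not reach. Illustrates why the top
#' individual spreaders need not form the best spreading set.
#'
#' @return List with `graph` and the node labels `a`, `b`, `c`.
#' @export
overlap_demo_fixture <- function() {
  x <- paste0("x", 1:3)
  y <- paste0("y", 1:3)
  z <- paste0("z", 1:3)
  edges <- rbind(cbind("a", c("b", x)),
                 cbind("b", x),
                 cbind("c", y),
                 cbind(y, z))
  list(graph = graph_from_edges(edges), a = "a", b = "b", c = "c")
}
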