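# Seed-set selection: the plain greedy maximizer of combinatorial local
# centrality, its lazy variant with precomputed tables and an incrementally
# maintained frontier, and an exhaustive maximizer used as a test oracle.
#
# Both greedy variants scan candidates in canonical node order and keep the
# first *strict* maximum (curVal > bestVal), so ties are broken identically
# and the two algorithms return bit-identical selections. bestVal/bestInd are
# reset at the top of every outer iteration, and selection stops early once no
# candidate has positive marginal gain (frontier saturation), which may return
# fewer than K nodes.

# Trace rows are accumulated as one block per outer iteration (bounded by n
# records each), then concatenated once, keeping trace bookkeeping linear.
trace_block <- function(iter, cand, action, gain, best) {
  list(iteration = rep(iter, length(cand)), candidate = cand,
       action = action, gain = gain, best = best)
}

bind_trace <- function(blocks) {
  pull <- function(f) unlist(lapply(blocks, `[[`, f), use.names = FALSE)
  data.frame(iteration = as.integer(pull("iteration") %||% integer(0)),
             candidate = as.character(pull("candidate") %||% character(0)),
             action = as.character(pull("action") %||% character(0)),
             gain = as.numeric(pull("gain") %||% numeric(0)),
             best = as.numeric(pull("best") %||% numeric(0)),
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

finish_result <- function(selected, values, blocks, evaluations) {
  structure(list(selected = selected, values = values,
                 trace = bind_trace(blocks),
                 evaluations = evaluations),
            class = "greedy_result")
}

#' @export
print.greedy_result <- function(x, ...) {
  cat(sprintf("greedy seed selection: %d node(s), %d marginal evaluation(s)\n",
              length(x$selected), x$evaluations))
  print(data.frame(node = x$selected, value = x$values))
  invisible(x)
}

#' Format a selection trace in the column style of a lazy-greedy run
#'
#' One column per chosen node; evaluated candidates print as
#' `node) gain`, lazily skipped candidates as `node) cached > best`.
#'
#' @param trace The `trace` data frame of a greedy result.
#' @return Character vector, one element per trace line, grouped by iteration.
#' @export
format_trace <- function(trace) {
  unlist(lapply(split(trace, trace$iteration), function(blk) {
    lines <- ifelse(blk$action == "skipped",
                    sprintf("%s) %g>%g", blk$candidate, blk$best, blk$gain),
                    sprintf("%s) %g", blk$candidate, blk$gain))
    c(sprintf("-- choosing node %d --", blk$iteration[1L]), lines)
  }), use.names = FALSE)
}

check_k <- function(K, n) {
  if (!is.numeric(K) || length(K) != 1L || K < 1 || K >= n) {
    stop(sprintf("K must satisfy 1 <= K < n = %d, got %s", n, K))
  }
  as.integer(K)
}

#' Greedy maximization of combinatorial local centrality
#'
#' At every iteration, evaluates the marginal gain of each remaining candidate
#' from scratch and adds the first strict maximizer in canonical order. Stops
#' early when no candidate has positive gain. Guarantees a (1 - 1/e) fraction
#' of the optimum because the objective is monotone and submodular.
#'
#' @param g Graph.
#' @param K Maximum seed-set size, `1 <= K < n`.
#' @return A `greedy_result`: `selected` (ordered labels), `values`
#'   (objective after each addition), `trace` (per-candidate records), and
#'   `evaluations` (number of marginal-gain computations).
#' @seealso [greedy_clc2()] for the equivalent lazy variant.
#' @export
greedy_clc <- function(g, K) {
  n <- igraph::gorder(g)
  K <- check_k(K, n)
  adj <- adjacency_index(g)
  nm <- node_names(g)
  tables <- precompute_tables(g)
  Qv <- unname(tables$Q[nm])
  clc_of <- function(ids) {
    f <- unique(unlist(adj[ids], use.names = FALSE))
    sum(Qv[f])
  }
  selected <- integer(0)
  values <- numeric(0)
  cur <- 0
  evals <- 0L
  blocks <- list()
  in_sel <- logical(n)
  iter <- 0L
  while (length(selected) < K) {
    iter <- iter + 1L
    bestVal <- 0
    bestInd <- NA_integer_
    cands <- which(!in_sel)
    gains <- numeric(length(cands))
    bests <- numeric(length(cands))
    for (j in seq_along(cands)) {
      i <- cands[j]
      curVal <- clc_of(c(selected, i)) - cur
      evals <- evals + 1L
      if (curVal > bestVal) {
        bestVal <- curVal
        bestInd <- i
      }
      gains[j] <- curVal
      bests[j] <- bestVal
    }
    blocks[[iter]] <- trace_block(
      iter,
      c(nm[cands], if (!is.na(bestInd)) nm[bestInd]),
      c(rep("evaluated", length(cands)), if (!is.na(bestInd)) "chosen"),
      c(gains, if (!is.na(bestInd)) bestVal),
      c(bests, if (!is.na(bestInd)) bestVal))
    if (is.na(bestInd)) break  # no positive gain anywhere: saturated
    selected <- c(selected, bestInd)
    in_sel[bestInd] <- TRUE
    cur <- cur + bestVal
    values <- c(values, cur)
  }
  finish_result(nm[selected], values, blocks, evals)
}

#' Lazy greedy maximization with precomputed tables
#'
#' Selection-equivalent to [greedy_clc()] (identical nodes, order, and
#' values), but (i) the per-node tables are computed once, (ii) the frontier
#' of the growing set is maintained incrementally so a marginal gain costs one
#' pass over the candidate's neighbors, and (iii) a candidate is re-evaluated
#' only when its cached previous marginal strictly exceeds the running best --
#' sound because marginal gains can only shrink as the set grows
#' (submodularity). Skipped candidates are recorded in the trace with their
#' cached bound.
#'
#' @inheritParams greedy_clc
#' @return A `greedy_result`; `evaluations` counts only the marginals actually
#'   recomputed, never more than [greedy_clc()] uses.
#' @export
greedy_clc2 <- function(g, K) {
  n <- igraph::gorder(g)
  K <- check_k(K, n)
  adj <- adjacency_index(g)
  nm <- node_names(g)
  tables <- precompute_tables(g)
  Qv <- unname(tables$Q[nm])
  sentinel <- sum(Qv) + 1  # strictly above any achievable gain
  lastVal <- rep(sentinel, n)
  in_frontier <- logical(n)
  selected <- integer(0)
  values <- numeric(0)
  cur <- 0
  evals <- 0L
  blocks <- list()
  in_sel <- logical(n)
  iter <- 0L
  while (length(selected) < K) {
    iter <- iter + 1L
    bestVal <- 0
    bestInd <- NA_integer_
    cands <- which(!in_sel)
    acts <- character(length(cands))
    gains <- numeric(length(cands))
    bests <- numeric(length(cands))
    for (j in seq_along(cands)) {
      i <- cands[j]
      if (lastVal[i] > bestVal) {
        nb <- adj[[i]]
        new_nb <- nb[!in_frontier[nb]]
        curVal <- sum(Qv[new_nb])
        evals <- evals + 1L
        lastVal[i] <- curVal
        if (curVal > bestVal) {
          bestVal <- curVal
          bestInd <- i
        }
        acts[j] <- "evaluated"
        gains[j] <- curVal
        bests[j] <- bestVal
      } else {
        acts[j] <- "skipped"
        gains[j] <- lastVal[i]  # the cached bound that licensed the skip
        bests[j] <- bestVal
      }
    }
    blocks[[iter]] <- trace_block(
      iter,
      c(nm[cands], if (!is.na(bestInd)) nm[bestInd]),
      c(acts, if (!is.na(bestInd)) "chosen"),
      c(gains, if (!is.na(bestInd)) bestVal),
      c(bests, if (!is.na(bestInd)) bestVal))
    if (is.na(bestInd)) break
    selected <- c(selected, bestInd)
    in_sel[bestInd] <- TRUE
    in_frontier[adj[[bestInd]]] <- TRUE
    cur <- cur + bestVal
    values <- c(values, cur)
  }
  finish_result(nm[selected], values, blocks, evals)
}

#' Exact maximization by exhaustive enumeration
#'
#' Enumerates every K-subset of the candidate nodes and returns the maximum
#' objective value together with the canonically-first argmax. A guard refuses
#' instances with more than `10^6` subsets.
#'
#' @param g Graph.
#' @param K Subset size, `1 <= K <=` number of candidates.
#' @param candidates Optional label vector restricting the search (defaults to
#'   all nodes); used, e.g., to search only subset-vertices of the hardness
#'   embedding.
#' @return A list with `set` (character vector, canonical order) and `value`.
#' @export
brute_force_max_clc <- function(g, K, candidates = NULL) {
  nm <- node_names(g)
  cand <- if (is.null(candidates)) nm else {
    check_nodes(g, candidates)
    canonical_order(unique(as.character(candidates)))
  }
  p <- length(cand)
  if (K < 1 || K > p) stop(sprintf("K must be in [1, %d], got %s", p, K))
  if (choose(p, K) > 1e6) {
    stop("more than 1e6 subsets to enumerate; shrink the instance")
  }
  adj <- adjacency_index(g)
  Qv <- unname(precompute_tables(g)$Q[nm])
  idx <- match(cand, nm)
  best_val <- -Inf
  best_set <- NULL
  combos <- utils::combn(idx, K)
  for (j in seq_len(ncol(combos))) {
    ids <- combos[, j]
    f <- unique(unlist(adj[ids], use.names = FALSE))
    val <- sum(Qv[f])
    if (val > best_val) {  # strict: keeps the canonically-first argmax
      best_val <- val
      best_set <- ids
    }
  }
  list(set = canonical_order(nm[best_set]), value = best_val)
}
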