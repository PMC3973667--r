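# Desk-scale experiment harness: method-comparison reports (objective value
# and simulated spread of seed sets chosen by the greedy optimizer vs the
# seven baseline measures, over sampled subgraph replicates and a percent
# grid) and a runtime benchmark for the two greedy variants. Everything is
# reproducible from a single seed; only orderings of wall times are ever
# asserted downstream, never magnitudes.

COMPARE_METHODS <- c("greedy2", BASELINE_MEASURES)

#' Compare seed-selection methods on sampled subgraphs
#'
#' For each of `replicates` sampled subgraphs and each percent of the grid,
#' selects seed sets with the lazy greedy optimizer and all seven baseline
#' measures (`K = floor(percent/100 * n)`, error if 0), records the
#' combinatorial local centrality of each set and its mean simulated spread.
#' The greedy optimizer may saturate early and return fewer than `K` nodes;
#' its objective value is then already the graph maximum.
#'
#' @param g Source graph.
#' @param percents Percent grid in `(0, 100]` (default `c(1, 3, 5, 10)`).
#' @param replicates Number of sampled subgraphs (default 1).
#' @param subgraph_n Nodes per sampled subgraph (default: the whole graph).
#' @param sample_method Passed to [induced_subgraph_sample()].
#' @param sir A [sir_config()] for the spread evaluation.
#' @param seed Optional integer seed making the whole report reproducible.
#' @return A data frame with columns `graph_id`, `replicate`, `method`,
#'   `percent`, `requested_k`, `selected_size`, `clc_value`, `mean_spread`,
#'   `spread_halfwidth`; one row per (replicate, percent, method).
#' @export
compare_methods <- function(g, percents = c(1, 3, 5, 10), replicates = 1L,
                            subgraph_n = igraph::gorder(g),
                            sample_method = "uniform",
                            sir = sir_config(), seed = NULL) {
  stopifnot(all(percents > 0), all(percents <= 100), replicates >= 1)
  if (!is.null(seed)) withr::local_seed(seed)
  gid <- igraph::graph_attr(g, "name")
  if (is.null(gid)) gid <- sprintf("graph-n%d", igraph::gorder(g))
  rows <- list()
  for (r in seq_len(replicates)) {
    sub <- if (subgraph_n < igraph::gorder(g)) {
      induced_subgraph_sample(g, subgraph_n, method = sample_method)
    } else {
      g
    }
    n_sub <- igraph::gorder(sub)
    tables <- precompute_tables(sub)
    for (pct in percents) {
      K <- as.integer(floor(pct / 100 * n_sub))
      if (K < 1L) {
        stop(sprintf("percent %g of %d nodes yields K = 0", pct, n_sub))
      }
      for (method in COMPARE_METHODS) {
        seeds <- select_seeds(sub, method, K)
        clc <- combinatorial_local_centrality(sub, seeds, tables)
        sp <- evaluate_spread(sub, seeds, sir)
        rows[[length(rows) + 1L]] <- data.frame(
          graph_id = gid, replicate = r, method = method, percent = pct,
          requested_k = K, selected_size = length(seeds), clc_value = clc,
          mean_spread = sp$mean, spread_halfwidth = sp$halfwidth,
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

time_once <- function(expr_fun, reps = 3L) {
  # min over a few repetitions damps scheduler jitter
  min(vapply(seq_len(reps), function(i) {
    unname(system.time(expr_fun())[["elapsed"]])
  }, numeric(1)))
}

#' Benchmark the plain vs lazy greedy selectors
#'
#' Generates (or samples) a graph at each requested size, selects
#' `k_fraction` of its nodes with both greedy variants, and reports wall
#' times (minimum over `reps` repetitions) plus whether the two selections
#' coincide (they must). The plain greedy is skipped with a notice above
#' `max_simple_n` nodes.
#'
#' @param sizes Integer vector of graph sizes.
#' @param k_fraction Fraction of nodes to select (default 0.05).
#' @param g Optional source graph to sample subgraphs from; when `NULL`,
#'   Erdos-Renyi graphs with mean degree ~10 are generated.
#' @param reps Timing repetitions per measurement (default 3).
#' @param max_simple_n Guard above which the plain greedy is skipped.
#' @param seed Optional integer seed.
#' @return Data frame with columns `n`, `k`, `time_greedy`, `time_greedy2`,
#'   `identical_selection`.
#' @export
runtime_bench <- function(sizes, k_fraction = 0.05, g = NULL, reps = 3L,
                          max_simple_n = 2000L, seed = NULL) {
  if (!is.null(seed)) withr::local_seed(seed)
  rows <- lapply(sizes, function(n) {
    gi <- if (is.null(g)) {
      random_graph("erdos-renyi", n = n, p = min(1, 10 / max(1, n - 1)))
    } else {
      induced_subgraph_sample(g, n)
    }
    K <- max(1L, as.integer(round(k_fraction * n)))
    t2 <- time_once(function() greedy_clc2(gi, K), reps)
    if (n <= max_simple_n) {
      t1 <- time_once(function() greedy_clc(gi, K), reps)
      same <- identical(greedy_clc(gi, K)$selected, greedy_clc2(gi, K)$selected)
    } else {
      message(sprintf("n = %d exceeds the plain-greedy guard (%d); skipped",
                      n, max_simple_n))
      t1 <- NA_real_
      same <- NA
    }
    data.frame(n = n, k = K, time_greedy = t1, time_greedy2 = t2,
               identical_selection = same)
  })
  do.call(rbind, rows)
}

#' Write an experiment report as CSV
#'
#' Numeric columns round-trip at 12 significant digits.
#'
#' @param report Data frame from [compare_methods()] or [runtime_bench()].
#' @param path Output path.
#' @export
write_report_csv <- function(report, path) {
  out <- report
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], function(x) signif(x, 12))
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Serialize a greedy trace or SIR result to JSON
#'
#' @param x A `greedy_result`, `sir_result`, or any list/data frame.
#' @param path Output path.
#' @export
write_json_result <- function(x, path) {
  if (inherits(x, "greedy_result")) {
    x <- list(selected = x$selected, values = x$values,
              evaluations = x$evaluations, trace = x$trace)
  } else if (inherits(x, "sir_result")) {
    x <- list(config = x$config[c("beta", "steps", "runs")],
              per_run_totals = x$totals, mean = x$mean,
              halfwidth = x$halfwidth)
  }
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
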