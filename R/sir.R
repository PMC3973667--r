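# Discrete-time SIR variant used for evaluating seed sets (after Chen et al.):
# at every step, each currently infected node picks ONE neighbor uniformly at
# random; if that neighbor entered the step susceptible it becomes infected
# (and acts from the next step onward). The acting node then recovers with
# probability beta, whether or not the attempt succeeded. The update is
# synchronous: all attempts are resolved against step-entry statuses, so run
# outcomes do not depend on node processing order. Attempts against
# non-susceptible targets are wasted; an infected node with no neighbors makes
# no attempt but still tests recovery.

SUSC <- 0L
INF <- 1L
REC <- 2L

#' SIR configuration
#'
#' @param beta Recovery probability in `[0, 1]`, tested after every attempt.
#' @param steps Number of synchronous time steps (default 10).
#' @param runs Ensemble size for [evaluate_spread()] (default 100).
#' @param seed Optional integer RNG seed for reproducible ensembles.
#' @return A validated list of class `sir_config`.
#' @export
sir_config <- function(beta = 0.5, steps = 10L, runs = 100L, seed = NULL) {
  stopifnot(is.numeric(beta), length(beta) == 1L, beta >= 0, beta <= 1,
            steps >= 1, runs >= 1)
  structure(list(beta = beta, steps = as.integer(steps),
                 runs = as.integer(runs), seed = seed),
            class = "sir_config")
}

status_init <- function(g, seeds) {
  seeds <- unique(as.character(seeds))
  if (length(seeds) == 0L) stop("seeds must be a nonempty subset of the nodes")
  check_nodes(g, seeds)
  nm <- node_names(g)
  status <- rep(SUSC, length(nm))
  status[match(seeds, nm)] <- INF
  status
}

# One synchronous step on an integer status vector, using a prebuilt integer
# adjacency list. Exposed through sir_step().
sir_step_idx <- function(adj, status, beta) {
  inf <- which(status == INF)
  if (length(inf) == 0L) return(status)
  newly <- integer(0)
  for (v in inf) {
    nb <- adj[[v]]
    if (length(nb) > 0L) {
      t <- nb[sample.int(length(nb), 1L)]
      if (status[t] == SUSC) newly <- c(newly, t)
    }
  }
  recov <- inf[stats::runif(length(inf)) < beta]
  status[newly] <- INF
  status[recov] <- REC
  status
}

#' One synchronous SIR step
#'
#' @param g Graph.
#' @param status Named integer vector over all nodes with values 0
#'   (susceptible), 1 (infected), 2 (recovered), e.g. from a previous step.
#' @param beta Recovery probability.
#' @return The updated status vector (same names and order).
#' @export
sir_step <- function(g, status, beta) {
  nm <- node_names(g)
  stopifnot(length(status) == length(nm))
  if (!is.null(names(status))) status <- status[nm]
  out <- sir_step_idx(adjacency_index(g), as.integer(status), beta)
  stats::setNames(out, nm)
}

#' Run one SIR realization from a seed set
#'
#' Applies `config$steps` synchronous steps from the seeded state and returns
#' the number of infected plus recovered nodes at the end (the total ever
#' infected).
#'
#' @param g Graph.
#' @param seeds Nonempty character vector of initially infected nodes.
#' @param config A [sir_config()].
#' @return Integer count in `[length(seeds), n]`.
#' @export
sir_run <- function(g, seeds, config = sir_config()) {
  status <- status_init(g, seeds)
  adj <- adjacency_index(g)
  for (s in seq_len(config$steps)) {
    status <- sir_step_idx(adj, status, config$beta)
    if (!any(status == INF)) break  # absorbed; counts can no longer change
  }
  sum(status != SUSC)
}

#' Monte-Carlo estimate of expected spread
#'
#' Runs `config$runs` independent SIR realizations from one seeded RNG stream
#' and summarizes the final infected-plus-recovered counts.
#'
#' @inheritParams sir_run
#' @return An object of class `sir_result`: `totals` (per-run counts), `mean`,
#'   `halfwidth` (95% normal-approximation half-width), and the config.
#' @export
evaluate_spread <- function(g, seeds, config = sir_config()) {
  if (!is.null(config$seed)) withr::local_seed(config$seed)
  status0 <- status_init(g, seeds)
  adj <- adjacency_index(g)
  totals <- vapply(seq_len(config$runs), function(r) {
    status <- status0
    for (s in seq_len(config$steps)) {
      status <- sir_step_idx(adj, status, config$beta)
      if (!any(status == INF)) break
    }
    sum(status != SUSC)
  }, numeric(1))
  m <- mean(totals)
  hw <- if (config$runs > 1L) {
    stats::qnorm(0.975) * stats::sd(totals) / sqrt(config$runs)
  } else {
    NA_real_
  }
  structure(list(totals = totals, mean = m, halfwidth = hw, config = config),
            class = "sir_result")
}

#' @export
print.sir_result <- function(x, ...) {
  cat(sprintf(
    "SIR spread over %d run(s), beta = %g, %d step(s): mean %.3f +/- %.3f\n",
    x$config$runs, x$config$beta, x$config$steps, x$mean,
    ifelse(is.na(x$halfwidth), 0, x$halfwidth)))
  invisible(x)
}

#' Exact expected spread by outcome-tree enumeration
#'
#' Enumerates every joint (target choice, recovery outcome) combination of the
#' infected nodes at each step, with probabilities, and returns the exact
#' expected infected-plus-recovered count after `steps` steps. Guarded to tiny
#' instances (`n <= 12`, `steps <= 10`); intended as an independent oracle for
#' validating the Monte-Carlo simulator.
#'
#' @param g Graph.
#' @param seeds Nonempty seed set.
#' @param beta Recovery probability.
#' @param steps Number of steps.
#' @return The exact expectation, a number.
#' @export
enumerate_expected_spread <- function(g, seeds, beta, steps) {
  n <- igraph::gorder(g)
  if (n > 12L || steps > 10L) {
    stop("enumeration guard: requires n <= 12 and steps <= 10")
  }
  adj <- adjacency_index(g)
  status0 <- status_init(g, seeds)
  memo <- new.env(parent = emptyenv())
  expect <- function(status, t) {
    inf <- which(status == INF)
    if (t == 0L || length(inf) == 0L) return(sum(status != SUSC))
    key <- paste(c(status, t), collapse = ",")
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    # per infected node: (target index or 0 for none) x (recover or not)
    node_opts <- lapply(inf, function(v) {
      nb <- adj[[v]]
      tg <- if (length(nb) > 0L) {
        data.frame(target = nb, p = 1 / length(nb))
      } else {
        data.frame(target = 0L, p = 1)
      }
      out <- merge(tg, data.frame(rec = c(TRUE, FALSE),
                                  pr = c(beta, 1 - beta)))
      out$prob <- out$p * out$pr
      out[out$prob > 0, c("target", "rec", "prob")]
    })
    total <- 0
    recurse <- function(k, status_next, p) {
      if (p == 0) return()
      if (k > length(inf)) {
        total <<- total + p * expect(status_next, t - 1L)
        return()
      }
      opts <- node_opts[[k]]
      v <- inf[k]
      for (r in seq_len(nrow(opts))) {
        st <- status_next
        tgt <- opts$target[r]
        if (tgt > 0L && status[tgt] == SUSC) st[tgt] <- INF
        if (opts$rec[r]) st[v] <- REC
        recurse(k + 1L, st, p * opts$prob[r])
      }
    }
    recurse(1L, status, 1)
    memo[[key]] <- total
    total
  }
  expect(status0, as.integer(steps))
}
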