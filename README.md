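# clcspread

Choosing *sets* of epidemic spreaders in a contact network. Picking the top
individually ranked nodes is a poor strategy for seeding a group: highly
central nodes tend to sit next to each other, so their two-hop neighborhoods
overlap and much of their combined reach is wasted. `clcspread` implements a
set-valued extension of local centrality together with greedy maximizers that
carry a provable approximation guarantee, and the discrete-time SIR machinery
to evaluate the chosen sets by simulation.

Intended users: network epidemiologists, computational social scientists, and
anyone selecting influence-maximization seed sets on undirected, unweighted
contact graphs at desk scale.

## The objective

For an undirected graph *G = (V, E)* with neighborhoods Γ(v), define

- **N(v)** — the number of nearest and next-nearest neighbors of *v*
  (nodes at distance 1 or 2; *v* excluded);
- **Q(v) = Σ<sub>u∈Γ(v)</sub> N(u)** — the precomputable per-node table;
- **C<sub>L</sub>(v) = Σ<sub>u∈Γ(v)</sub> Q(u)** — *local centrality*, a
  cheap, neighborhood-based score known to track a node's individual
  spreading ability under SIR dynamics;
- **C<sub>LC</sub>(S) = Σ<sub>u∈Γ(S)</sub> Q(u)** — *combinatorial local
  centrality* of a node set *S*, where Γ(S) = ∪<sub>v∈S</sub> Γ(v): each
  distinct first neighbor contributes its Q once, so overlapping
  neighborhoods are *not* double-counted. For a singleton,
  C<sub>LC</sub>({v}) = C<sub>L</sub>(v).

Maximizing C<sub>LC</sub> over sets of size K is NP-hard (the package ships
the directed max-k-cover embedding behind that reduction as a testable
generator). But C<sub>LC</sub> is monotone and submodular, so the greedy
algorithm achieves a (1 − 1/e) ≈ 0.632 approximation — the best possible in
polynomial time unless P = NP:

- `greedy_clc()` — the plain greedy: re-evaluates every candidate's marginal
  gain each round.
- `greedy_clc2()` — selection-identical but much faster: precomputes N and Q
  once, maintains the frontier Γ(S) incrementally, and lazily skips any
  candidate whose cached previous marginal cannot beat the running best
  (sound by submodularity). Its trace records every evaluation and skip.

Seed sets are evaluated under an SIR variant in which each infected node
contacts **one** uniformly random neighbor per step and then recovers with
probability β; spread is the number of infected-plus-recovered nodes after a
fixed number of steps (default 10).

## Worked example

```r
library(clcspread)
g <- random_graph("barabasi-albert", n = 500, m = 2, seed = 42)

res <- greedy_clc2(g, K = 10)
res
#> greedy seed selection: 10 node(s), 665 marginal evaluation(s)
#>    node value
#> 1     4 18764
#> 2     6 34344
#> 3    14 43529
#> 4     2 50845
#> 5     5 57773
#> 6    23 63473
#> 7     1 68709
#> 8    24 72919
#> 9    19 76184
#> 10   33 78701

# the classical alternative: top-10 by degree
base <- top_k(centrality_scores(g, "degree"), 10)
combinatorial_local_centrality(g, base)
#> [1] 76083

evaluate_spread(g, res$selected, sir_config(beta = 0.5, steps = 10, runs = 2000, seed = 1))
#> SIR spread over 2000 run(s), beta = 0.5, 10 step(s): mean 86.422 +/- 0.848
evaluate_spread(g, base, sir_config(beta = 0.5, steps = 10, runs = 2000, seed = 1))
#> SIR spread over 2000 run(s), beta = 0.5, 10 step(s): mean 83.323 +/- 0.828
```

Reading the numbers: the lazy greedy needed only 665 marginal evaluations
(the plain greedy would use 4,955 on this instance); `value` is the running
objective C<sub>LC</sub> after each addition. The greedy set scores 78,701
against 76,083 for the degree top-10, and that objective gap carries over to
simulated epidemics: on average ~86.4 versus ~83.3 of the 500 nodes
infected after ten steps (95% confidence half-widths shown).

`compare_methods()` runs this comparison systematically against all seven
baseline measures (degree, k-shell, betweenness, closeness, eigenvector,
PageRank, and top local centrality) over sampled subgraph replicates and a
percent grid; `runtime_bench()` times the two greedy variants against each
other. A thin command-line wrapper with `select`, `simulate`, `synth`,
`compare`, and `bench` subcommands is installed at
`system.file("cli", "clcspread", package = "clcspread")`.

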