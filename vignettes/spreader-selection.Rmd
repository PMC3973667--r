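---
title: "Selecting near-optimal spreader sets with combinatorial local centrality"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selecting near-optimal spreader sets with combinatorial local centrality}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clcspread)
```

## The problem

Local centrality $C_L$ is a cheap neighborhood-based score that tracks how
well a *single* node seeds an epidemic: it looks two hops out, which is where
most of the action of a short SIR epidemic happens, without the cost of
path-based measures such as betweenness. But seeding a *group* by taking the
top-$K$ individually ranked nodes fails in a characteristic way: strong
spreaders cluster, their two-hop neighborhoods overlap, and the group reaches
far fewer distinct nodes than the sum of its parts suggests. This package
implements the set-valued correction and the algorithms that optimize it.

## The objective and its structure

Three nested quantities on an undirected simple graph $G=(V,E)$ with
neighborhoods $\Gamma(v)$:

$$N(v) = |\{u \ne v : d(v,u) \le 2\}|, \qquad
  Q(v) = \sum_{u \in \Gamma(v)} N(u), \qquad
  C_L(v) = \sum_{u \in \Gamma(v)} Q(u),$$

and for a set $S$, with $\Gamma(S)=\bigcup_{v\in S}\Gamma(v)$,

$$C_{LC}(S) = \sum_{u \in \Gamma(S)} Q(u).$$

Each distinct first neighbor contributes its $Q$ exactly once, which is the
whole point: overlap between members' neighborhoods is not rewarded.
Two structural facts drive everything else:

* **Monotonicity** — growing $S$ can only grow $\Gamma(S)$, and $Q \ge 0$.
* **Submodularity** — the marginal gain of adding $v$,
  $\sum_{u \in \Gamma(v)\setminus\Gamma(S)} Q(u)$, can only shrink as
  $\Gamma(S)$ grows.

Exact maximization is NP-hard (max-k-cover embeds into it; see below), but
monotone submodular maximization under a cardinality constraint admits the
classical greedy $(1-1/e)$ guarantee, and no polynomial algorithm can do
better unless P = NP. Both properties, the guarantee, and the embedding are
exercised as property tests and by `scripts/acceptance.R`, not merely assumed.

### One deliberately open choice

Whether $\Gamma(S)$ should exclude members of $S$ themselves is genuinely
ambiguous in the set-extension literature. We use the plain union (a seed
adjacent to another seed stays in the frontier), because it is the unique
choice under which $C_{LC}(\{v\}) = C_L(v)$ for every node — singleton
consistency. Both `frontier()` and `combinatorial_local_centrality()` expose
`exclude_seeds = TRUE` for the other reading.

## The two greedy algorithms

`greedy_clc()` is the textbook loop: for each of up to $K$ rounds, evaluate
every remaining candidate's marginal gain from scratch and add the best. Its
cost is dominated by $O(nK)$ full objective evaluations.

`greedy_clc2()` returns *bit-identical* selections faster, via three
mechanisms:

1. $N$ and $Q$ are precomputed once (`precompute_tables()`).
2. The frontier $\Gamma(S)$ is maintained incrementally
   (`update_frontier()`), so a marginal gain is one pass over the candidate's
   neighbors: $\sum_{u \in \Gamma(i),\, u \notin \Gamma(S)} Q(u)$.
3. **Lazy evaluation**: each candidate caches its last computed marginal.
   Since marginals only shrink, a candidate whose cache does not strictly
   exceed the current best cannot win this round and is skipped without
   recomputation. The cache is initialized to a sentinel strictly above any
   achievable gain ($\sum_v Q(v) + 1$), so every candidate is evaluated at
   least once before it can be skipped.

Equivalence is exact, not approximate, because both variants scan candidates
in the same canonical node order (numeric ascending when all labels are
integer-like, lexicographic otherwise) and keep the first *strict* maximum
(`curVal > bestVal`). A skipped candidate's true marginal is at most its
cache, which is at most the running best, so skipping never changes which
node wins — the acceptance suite verifies identical selections and value
sequences on 200 random instances, and that the lazy variant never performs
more marginal evaluations.

Two behaviors worth knowing:

* **Tie-breaking.** Among gain-tied candidates the canonically first wins.
  This pins down the selection uniquely and is what makes cross-variant
  bit-identity testable.
* **Early saturation.** Once $\Gamma(S)$ covers all of $V$ every marginal is
  0 and both algorithms stop, possibly below $K$. The value already attained
  is then the global maximum — no larger set can beat it — which downstream
  reporting treats as a feature (smaller seed sets at no objective cost).
  The best-so-far trackers are reset at the top of every round; selection
  traces record every `evaluated`, `skipped` (with its cached bound), and
  `chosen` event, and `format_trace()` prints them in the compact
  `node) cached > best` column style.

`brute_force_max_clc()` enumerates all $\binom{n}{K}$ subsets (guarded at
$10^6$) and is the oracle behind the approximation-ratio tests; it is never
used in any production path.

## The SIR variant

Evaluation uses the discrete-time SIR variant under which local centrality
was originally validated, *not* classic per-contact-probability SIR: at every
step, each infected node picks **one** neighbor uniformly at random; if that
neighbor entered the step susceptible it becomes infected (acting from the
next step); the acting node then recovers with probability $\beta$ regardless
of the attempt's outcome. Spread is measured as infected-plus-recovered after
a fixed horizon.

The published description leaves three details open; our choices, all
documented in code:

* **Synchronous two-phase update.** All attempts resolve against step-entry
  statuses, so outcomes are independent of node processing order.
* **Wasted attempts.** The target is drawn from *all* neighbors; hitting an
  infected or recovered neighbor simply wastes the attempt.
* **Recovery is tested after every attempt**, including wasted ones and the
  no-neighbor case.

Defaults: `steps = 10` (the standard evaluation horizon for this variant);
`beta = 0.5` and `runs = 100` are this package's own defaults, chosen as
moderate values — both are prominent arguments of `sir_config()` and echoed
into every serialized result. `evaluate_spread()` reports the per-run totals,
their mean, and a 95% normal-approximation half-width from a single seeded
RNG stream.

`enumerate_expected_spread()` computes the *exact* expectation by
enumerating the full outcome tree with memoization, guarded to $n \le 12$ and
$\le 10$ steps. It exists purely as an independent oracle: the test suite and
acceptance script check that Monte-Carlo means at 10,000 runs fall within
three standard errors of the exact value on triangle, path, and star
fixtures across $\beta \in \{0.25, 0.5, 1\}$.

## Baselines

`centrality_scores()` scores all nodes under degree, k-shell (core number),
betweenness (unnormalized, endpoints excluded), closeness, eigenvector,
PageRank, or top local centrality, and `top_k()` takes the $K$ best with
canonical-order tie-breaking. Standard measures delegate to igraph; since
only rank order feeds top-$K$ selection, normalization choices matter only
through ties. Conventions for the unstated corners: closeness is computed
per component as $(c-1)/\sum d$ within the node's component of size $c$
(isolates score 0), PageRank damping is 0.85, eigenvector centrality is
scaled to maximum 1.

## Synthetic generators, and what they do not show

`random_graph()` provides Erdős–Rényi, Barabási–Albert, Watts–Strogatz, and
random-bipartite models (the bipartite one mirrors two-mode structures such
as heterosexual interaction networks, a case known to saturate early).
These are the test beds for every property check. They emulate size, sparsity,
degree heterogeneity (BA), clustering (WS), and two-mode structure — but not
community structure, degree assortativity, or the heavy-tailed *and*
clustered combination of real contact networks. Passing tests therefore
demonstrate correctness of the algorithms and the claimed mathematical
properties on those regimes, not that the chosen seed sets are optimal for
any particular real epidemic.

`induced_subgraph_sample()` supports uniform node sampling and BFS-snowball
sampling. How the original evaluation subgraphs were drawn is not on record;
both methods are offered as labelled guesses, with uniform the default and
snowball provided because uniform samples of sparse graphs shatter into
fragments.

### The hardness embedding

`embed_max_k_cover()` turns a max-k-cover instance into a *directed* graph:
subset-vertex → element-vertex edges for membership, plus a two-edge tail
element → y → z per element. Under out-neighbor semantics every element
vertex has exactly one two-hop successor, so $Q(\text{element}) = 1$,
$Q(y) = 0$, and the set objective of any family of subset-vertices equals the
number of distinctly covered elements. The construction is stated inside an
otherwise-undirected framework in the literature; we implement it in
directed-out mode because only there does the objective reduce exactly to
cover counts (in the undirected reading, element vertices see each other
through shared subsets and dominate the sums). The acceptance suite
double-checks this with two independent brute forces: exact max-k-cover
versus exact objective maximization over subset-vertices, on 50 random
instances.

`overlap_demo_fixture()` is a 13-node deterministic graph with marked nodes
$a, b, c$ where $C_L(b) > C_L(c)$ yet $\{a,c\}$ beats $\{a,b\}$ as a set —
the smallest honest demonstration of why this package exists. Greedy, having
taken $a$, picks $c$.

## Experiment harness and numerical conventions

`compare_methods()` reproduces the comparison design at desk scale: for each
sampled subgraph replicate and each percent of a grid (default
$\{1, 3, 5, 10\}\%$, $K = \lfloor pn/100 \rfloor$, an error if 0), it selects
seeds with the lazy greedy and all seven baselines and records each set's
objective value and simulated spread. `runtime_bench()` times the two greedy
variants (minimum over 3 repetitions to damp scheduler jitter); only
*orderings* of wall times are ever asserted, never magnitudes, since
absolute runtimes are hardware-bound. Statistical reporting is means ±
normal-approximation half-widths; formal analysis-of-variance comparisons
are left to the user's statistics environment.

Reproducibility: every stochastic entry point takes a seed and restores the
caller's RNG state afterwards; reports rerun byte-identically under a fixed
seed. CSV report writers round to 12 significant digits, which round-trips
through `read.csv` losslessly at these magnitudes. The CLI accepts a flat
JSON config file (`--config`) whose keys mirror the long option names, with
explicit flags taking precedence.

Problem sizes used by the shipped test and acceptance suites — chosen so the
full property battery (hundreds of random graphs, $10^4$-replicate SIR
ensembles, double brute-force cover checks) completes in a few minutes on one
core: random graphs up to $n = 300$ for equivalence checks, $n \le 14$ for
brute-force optima, $n = 200$ Erdős–Rényi replicates at mean degree 10 for
the method comparison, and benchmark sizes $n \in \{100, 200, 700\}$.

## Known limitations

* Unweighted, undirected, static graphs only; no multigraphs or temporal
  dynamics. Directed mode exists solely for the hardness embedding.
* The SIR variant is the single-contact-per-step model; classic SIR, SIS,
  rumor-stifler, and threshold dynamics are out of scope.
* Edge-list output cannot represent isolated vertices (two tokens per line);
  round-trips are exact on graphs without isolates.
* The exact-expectation oracle is exponential and guarded; it validates the
  simulator on fixtures, not on analysis-scale graphs.
* Greedy selections are near-optimal for the *objective*; how faithfully the
  objective proxies true epidemic spread inherits the empirical support of
  local centrality and the simulation comparisons, not a theorem.
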