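---
title: "Validated signed projections of typed bipartite networks: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validated signed projections of typed bipartite networks: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bipval)
```

## The inference problem

Many observational data sets record which *agents* took part in which
*events*, and how: parliament members support, oppose or abstain on motions;
investors buy, sell or day-trade a security on a trading day. Such data form
a bipartite network whose links carry a qualitative *type*. Direct
agent-agent relationships are not observed; the standard surrogate is a
one-mode projection linking agents that share events. An unfiltered
projection is almost always near-complete, so the scientific content lies in
deciding which co-occurrences are *statistically surprising*.

`bipval` validates pairs of agents against a null model in which agents keep
their observed activity levels and link-type habits but choose events and
types at random. Writing $N$ for the number of events, $N_i$ for the number
of events agent $i$ attends, and $p_i(a_k)$ for the empirical frequency with
which $i$ uses type $a_k$, the chance that $i$ and $j$ use the same type at
a jointly attended event is

$$p_{ij} = \sum_k p_i(a_k)\,p_j(a_k).$$

Under the null, the number of jointly attended events $X$ is hypergeometric
(only the agent-side degree sequence is fixed; events are exchangeable), and
conditional on $X$ the number of same-type matches is binomial. The tail
probability of an observed same-type overlap $\tilde N_{ij}$ is therefore
the hypergeometric–binomial mixture

$$P(Y \ge \tilde N_{ij}) \;=\; \sum_{X=\tilde N_{ij}}^{\min(N_i,N_j)}
  H(X \mid N, N_i, N_j)\; B(Y \ge \tilde N_{ij} \mid X,\, p_{ij}),$$

implemented by `hb_mixture_survival()`. Replacing $\tilde N_{ij}$ by the
count of events where the two agents used *opposing* types, and $p_{ij}$ by
$q_{ij} = \sum_{(a_+,a_-)} p_i(a_+)p_j(a_-) + p_i(a_-)p_j(a_+)$ over the
declared opposing pairs, gives the negative-link test. `project()` runs both
tests over all pairs, applies multiple-test correction, and returns a signed
network; `triad_census_signed()` classifies its triangles by structural
balance (a triangle is stable iff the product of its edge signs is
positive).

The classical *reference* method validates each link type separately with a
hypergeometric upper tail on per-type degrees and aggregates the per-type
p-values (minimum, mean or maximum). It is included (`model = "reference"`
in `validate_pairs()`/`project()`) both as a baseline and because the
contrast is instructive: a pair can be significant in one rare type yet
unremarkable — or significantly *opposed* — once all types are considered
jointly, which is exactly what happens in the package's bundled two-agent
example (`table1_network()`).

### Assumptions

* Only the agent-side degree sequence is fixed; event nodes are treated as
  exchangeable. When events differ strongly in intrinsic popularity this
  assumption is wrong, and the p-values are anti-conservative for popular
  events. Batch-wise validation or maximum-entropy ensembles that also fix
  event degrees are outside this package's scope.
* Preference vectors are plug-in estimates from the same data being tested.
  For agents with few events they are noisy; degree filters
  (`filter_agents_by_degree()`) are the standard mitigation.
* At most one typed link per (agent, event); weighted or multi-edge
  bipartite data must be discretized first (see `trading_states()` for the
  bought/sold volume case, with its closed neutral band
  $-\theta \le v \le \theta$ so that boundary values are classified).

## Tunable parameters

| Parameter | Where | Default | Rationale |
|---|---|---|---|
| `alpha` | `project()` | 0.01 | conventional significance level for validated political/investor networks |
| `correction` | `project()`, `ensemble_experiment()` | Bonferroni | strict familywise control; `none` exposes raw thresholds |
| `family` | `project()` | `per_sign` | positive and negative tests answer different questions per pair, so each family is corrected with $m$ = number of tested pairs; `joint` pools them for users who prefer a single family of $2m$ |
| `preference_mode` | validation functions | `per_agent` | the worked example and empirical uses estimate $p_i$ per agent; `population` pools all agents |
| `aggregation` | reference model | `min` | the sharpest (hardest-to-beat) reference aggregation |
| `theta` | `trading_states()` | 0.1 | conventional net-volume threshold for buy/sell/day-trade states |
| `window_size`, `step` | `rolling_window_projection()` | — | the political-affiliation use case employs 120-event windows stepped by 30 |

## The influence-model generator

`simulate_bipartite()` produces synthetic typed bipartite networks from a
ground-truth graph (the bundled 34-node, 78-edge karate-club fixture by
default) so that reconstruction performance can be measured against a known
answer. Per realization each agent carries three fixed attributes: a
connection probability $n_i \sim U[0,1]$, a mimicry probability
$c_i \sim U[0,1]$, and a link-type preference vector. Each of the 100 events
(3 link types) starts from a uniformly chosen seed agent who always
connects, typed from its own preferences; participation then spreads in
breadth-first order — an exposed agent connects with probability $n_i$, and
on connecting copies the type of a uniformly chosen already-connected graph
neighbor with probability $c_i$, otherwise draws from its own preferences.
Neighboring agents therefore co-attend and co-type more often than distant
ones, which is the signal the validation methods are asked to recover.

Three aspects of this generator were genuinely open and are worth recording:

* **Preference sampling.** "Random preferences ranging from full
  concentration to exact equality" is realized in two stages: a per-agent
  concentration level $s \sim U[0,1]$ mapped through the odds transform to a
  symmetric Dirichlet parameter $\alpha = s/(1-s)$. The endpoints are exact
  ($s=0$ gives a one-hot vector, $s=1$ the uniform vector) and the median
  agent sits at the flat Dirichlet. The mapping is a package choice; any
  scheme spanning the same range is admissible, and restricted ensembles
  (`concentration_range`, `ni_range`, `ci_range`) expose the ranges
  directly.
* **Exposure semantics.** By default an agent decides *once per event*, on
  first exposure (`exposure = "once"`). The alternative classical
  independent-cascade reading — each newly connected neighbor grants one
  more independent attempt — is available as `exposure = "per_neighbor"`;
  it raises effective connectivity and with it the density of significant
  overlaps. The once-per-event default was chosen because it reproduces the
  relative behavior of the four validation variants (mixture and the three
  reference aggregations) on the reconstruction benchmark most cleanly;
  both variants are tested.
* **RNG discipline.** A single seeded generator drives attribute sampling
  first, then the events in order, so a fixed seed makes a realization — and
  the entire `ensemble_experiment()` — bit-reproducible.

What the generator does *not* emulate: heterogeneous event popularity
(events are statistically identical), temporal drift in preferences, agent
entry/exit, and any dependence between events. Passing reconstruction
benchmarks on this generator therefore demonstrates correctness of the
statistical machinery under the null model's own assumptions, not
performance on real data with popular events or regime changes.

## Benchmarks and problem sizes

`ensemble_experiment()` simulates an ensemble, validates every pair with the
mixture null and the three reference aggregations, and scores edge sets
against the ground truth: rank-based AUC of $1 - p$ (`auc_from_pvalues()`,
midranks for ties; pairs never co-typed receive $p = 1$), plus precision,
recall, F1 and accuracy across a grid of significance levels with Bonferroni
correction per projection, and paired t-tests between methods run-by-run on
identical networks. The package's test suite and acceptance script use
ensembles of 200 simulations at 100 events — large enough that the ensemble
mean AUC has a standard error of about 0.002 while keeping the whole suite
fast; the original study size of 1000 simulations is a single argument
change.

`enumerate_two_agent_study()` covers the complementary deterministic
question: over *all* two-agent configurations at 20 events and 3 types, how
do the mixture and reference p-values compare? All reported quantities
depend on a configuration only through its sufficient statistic — each
agent's per-type link counts and the per-type overlaps — so the enumeration
iterates those classes (about $9.7\times 10^7$ at the default size, a
C++ kernel finishing in about a minute) rather than the astronomically
larger space of labeled configurations. An optional exact multiplicity
weight (inclusion–exclusion over forced same-type matches) recovers counts
over labeled configurations where those are wanted; both weightings are
emitted because "fraction of validated configurations" is ambiguous between
the two readings. Off-diagonal feasibility of a class is checked via the
transportation-polytope condition
$(r_k - o_k) + (c_k - o_k) \le N - \sum_l o_l$ for every type $k$.

## Numerical choices

* All tail probabilities are accumulated in log space
  (`dhyper(log = TRUE)` + `pbinom(log.p = TRUE)`, rescaled by the largest
  term) so that values down to the $10^{-12}$ scale the enumeration study
  reaches are computed without underflow; results are clamped to $[0,1]$.
* `hb_mixture_survival()` returns 1 at $k \le 0$ and 0 (with a warning) when
  $k$ exceeds $\min(N_i, N_j)$ — filtered empirical data can legitimately
  present such queries, and a warning preserves detectability. With a single
  effective link type ($p = 1$) it reduces to the plain hypergeometric upper
  tail; tests enforce this to a relative tolerance of $10^{-9}$ and check
  the mixture against an exhaustive subset-enumeration oracle at
  $10^{-12}$.
* Degree-zero agents are retained in the network but excluded from pairwise
  validation (their preference vectors are undefined); the count is logged.
* The repeating decimals of the worked example are carried as exact
  rationals ($118/300$, $32/75$), never as truncated decimals.
* Pairs are iterated and emitted in locale-independent lexicographic order,
  so outputs are byte-stable across platforms.
* Empty predictions at strict thresholds have precision defined as 0 and
  flagged (`empty_prediction`), keeping ensemble averages of F1 defined.
  A consequence worth knowing: precision is *not* a per-run monotone
  function of the threshold — tightening $\alpha$ can drop a true positive
  while false positives remain, and at the strictest levels the
  empty-prediction convention can pull run-level precision to zero. Recall,
  by contrast, is monotone run by run (the edge set only shrinks), and the
  tests assert exactly that.
* A pair significant in both directions keeps both signed edges; the triad
  census resolves such pairs to the smaller p-value by default
  (`multi_edge = "min_p"`, with `"exclude"` as the alternative), since
  multigraph triads have no standard balance classification.

## Known limitations

* The null model treats events as interchangeable; validated links between
  agents concentrated on systematically popular events should be read with
  care.
* Preference vectors estimated inside short rolling windows are noisy;
  window-level p-values are best interpreted through medians over pairs, as
  in the affiliation-switch use case.
* The influence model is one concrete generator among many consistent with
  its verbal description; reconstruction figures obtained from it carry that
  model uncertainty, which is why the benchmark assertions use tolerances
  far looser than the Monte-Carlo error of the ensembles.
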