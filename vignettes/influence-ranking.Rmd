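---
title: "Ranking influential spreaders with INF: model, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ranking influential spreaders with INF}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(infnet)
```

## The problem

Given a network of social or biological contacts, which nodes, if initially
"infected" with a disease, rumour or signal, spread it furthest? The
reference answer is simulation: seed a node, run a spreading process many
times, average the final outbreak size. That is far too expensive as a
ranking method, so the field uses *centralities* — cheap structural scores —
and judges them by how well their ranking agrees with the simulated one.
This vignette describes the indicator this package is built around, the
conventions behind every computed quantity, and the choices made where the
design was genuinely open.

## The INF indicator

For node $i$ with neighbourhood $\Gamma(i)$, edge weights $w_{ij}$
($w_{ij}=1$ for unweighted graphs) and neighbour degrees $k_j$:

$$\mathrm{raw}(i) \;=\; \sum_{0 < d_{ij} \le R}
  \frac{w_{ij}}{k_j}\cdot\frac{1}{d_{ij}^{2}},\qquad
\mathrm{INF}(i) \;=\; \frac{1}{1+e^{-\mathrm{raw}(i)}}.$$

The intuition is an attention budget: every node divides a unit of influence
evenly among its $k_j$ neighbours, and $i$'s raw influence is the total
share it receives, discounted by squared distance beyond the first hop. A
high-degree neighbour contributes little (its attention is split many ways);
a degree-one neighbour contributes a full unit. This is what separates INF
from degree centrality at identical cost order: on the built-in kite fixture,
Ike has the second-lowest degree but the second-highest INF, because his
single-degree neighbour Jane depends on him completely.

Conventions, all visible in `methodParams()` of the returned `ScoreTable`:

* **Truncation radius `R`** (default 1, the recommended operating point).
  At $R=1$ all $d_{ij}=1$ and the distance factor is moot. For $R>1$ the
  package defaults to $d^2$ in the *denominator* — the same decay the
  gravity family (`gravityCentrality()`, `localGravity()`) uses — and
  exposes `distanceWeight = "numerator"` as the alternative reading, since
  with a generalized neighbourhood either placement defines a usable
  semi-local score. Distances are always hop counts; weights enter only
  through the $w_{ij}$ factor (and, for non-adjacent pairs within radius
  $R>1$, $w_{ij}=1$).
* **Normalization** (default `"logistic"`). The raw sum is unbounded above;
  the logistic map sends it to $(0,1)$ with the natural anchors: an isolated
  node scores exactly $0.5$ and any connected node scores above $0.5$.
  Because the map is strictly monotone the ranking — the quantity that
  matters for influencer identification — is identical in `"raw"` mode,
  which is kept for transparency and for downstream statistics that want
  the unsquashed sums (Kendall tau is invariant between the two; the test
  suite checks this).

### Multilayer networks

A `MultilayerNetwork` is a family of layer graphs $G_\alpha$ plus weighted
inter-layer couplings; `supraAdjacency()` assembles the block matrix with
$A_1\ldots A_L$ on the diagonal and the couplings off it, indexed
layer-major as `"layer::node"` replicas. `infScoresMultilayer()` evaluates
the INF sum over that supra-graph, so at $R=1$ a replica collects
$w_{ij}/k_j$ from every intra-layer *and* inter-layer neighbour.

One convention was genuinely open: the degree $k_j$ of a neighbour reached
through an inter-layer edge. The default (`degreeMode = "supra"`) uses the
replica's full supra-degree (intra-layer plus inter-layer incident edges),
because the model treats both edge types as equal transmission channels;
this also makes the multilayer score exactly the monolayer score of the
supra-graph, which is the cleanest invariant to test against. The
alternative (`"intra"`) counts only the neighbour's intra-layer degree and
is provided as a switch; replicas with no intra-layer edges then contribute
nothing. With one layer and no couplings both reduce to the monolayer
indicator. `aggregate = TRUE` additionally sums a physical node's raw
scores across its replicas before normalizing, for per-individual rankings.

## Baseline centralities

The comparison set uses these exact conventions (chosen so that the
standard worked-example values are reproduced to four decimals):

| indicator | convention |
|---|---|
| degree | unit degree / $(N-1)$; raw mode = weighted degree |
| betweenness | endpoints excluded, divided by $(N-1)(N-2)/2$ |
| closeness | $(N-1)/\sum_j d_{ij}$; component-wise on disconnected input |
| eigenvector | principal adjacency eigenvector, $L_2$-normalized |
| PageRank | fixed point of $PR(i)=(1-d)/N+d\sum_j a_{ji}PR(j)/k_j^{out}$, default $d=1$ (pure recursion; $0.85$ is the conventional teleporting option) |
| Katz | $x=\alpha A x+\beta\mathbf 1$, $\alpha=0.1$, $\beta=1$, $L_2$-normalized |
| clustering | triangles / wedges, 0 below degree 2 |
| gravity | $\sum_{d\le 3} ks(i)ks(j)/d^2$ (k-shell masses) |
| local gravity | $\sum_{d\le R} k_ik_j/d^2$; `R = "auto"` gives $\lceil D/2\rceil$ on the largest component |

All baselines are computed on the unit-weight skeleton: no weighted variant
of these indicators is defined here, and mixing conventions would make the
comparison experiments incoherent. Numerical notes: the eigenvector score
is obtained by power iteration from a uniform start with the convergence
contract $\|Ax-\lambda x\|\le \mathrm{tol}\,\|x\|$ (non-convergence is an
error, not a silent result); PageRank uses a *lazy* power iteration
($x \leftarrow (x + T(x))/2$), which keeps the damping-free $d=1$ case
convergent on periodic structures such as bipartite graphs and directed
cycles; Katz refuses $\alpha\ge 1/\lambda_{\max}$.

## SIR simulation

`sirRun()` implements the discrete-time susceptible–infected–recovered
process with synchronous, generation-based updates: at each step every
infectious node attempts each susceptible neighbour independently with
probability $\min(1, w_{ij}\beta)$, then recovers with probability $\gamma$
(default 1, so each node transmits during exactly one step). Nodes infected
at step $t$ become infectious at $t+1$. The recovery-after-transmission
ordering is the only one under which $\gamma=1$ still spreads at all, and
its simulated outbreak sizes match the published kite reference values.
Two further conventions:

* **Iterations** are the number of synchronous steps until no infectious
  node remains, counting the step of the last recovery. A fully
  deterministic flood ($\beta=1,\gamma=1$) from the kite's hub therefore
  takes 5 steps: four infection waves plus the final tail recovery. The
  step count is reported as a diagnostic; outbreak size is the quantity the
  experiments gate on.
* **Inter-layer transmission** uses $\beta_M = w_{ij}\beta$; weighted
  intra-layer edges scale the same way (one rule for all contacts), with
  unit weights leaving $\beta$ untouched.

`spreadEstimate()` aggregates `nRuns` independent runs (Monte-Carlo SE of
the mean scales as $\sigma/\sqrt{\mathrm{nRuns}}$; at 10,000 runs on the
kite that is about 0.02 recovered nodes), and
$\beta_c=\langle k\rangle/(\langle k^2\rangle-\langle k\rangle)$
(`epidemicThreshold()`) locates the interesting regime — the experiments
default to $\beta=0.35$ on the kite, just above its $\beta_c\approx0.316$.
All stochastic entry points take an `rngSeed` and replay bit-identically.

## Evaluation experiments

* **Kendall tau** (`kendallTau()`) is deliberately *tau-a*:
  $(N_c-N_d)/\binom n2$ with tied pairs counted neither way. Ties are
  informative here — an indicator that cannot separate nodes (degree on a
  near-regular graph) *should* lose agreement — so the tie-corrected tau-b
  would hide exactly the failure mode the comparison is about. The
  implementation is checked against a brute-force $O(n^2)$ pair enumeration.
* **Ground truth** (`sirGroundTruth()`) seeds every node alone in `nRuns`
  simulations and records mean $P(i)=N_R/N$.
* **Removal curves** (`removalCurve()`) delete nodes in descending score
  order — computed once on the intact graph, since re-scoring after every
  removal answers a different (adaptive-attack) question, available via
  `recompute = TRUE` — with ties broken by ascending identifier. Removed
  nodes are deleted, not isolated; the component count therefore rises to a
  maximum when the last edge disappears and then falls to zero.
* **Top-k spreading** (`topkSpread()`) seeds each indicator's top-k set at
  $\beta = 1.5\,\beta_c$ by default (configurable, always recorded in the
  result's attributes) and uses common random numbers across cells so that
  indicator curves are directly comparable run-by-run.

## Synthetic data and what the tests do (and do not) show

The generators (`randomGraph()` for Erdős–Rényi, Barabási–Albert and
Watts–Strogatz monolayers; `toyMultilayer()` for coupled Erdős–Rényi
layers) are seeded and label-stable, and exist to exercise every code path
at desk scale: the property tests run on graphs of 8–60 nodes, the
worked-example regressions on the 10-node kite and the 34-node karate club,
and the SIR reference check uses 10,000 runs per seed — sizes chosen so the
whole suite completes in well under a minute while leaving Monte-Carlo
error far below the tested tolerances. These fixtures emulate the
*structure* classes real benchmarks fall into (homogeneous, scale-free,
small-world, multiplex) but not their scale, degree heterogeneity extremes
or community structure; passing tests certify the implementation of the
indicator and experiments, not a claim that INF dominates its competitors
on any particular real dataset. The experiment harness accepts arbitrary
user-supplied edge lists for that purpose.

## Degenerate inputs and edge cases

Readers reject self-loops, duplicate edges, non-positive weights and
malformed lines (naming the line number). Isolated nodes: degree/INF score
0 (logistic 0.5), closeness 0 with a warning, one component each. Empty
graphs: 0 components; summaries refuse them. Regular graphs have undefined
assortativity (reported as `NA`) and perfect-matching graphs an undefined
epidemic threshold (an error, since $\langle k^2\rangle\le\langle
k\rangle$). `topK()` breaks score ties by ascending node identifier so all
orderings are reproducible.

## Known limitations

* Betweenness/closeness-based experiments are quadratic-or-worse in network
  size; INF itself is linear in edges, but the *evaluation* harness is meant
  for benchmark-scale graphs, not millions of nodes.
* Layers are unordered: temporal or ordinal layer semantics are out of
  scope.
* GraphML/GML input is not parsed; convert to the plain-text edge-list
  dialects first.
* Influence maximization proper (optimizing a seed *set* jointly) is not
  attempted; `topK()` selects by individual score.
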