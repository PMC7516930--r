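# infnet

Identifying influential spreaders — nodes whose infection, rumour or message
reaches the largest part of a network — is a core task in social-network
analysis, epidemiology and systems biology. Global centralities (betweenness,
closeness, eigenvector) rank such nodes well but cost too much on large
graphs; pure degree is cheap but blind to a node's surroundings. `infnet`
implements a local influence indicator, **INF**, that keeps the cost of
degree centrality while looking one step deeper, and extends it to
**multilayer networks** (several interaction layers coupled by inter-layer
edges), where classical centralities do not directly apply.

## The indicator

For a node *i* of a (possibly weighted) graph, with truncation radius
*R* = 1,

```
raw(i) = Σ_{j ∈ Γ(i)}  w_ij / k_j          INF(i) = 1 / (1 + exp(−raw(i)))
```

where Γ(i) are *i*'s neighbours, `w_ij` the edge weight (1 for unweighted
networks) and `k_j` the neighbour's degree: each neighbour hands node *i* a
share of its attention, inversely proportional to how many neighbours it has
to share among. The logistic map normalizes the open-ended sum into (0, 1)
without changing the ranking. For `R > 1` the sum extends over the whole
*R*-hop neighbourhood with a `1/d_ij²` gravity-style decay. On a multilayer
network the same sum runs over the **supra-graph** — the block structure with
the layer adjacencies `A_1 … A_L` on the diagonal and inter-layer couplings
`I_αβ` off it — so intra- and inter-layer contacts contribute on equal
footing (`supraAdjacency()` exposes the matrix itself).

Around the indicator the package provides:

* the classical comparison centralities: degree, betweenness, closeness,
  eigenvector, PageRank, Katz, local clustering, gravity, gravity-plus and
  local-gravity (`degreeCentrality()`, …, `localGravity()`),
* a discrete-time SIR spreading simulator with per-contact probability
  `min(1, w·β)` and the inter-layer rule `β_M = w_ij·β`
  (`sirRun()`, `spreadEstimate()`, `epidemicThreshold()`),
* the standard validation experiments: Kendall tau-a agreement with SIR
  ground truth (`kendallTau()`, `tauBenchmark()`), targeted node-removal
  fragmentation curves (`removalCurve()`), and top-k seeding spread curves
  (`topkSpread()`),
* plain-text readers/writers for edge lists and multiplex edge lists
  (`readEdgeList()`, `readMultiplex()`), the Krackhardt kite and Zachary
  karate-club fixtures, seeded synthetic generators, and a command-line
  front end (`infnetMain()`; wrapper script in `inst/scripts/infnet`).

## Worked example: the Krackhardt kite

The 10-node kite is the classic network on which different centralities
crown different nodes. INF agrees with degree that Diane is the hub, but
separates the tail nodes better:

```r
library(infnet)
g  <- kiteNetwork()
st <- infScores(g)           # R = 1, logistic normalization
st
#> ScoreTable <inf> over 10 nodes
#>   params: R=1, normalization=logistic, distanceWeight=denominator
#>   top: Diane=0.8273, Ike=0.7914, Fernando=0.7830, Garth=0.7830, Andre=0.7211 ...

topK(st, 4)
#> [1] "Diane"    "Ike"      "Fernando" "Garth"
```

Diane's score comes from `raw = 1/4 + 1/4 + 1/3 + 1/3 + 1/5 + 1/5 = 1.5667`
and `1/(1+e^−1.5667) = 0.8273`. Note Ike: degree ranks him ninth of ten, but
his neighbour Jane depends on him entirely (`1/k_Jane = 1`), so INF lifts
him to second place — the "gatekeeper of a dependent periphery" pattern that
pure degree misses.

Simulated spreading confirms the ranking. Seeding Diane in 10,000 SIR runs
at β = 0.35, γ = 1:

```r
spreadEstimate(g, "Diane", beta = 0.35, nRuns = 10000, rngSeed = 42)
#> SIROutcome: 10000 runs on N=10 | mean recovered 5.2756 (P = 0.5276), mean steps 3.3487

networkSummary(g)
#> NetworkSummary
#>   |V| = 10  |E| = 18
#>   <k> = 3.6000  <d> = 1.9778
#>   |C| = 0.5200  r = 0.1525  |H| = 1.1574  beta_c = 0.3158
```

An infection seeded at Diane ends up reaching about half the network on
average (P ≈ 0.53); β = 0.35 sits just above the epidemic threshold
β_c ≈ 0.316, the regime where seed choice matters most.

The same pipeline runs from the shell:

```sh
Rscript inst/scripts/infnet rank --method inf kite.tsv
Rscript inst/scripts/infnet sir --seed-node Diane --beta 0.35 --runs 10000 --rng-seed 42 kite.tsv
```

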