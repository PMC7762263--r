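# iacd — community detection by internode attraction

`iacd` finds non-overlapping communities in undirected, unweighted
networks — social graphs, protein-interaction networks, co-purchase
graphs — without any user-set parameter. It is aimed at analysts who need
stable, reproducible partitions on networks from a few dozen to hundreds of
thousands of nodes, where popular alternatives either require the number of
communities up front or give a different answer on every run.

## The method

Every node gets an influence score combining how connected it is with how
central it sits:

    IF(v)  = Deg(v) × KScore(v)          (degree × k-core index)
    GIF(v) = IF(v) / max_u IF(u)         (normalized to (0, 1])

Pairs of nearby nodes then attract each other like masses under gravity.
For a node *v* and a candidate *m* within distance 2 (reachable through
*v*'s neighbours):

    Attr(v, m) = P(v, m) · GIF(v) · GIF(m) / SL(v, m)²
    P(v, m)    = (|N(v) ∩ N(m)| + 1) / Deg(v)

where SL is the shortest-path length (1 or 2). Each node is paired with its
strongest attractor (ties: smaller path length, then the tie policy), and
communities are the connected components of the resulting pair graph — a
merge that provably does not depend on processing order. The whole pipeline
costs O(n⟨k⟩² + e).

## Worked example

The bundled 16-node example network illustrates every stage (it validates
its own structural tables on construction):

```r
library(iacd)
ex <- example_network()
influence_table(ex$network)
#> Node influence table (16 nodes, max influence 15)
#>  node deg kscore influence  gif
#>     1   5      3        15 1.00
#>     2   4      3        12 0.80
#>     3   4      3        12 0.80
#>     4   5      3        15 1.00
#>     5   3      3         9 0.60
#>     ...
#>     8   2      2         4 0.27
#>    13   4      2         8 0.53
#>    16   3      2         6 0.40
```

Node 1 has the network's maximum influence (degree 5 in the 3-core), so
its `gif` is 1.00; node 8 scores 4/15 ≈ 0.27. Its strongest attractor is
node 4 — adjacent (`sl = 1`), three shared neighbours, so
`Attr(1,4) = (3+1)/5 · 1 · 1 / 1² = 0.8` — and the full detection returns
the three communities the network was built around:

```r
iacd_detect(ex$network)
#> Partition of 16 nodes into 3 communities
#>   [1] n=5: 1 2 3 4 5
#>   [6] n=7: 6 7 8 9 10 11 12
#>   [13] n=4: 13 14 15 16
evaluate_partitions(iacd_detect(ex$network), ex$truth)
#> nmi     1.0000
#> ari     1.0000
#> purity  1.0000
```

The metric report reads: the detected partition carries exactly the same
information as the ground truth (NMI 1), agrees on every node pair
(ARI 1), and every community is pure (purity 1).

## Command line

A thin launcher wraps the same functions
(`system.file("scripts", "iacd", package = "iacd")`):

```sh
iacd detect    --input net.edges --output net.communities
iacd evaluate  --pred net.communities --truth truth.communities
iacd benchmark --mu 0.1 --mu 0.2 --n 1000 --seeds 1,2,3 --output bench.csv
```

`detect` reads edge-list or GML input and writes a `node<TAB>community`
file; `evaluate` prints an NMI/ARI/purity TSV; `benchmark` generates
seeded LFR instances over a parameter grid, runs the detector, and writes
one CSV row per (configuration, seed).

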