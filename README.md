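# ipdnet

Divide-and-conquer iterated Prisoner's Dilemma tournaments on social
networks, for researchers in evolutionary game theory who want a
reproducible, exactly-validated simulator of strategy competition on
graphs.

## The problem

In spatial evolutionary games a node classically chooses one move —
cooperate (C) or defect (D) — and plays it against all neighbours.  Real
actors do not work that way: they keep separate relationships.  In the
*divide-and-conquer* convention each node holds a single **strategy** but
plays an independent iterated game on every edge, conditioning each move
on the private history with that neighbour.  `ipdnet` asks which of two
strategies prevails on a network under this convention, and how much the
answer depends on *where* a strategy's players sit in the degree
sequence.

The stage game uses payoffs (R, S, T, P) = (3, 0, 5, 1) with
T > R > P ≥ S and 2R > T + S.  Fourteen classic strategies are built in:
AC, AD, Random, TFT, GTFT, WSLS, extortionate and generous
zero-determinant strategies (ZDe with s_X − P = 3(s_Y − P), ZDg with
s_X − R = 3(s_Y − R)), Hard Joss, TF2T, Grim, Hard TFT, Hard Majority and
Hard TF2T.  Ten of them are memory-one, i.e. a vector
p = (p_CC, p_CD, p_DC, p_DD) of cooperation probabilities conditioned on
the previous joint outcome.

Three layers:

1. **Exact pairwise payoffs** — `expected_payoff()` computes the long-run
   per-round payoff E(a, b) by the Press–Dyson determinant ratio
   D(p, s, S_x)/D(p, s, 1) for ergodic memory-one pairs, exact cycle
   detection for deterministic pairs, and an exact ≤256-state Markov
   chain for every other pair not involving Hard Majority (whose
   unbounded counter requires an ensemble simulation).  The invasion
   statistic δ(a, b) = E(a, a) − E(b, a) is `payoff_delta()`.
2. **Round-robin tournament** — `round_robin()` plays all 91 pairs
   (10,000 rounds × 100 repeats), decides winners by head-to-head total
   with a self-play tie-break, and labels losers *weak* / winners
   *strong*.  Exactly 54 matches are decided; the rest are exact draws.
3. **Network tournament** — `dnc_run()` plays per-edge games on
   Watts–Strogatz or Barabási–Albert presets (N = 1024, 3,072 / 3,066
   edges), with epoch fitness φ (accumulated) or ψ (= φ/k) and
   synchronous best-takes-over imitation every 200 rounds, up to 20,000
   rounds or extinction.  `assign_strategies()` seeds a fraction α of the
   weak half onto the top-degree nodes; `run_sweep()` runs the
   (α × replicate) grid with per-cell reproducible substreams.

## Worked example

```r
library(ipdnet)

payoff_delta("random", "ad")
#> [1] -0.75
payoff_delta("zde", "random")
#> [1] -0.5208333

set.seed(1)
round_robin(rounds = 10000, repeats = 100)
#> Round-robin scoreboard: 10000 rounds x 100 repeats
#> 54 of 91 matches decided (non-draw)

set.seed(1)
net <- network_preset("basn1")
net
#> ipd_network: 1024 nodes, 3066 edges, mean degree 5.99
asg <- assign_strategies(net, "tft", "zde", alpha = 0)
dnc_run(net, asg, dnc_config("psi"))
#> dnc_trajectory: tft (weak) vs zde (strong), 100 epochs, cap at round 20000, f_w = 0.9258

expected_payoff("zde", "ac")
#> E(zde, ac) = 3.72727  [determinant]
```

Reading the output: δ(Random, AD) = −0.75 < δ(AD, Random) = 0.5 means AD
wipes Random out on networks; the scoreboard decides 54 of 91 matches
(the other 37 are exact draws among mutually-cooperating strategies plus
AD vs Hard Majority); and although ZDe beats TFT head-to-head, TFT — the
*weak* strategy — ends up holding ~93% of the scale-free network under
average-payoff fitness, because extortioners earn little from each other.

A thin command-line interface over the same functions is installed at
`inst/cli/ipdnet.R` (subcommands `expected`, `table`, `roundrobin`,
`run`, `sweep`, `fixtures`).

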