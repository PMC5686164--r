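---
title: "Divide-and-conquer Prisoner's Dilemma tournaments on networks"
author: "ipdnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Divide-and-conquer Prisoner's Dilemma tournaments on networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

## The model

`ipdnet` simulates competition between two strategies of the iterated
Prisoner's Dilemma (IPD) on a social network, under the
*divide-and-conquer* convention: a node holds a single strategy but plays a
completely independent iterated game with each neighbour, so its move
toward one neighbour depends only on its private history with that
neighbour.  This contrasts with the classic one-individual-one-move spatial
games, where a node must play the same move against everyone.

The stage game uses payoffs \((R, S, T, P) = (3, 0, 5, 1)\) — reward,
sucker's payoff, temptation, punishment — satisfying \(T > R > P \ge S\)
and \(2R > T + S\).  Writing a player's move as
\(\Omega_i = (X_i, 1 - X_i)\) with \(X_i = 1\) for cooperation, the single
game payoff is the bilinear form
\(\Omega_i^{\mathsf T} \begin{pmatrix} R & S \\ T & P \end{pmatrix} \Omega_j\).

Each *epoch* consists of \(\mathcal{R} = 200\) rounds.  Node \(i\)'s
accumulated fitness is
\(\varphi_i = \sum_{j \in N_i} \sum_{r=1}^{\mathcal R} \mathcal{P}_{ijr}\),
the payoff summed over all its edges and rounds of the epoch, and its
average fitness is \(\psi_i = \varphi_i / k_i\) with \(k_i\) the degree.
At the end of every epoch all nodes update synchronously by
*best-takes-over* local learning: a node keeps its strategy if its fitness
is at least that of every neighbour, and otherwise copies the strictly
fittest neighbour.  A run lasts 20,000 rounds (100 updates) or stops at
the extinction of either strategy; the final weak-strategy frequency
\(\bar f_w\) is averaged over the last 2,000 rounds, or is 0/1 at
extinction.

Two details matter and are easy to get wrong:

* **Histories persist across strategy updates.**  A node that converts
  from unconditional defection to tit-for-tat does *not* restart with a
  cooperative first move; its next move on each edge is the new policy
  applied to the old history.  The grim trigger is likewise evaluated
  from the persisted opponent-defection count.
* **Exact fitness ties.**  \(\varphi\) is an integer-valued sum, exact in
  doubles, and \(\psi\) comparisons are done by cross-multiplication
  (\(\varphi_i k_j\) vs \(\varphi_j k_i\)), so "keep on tie" is decided
  exactly rather than at floating-point mercy.

## The fourteen strategies

The tournament pool is the classic set: AC, AD, Random (fair coin), TFT,
GTFT, WSLS (Pavlov), an extortionate and a generous zero-determinant
strategy (ZDe, ZDg), Hard Joss, TF2T, Grim, Hard TFT, Hard Majority, and
Hard TF2T.  All open cooperatively except Hard Majority and AD; Random
flips its coin.  Ten of them are *memory-one*: their play is a vector
\(p = (p_{CC}, p_{CD}, p_{DC}, p_{DD})\) of cooperation probabilities
conditioned on the previous joint outcome (own move first).  The
literature names these strategies but rarely fixes every parameter, so the
package pins them as follows, each choice validated against the published
expected-payoff table by the exact machinery below:

| strategy | definition |
|---|---|
| `gtft` | \((1, 1/3, 1, 1/3)\) |
| `wsls` | \((1, 0, 0, 1)\) |
| `zde` | \((11/13, 1/2, 7/26, 0)\), extortion factor \(\chi = 3\) |
| `zdg` | \((1, 2/11, 1, 4/11)\), generosity factor 3 about \(R\) |
| `hard_joss` | \((0.9, 0, 0.9, 0)\): TFT that forgives nothing and defects spontaneously 10% of the time |
| `tf2t` | defects only after two consecutive opponent defections |
| `hard_tft` | defects if the opponent defected in any of the last three rounds |
| `hard_majo` | opens with D; defects whenever opponent defections \(\ge\) cooperations to date |
| `hard_tf2t` | defects after two consecutive opponent defections within the last three rounds |

The ZD vectors satisfy the Press–Dyson linear relations exactly:
\(E(\mathrm{ZDe}, X) - P = 3\,(E(X, \mathrm{ZDe}) - P)\) and
\(E(\mathrm{ZDg}, X) - R = 3\,(E(X, \mathrm{ZDg}) - R)\) for every
opponent \(X\), which the test-suite asserts against all fourteen.

Reproducibility contract: stochastic strategies consume exactly one
uniform draw per decision from R's RNG stream, deterministic ones none;
in engine loops, edges are visited in storage order with the
lower-numbered endpoint drawing first.  The compiled engine and the pure-R
reference engine follow the same order, and the tests check that their
trajectories are bit-identical under a fixed seed.

## Exact expected payoffs

`expected_payoff()` computes the long-run per-round payoff \(E(a, b)\) of
one strategy against another by the strongest applicable method:

1. **Determinant** (ergodic memory-one pairs).  The joint play is a Markov
   chain on the four outcomes; Press and Dyson's determinant identity
   gives the stationary payoff as a ratio \(D(p, s, S_x)/D(p, s, 1)\) of
   4×4 determinants.  A pair is treated as ergodic when
   \(|D(p, s, 1)| > 10^{-9}\).
2. **Cycle** (deterministic pairs).  Exact play from the defined first
   moves until the bounded joint state — both windows, both trigger
   flags, plus Hard Majority's exact counter — recurs; the cycle average
   is exact.  When a majority counter drifts monotonically (e.g. against
   AC), recurrence of the reduced state with a provably frozen majority
   sign is used instead.
3. **Chain** (anything else not involving Hard Majority).  Every other
   strategy is a function of the last three joint moves plus trigger
   flags, so the pair is an exact finite Markov chain on at most 256
   states.  The limiting distribution from the defined first moves is
   computed by repeatedly squaring the lazy chain \((M + I)/2\) (with row
   renormalisation against round-off drift), which converges for
   absorbing and periodic chains alike.
4. **Simulation** (Hard Majority vs a stochastic opponent).  The majority
   counter is unbounded and, against a random opponent, performs a random
   walk — single-trajectory time averages do not self-average, and
   against ZDe the pair absorbs into mutual defection only on very long
   horizons.  The tabulated quantity is therefore the *ensemble* mean of
   the published match protocol: 10,000-round matches repeated 100 times,
   reported with a standard error over repeats.

Methods 1–3 are exact; the tests cross-validate them against long
independent simulations (four standard errors) and against each other
where two routes apply.  `payoff_table()` assembles all 196 ordered-pair
values in well under a minute, and `payoff_delta(a, b) = E(a,a) - E(b,a)`
gives the invasion statistic discussed in the results.

A note on the published table: its text rendering is garbled in places and
mixes two conventions for Joss (forgiving vs non-forgiving after own
defection).  The package follows the single convention above; the
test-suite freezes every cell that an independent oracle confirms and
documents the handful of inconsistent cells as excluded.

## The two tournaments

**Round robin** (`round_robin()`): all 91 unordered pairs play 10,000
rounds × 100 repeats.  Higher head-to-head total wins; exact ties fall
back to the self-play total (the mean of the two seats of the strategy's
self-match); double ties are draws.  Nine strategies are *nice* (never
defect first), so their 36 mutual matches are exact all-cooperation draws,
and AD vs Hard Majority is an exact all-defection draw — leaving 54
decided matches, whose losers are the *weak* strategies of the network
tournament.

**Network tournament** (`dnc_run()`, `run_sweep()`): a preset graph —
Watts–Strogatz (\(N = 1024\), \(k = 6\), \(p \in \{0.1, 0.2\}\), 3,072
edges) or Barabási–Albert (\(m = m_0 = 3\), \(N \in \{1024, 2048\}\)) —
is split half-and-half between the weak and the strong strategy.  The
seeding parameter \(\alpha\) forces \(\varepsilon = \lfloor \alpha N/2
\rfloor\) weak players onto the highest-degree nodes (descending degree,
ties broken by a seeded shuffle — important on the near-regular WS
graphs); the remaining weak players are placed uniformly.  The published
grid is \(\alpha \in \{0, 0.01, \dots, 1\}\) with ten replicates each,
i.e. 20,200,000 rounds per match and 8,726,400,000 rounds across 54
matches and 8 configurations, which `sweep_accounting()` reproduces as
pure arithmetic.

## Generators and their defaults

The WS generator is the classic one: ring lattice of degree \(k\), each
lattice edge's far endpoint rewired independently with probability
\(p\), resampling on collisions, so the edge count is exactly \(Nk/2\).
The BA generator seeds with a complete graph on \(m_0\) nodes and
attaches \(m\) distinct degree-proportional edges per new node, giving
exactly \(\binom{m_0}{2} + (N - m_0)m\) edges — 3,066 at \(N = 1024\).
(The companion \(N = 2048\) figure printed alongside the study's 1024-node
count corresponds to an edgeless seed; the triangle-seed convention is
used consistently here, so `basn2` has 6,138 edges, three more than the
printed value.)  Presets are regenerated until connected; at these
parameters disconnection is vanishingly rare.

These generated graphs are the study conditions, not real social
networks: they reproduce degree heterogeneity (BA) and local clustering
with short paths (WS), but none of the community structure, degree
correlations, or edge dynamics of empirical networks.  Passing tests
therefore certify the dynamics on these canonical topologies only.

## Numerical and design choices

* **Synchronous updates** from a single end-of-epoch fitness snapshot;
  extinction is checked at epoch boundaries, where composition alone can
  change.
* **Fitness resets each epoch** (the accumulation window is the epoch, not
  the whole run).  This is the literal reading of the fitness definition;
  it also makes \(\varphi\) bounded and exactly representable.
* **Tie-breaking**: self wins ties with the neighbourhood maximum; ties
  among strictly better neighbours are broken uniformly at random, one
  draw per tied node in ascending node order.
* **Ergodicity tolerance** \(10^{-9}\) on the normalising determinant;
  lazy-chain squaring runs 60 doublings (\(2^{60}\) steps), ample for
  any mixing time these 256-state chains exhibit.
* **Degenerate inputs**: a population initialised with a single strategy
  terminates at round 0 with frequency 0/1 by label bookkeeping; odd node
  counts and non-divisible epoch lengths are rejected at construction.
* **Problem sizes in the tests**: the acceptance checks run the full
  published round-robin protocol, the full 196-cell table, and ten
  replicates of each headline network configuration on the 1024-node BA
  preset; unit tests use 4–8-node fixtures where exact hand computation
  is possible.

## What the package does not do

Asynchronous or Moran updating, pairwise-comparison (Fermi) imitation,
mutation in strategy copying, co-evolving topology, user-defined
strategies beyond the fourteen, and discounted (finite-horizon) expected
payoffs are all out of scope.  The single-trajectory non-convergence of
Hard Majority against stochastic opponents is inherent to that strategy's
unbounded counter; the package reports the ensemble quantity and a
standard error rather than pretending a stationary value exists.

## A worked example

```{r example, eval = FALSE}
library(ipdnet)

# Exact invasion statistics
payoff_delta("random", "ad")   # -0.75: AD invades a Random population
payoff_delta("zde", "random")  # -0.52: Random resists the extortioner

# Scoreboard
set.seed(1)
sb <- round_robin(rounds = 10000, repeats = 100)
sb$n_nondraw                   # 54

# One network match
set.seed(1)
net <- network_preset("basn1")
asg <- assign_strategies(net, "tft", "zde", alpha = 0)
dnc_run(net, asg, dnc_config("psi"))
```

The chunk above is not evaluated while building the vignette (a full run
takes a few seconds per replicate); the README shows the same example
with its actual output.
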