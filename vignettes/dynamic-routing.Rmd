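---
title: "The dynamic routing model: current flow as a policy under sparse reward"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The dynamic routing model: current flow as a policy under sparse reward}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dynroute)
```

## The model

`dynroute` implements a model-based reinforcement-learning agent whose world
model is a physical object: a directed, rectified resistive network. The
architecture is motivated by gap-junction connectivity between the parallel
Kenyon-cell axons of the insect mushroom body — each state of a discrete task
is one node (one Kenyon cell under one-hot coding), and the conductance
`W[i, j]` of the directed edge `i -> j` plays the role of a rectifying,
adaptive gap junction. Three mechanisms make this a complete agent:

1. **Latent learning of transitions.** Whenever the agent experiences the
   state change `i -> j` (with or without reward, and regardless of which
   action caused it), the edge conductance grows by a saturating Euler step

   `W[i,j] <- W[i,j] + dt * alpha * (w1max - W[i,j])`,

   so after `n` traversals `W[i,j] = w1max * (1 - (1 - dt*alpha)^n)`. The
   conductance matrix converges to a graph of the environment's possible
   transitions, weighted by experience. There is no self-loop learning: the
   diagonal stays zero, so the network remains a transition model even when
   an action bounces off a wall.

2. **Grounding of goals.** Reward experienced in state `g` connects node `g`
   to the zero-potential ground with conductance `w2max` — permanently, across
   episodes. Tasks that announce their goal instead ground the announced
   target and release the previous one (`set_explicit_target()`). Value is
   therefore stored *only* at rewarded states; it is never propagated into a
   table.

3. **Current flow as planning.** At decision time the active state node is
   pinned to potential 1 and the node potentials solve Kirchhoff's current
   law, with each edge conducting only while its upstream potential exceeds
   its downstream potential (`I[i,j] = W[i,j] * (V_i - V_j)` when `V_i > V_j`,
   else 0). Current can only flow from the active state towards grounded
   goals, concentrating on the route of least effective resistance. The
   neighbouring state on the edge with the largest power consumption
   `P[i,j] = I[i,j] * (V_i - V_j)` becomes the *subgoal* `j'`; the action is
   then sampled with probabilities proportional to the second-order weights
   `W2[i, j', k]` (the "simplified" input mode; the power factor common to all
   actions cancels in the normalisation). A second plasticity rule credits
   actions: the action that actually produced `i -> j` gains
   `dt * alpha * beta` on `W2[i, j, k]`, while an action that was chosen for
   subgoal `j'` but failed to reach it decays by the factor
   `1 - dt * alpha * c`.

The model is written as a continuous-time system discretised by the Euler
method; one environment step advances time by `dt` (0.02 s in all presets).

### What the solver actually computes

Nodal analysis for bidirectional resistors is a single linear solve. The
rectified (diode-like) edges make the conducting set depend on the solution,
so `solve_circuit()` iterates an **active set**: solve the linear system
assuming a set of conducting edges, reclassify every edge by the sign of its
potential drop, and repeat until the classification is a fixed point
(tolerance `1e-10` on potentials, cap 100 iterations). Two numerical details
matter:

* **Hysteresis on ties.** An edge joining two equal-potential nodes carries
  no current either way; classifying it as blocked can flip the potentials
  back and forth indefinitely. Active edges therefore stay active at zero
  bias and deactivate only on a strictly reversed drop, while blocked edges
  activate only on a strictly positive drop. Plateaus of equal potential are
  then stable, and the returned currents still satisfy the strict-inequality
  reading of rectification (`I = W * max(V_i - V_j, 0)`). Past 40 iterations
  the classification additionally uses damped potentials; non-convergence is
  flagged rather than raised, and a flagged step falls back to a uniformly
  random action.
* **Degenerate drives.** Only the connected component containing the active
  state is solved (everything else carries no current and reports potential
  0). If that component contains no grounded node — always the case before
  the first reward — no current can flow, every node reachable through
  forward-conducting edges floats at the source potential, and the agent
  explores at random. Nodes attached to the source only through *blocked*
  diodes are electrically floating; their potential is not determined by the
  physics, and the solver reports 0 for them. The test suite consequently
  cross-checks the solver against a brute-force enumeration oracle on the
  *unique* observables (all currents, and potentials of current-carrying
  nodes).

### Shortest paths, or least resistance?

On a uniformly weighted **tree** the subgoal chain provably follows the
unique simple path to the grounded goal, which is also the breadth-first
shortest path; the suite verifies this exactly on random trees up to 25
nodes. On graphs with cycles the current concentrates on the route of least
*effective* resistance, and a bundle of parallel branches can draw more
current than a strictly shorter single corridor: in a few percent of
(graph, start) pairs on tree-plus-extra-edge graphs the greedy route is one
hop longer than the BFS distance. This is a property of the physics, not a
solver artefact; the corresponding property test bounds the detour instead
of asserting equality.

## Parameters

`agent_params()` bundles the tunables, with one preset per benchmark task:

| field | meaning (units) | taxi | voronoi | maggot |
|---|---|---|---|---|
| `dt` | Euler step per environment step (s) | 0.02 | 0.02 | 0.02 |
| `alpha` | first-order learning rate (1/s) | 0.05 | 0.05 | 0.001 |
| `beta` | second-order rate ratio (–) | 2 | 2 | 2 |
| `c` | second-order decrease factor (1/s) | 400 | 400 | 400 |
| `w_ij0` | initial edge conductance | 0 | 0 | 0 |
| `w1max` | edge conductance ceiling | 1 | 1 | 10 |
| `w_ijk0` | initial edge-to-action weight | 0.01 | 0.01 | 1e-10 |
| `w2max` | goal ground conductance | 1 | 1 | 1 |
| `n_actions` | action nodes N | 6 | 5 | 5 |
| `max_steps` | episode cap (steps) | 100000 | 10000 | 40 |
| `recalc_interval` | steps between circuit re-solves | 1 | 10 | 1 |

Notes on choices the formulation leaves open:

* `w_ij0 = 0` (no initial connectivity) is workable because all-zero edge
  powers trigger the uniform-random subgoal fallback; a "very weak initial
  connection" reading is available by overriding `w_ij0`.
* Second-order weights grow linearly and are deliberately **uncapped**; the
  multiplicative decrease keeps them nonnegative. They are stored as a dense
  `n x n x K` array prefilled with `w_ijk0` — semantically a default-valued
  sparse map, but orders of magnitude faster to index in R.
* `recalc_interval` re-solves the circuit every step in the Taxi and
  maggot presets, but every 10 steps in the Voronoi preset. This is more
  than a compute saving: a stale field is a *fixed*, strictly descending
  potential gradient, so following local maximum-power edges on it always
  makes progress toward the target, whereas re-pinning the moving source
  at potential 1 on every step can make the maximum-power edge at node A
  point to its neighbour B and the one at B point back to A — a subgoal
  ping-pong that each hop "successfully" completes and the second-order
  rule therefore reinforces. Navigation tasks with announced targets use
  the stale-field mode; the within-episode field is refreshed every 10
  steps and always at the episode's first decision.
* Softmax action selection and stochastic (power-proportional) subgoal
  sampling exist behind flags and are off by default, as in the benchmark
  configuration. A global first-order weight decay (forgetting) is likewise
  off by default.
* Episode resets are teleports, not experienced transitions: no edge is
  learned across an episode boundary (`agent_begin_episode()`), and in the
  maggot task none is learned across a dish transfer, which the model treats
  as an episode boundary.

## The environments and what they do (not) emulate

**Taxi** (500 states: 25 cells x 5 passenger locations x 4 destinations,
6 actions, the standard wall layout) is built as a full transition table and
cross-checked against an independent, map-derived implementation on all
500 x 6 pairs. Training is *sparse*: +20 on a successful dropoff and nothing
else, no step limit short of 100000. The conventional dense accounting (-1
per step, -10 per illegal pickup/dropoff, +20 on success) is computed by the
metrics module for evaluation only and never reaches the agent. Because the
destination is fixed within an episode, the learned graph decomposes into
four disconnected components, one per destination — a structural signature
the acceptance suite checks.

**Voronoi world**: 150 locations Poisson-disk-sampled in the unit square
(Bridson's algorithm), joined by their Delaunay triangulation
(Bowyer-Watson; no installed package provides one). Walls dual to a uniform
random spanning tree (Wilson's algorithm) are always opened so the world is
connected — unbounded episodes would otherwise be possible — and every other
wall opens independently with probability 0.3. Actions index each location's
ascending-sorted neighbour list; node degree varies, so the action count
does. The target is announced each episode and grounded explicitly; episodes
chain (each starts where the last ended). The two-goal variant grounds two
targets and ends at whichever is reached first.

**Petri dish**: a 5-location linear dish; uniform single-odour training
dishes and two-odour test dishes with opposed odour gradients; appetitive
actions move up-gradient (or randomly when there is no gradient), and
consuming fructose activates a dedicated perceptual state for one step and
grounds it. Thirty independent maggot agents per protocol, 40 steps per
dish, six training dishes then one test dish, with learning continuing in
the test. The preference index `PREF = (n_AM - n_OCT) / n_total` counts the
dish sides per step (middle counts to neither side); the learning index
`LI = (PREF[AM+] - PREF[OCT+]) / 2` contrasts reciprocal protocols.

None of these environments has sensory noise, partial observability,
continuous space, or stochastic transitions (outside the explicitly random
uniform-dish moves). Passing tests therefore demonstrate the mechanism —
latent graph learning plus current-driven routing solves sparse-reward
tasks — not robustness of that mechanism to noisy or aliased perception.

## The Q-learning baseline

Tabular Q-learning runs under the identical sparse-reward configuration
(defaults `lr = 0.1`, `gamma = 0.99`, `epsilon = 0.1`, zero-initialised
table; for the Voronoi task the Q state is the (location, target) pair).
Under sparse reward the zero table makes greedy selection degenerate —
every action ties — so the tie-breaking convention dominates behaviour.
`epsilon_greedy()` defaults to uniformly random tie-breaks, but the episode
runner defaults to `tie_break = "first"`, the first-index argmax convention
of common array libraries: it is the convention that reproduces the
published failure regime (episode step counts frequently pinned at the cap,
no convergence of the moving-average reward) on *both* benchmark tasks,
whereas uniform tie-breaks reduce the baseline to a plain random walk and
never hit the cap. Both conventions are available; the sanity check that the
same code converges to a successful policy under the conventional dense
reward runs in the suite. The magnitude of the baseline's failure depends
strongly on this convention (and on the unknowable details of the original
baseline), so the baseline comparisons should be read as order-of-magnitude
statements.

## Problem sizes and reproducibility

Every run draws all randomness from R's single sequential RNG stream,
seeded once at the start of `run_experiment()`; identical `(task, seed,
config)` reproduce logs bit for bit, which the suite asserts. The packaged
study sizes: Taxi trains for 1000 episodes by default (the acceptance
script uses 800, which covers the ~400-episode convergence point plus a
stable final window, three seeds); Voronoi runs use 150 locations and 600 -
800 episodes, three seeds; the maggot experiment uses 4 protocols x 30
maggots x 7 dishes x 40 steps, aggregated over 10 seeds; Q-learning
baselines run 100 (Taxi) and 200 (Voronoi) episodes. The convergence
detector reports the first episode whose trailing 100-episode mean of the
evaluation reward reaches -10, and requires a full window, so it can never
fire before episode 100.

## Known limitations

* One-hot states only: learning with sparse multi-node codes is out of
  scope (the solver itself accepts multi-node drives, which the circuit
  tests exercise).
* The active-set solve is dense per component (`O(m^3)` per iteration);
  fine for hundreds of states, not for tens of thousands.
* Routing follows least resistance, which is not always fewest hops (see
  above).
* No forgetting by default: a changed environment leaves stale edges until
  `weight_decay` is enabled.
* Rewarded-state grounding is permanent; tasks whose goals move without
  announcement would mislead the agent.
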