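# dynroute

Reinforcement learning with a **rectified resistive network** as the world
model — a computational account of how adaptive, diode-like gap junctions
between parallel neural fibres (as hypothesised for Kenyon-cell axons in the
insect mushroom body) could solve the *sparse-reward* problem: tasks whose
only reinforcement arrives when the goal is reached.

The package is for computational neuroscientists and RL researchers who want
to run, probe or extend this "dynamic routing" agent. It ships:

* the circuit core: a nodal-analysis solver for directed networks whose
  edges conduct in one direction only (`solve_circuit()`);
* the agent: latent learning of state transitions as conductances, goal
  grounding, current-driven subgoal/action selection, second-order
  action plasticity (`drm_agent()`, `agent_step()`);
* three benchmark environments — the 500-state Taxi grid world, a
  procedurally generated 150-location Voronoi navigation world, and a
  linear Petri-dish olfactory conditioning task for larval *Drosophila*;
* a tabular Q-learning baseline run under identical sparse rewards, and
  metrics (moving averages, convergence detection, graph recovery,
  maggot preference/learning indexes).

## The model in one paragraph

States are nodes; the directed conductance `W[i,j]` encodes how often the
transition `i → j` has been experienced, learned by the saturating rule
`dW[i,j]/dt = α (w1max − W[i,j])` whenever that transition occurs. A
rewarded state is *grounded*: connected to the zero-potential reference with
conductance `w2max`. At decision time the current state node is pinned high
and Kirchhoff's current law is solved with rectified edges,

```
I[i,j] = W[i,j] (V_i − V_j)   if V_i > V_j,   else 0 ,
```

so current flows from the active state toward grounded goals along the route
of least effective resistance. The outgoing edge with maximal power
`P[i,j] = I[i,j](V_i − V_j)` names the next *subgoal* `j′`, and the action is
drawn with `P(a) ∝ W2[i,j′,a]`, second-order weights trained by
`dW2[i,j,k]/dt = αβ` on success and `dW2[i,j′,k]/dt = −αc·W2[i,j′,k]` when
action `k` misses its subgoal. No value table exists anywhere: value lives
only at grounded states and is interpolated on demand by the physics of the
circuit.

## Worked example

Current through a three-node chain, with the goal grounded at the far end:

```r
library(dynroute)
W <- matrix(0, 3, 3); W[1, 2] <- 1; W[2, 3] <- 1
sol <- solve_circuit(resistive_network(W, ground = c(0, 0, 1)), sources = 1)
tidy(sol)
#> # A tibble: 2 × 5
#>    from    to current power  drop
#>   <int> <int>   <dbl> <dbl> <dbl>
#> 1     1     2   0.333 0.111 0.333
#> 2     2     3   0.333 0.111 0.333
```

The potentials divide 1, 2/3, 1/3 across the chain; both edges carry the
same 0.333 current (Kirchhoff), each dissipating power 0.111 — it is these
powers that rank candidate subgoals.

Training the agent to navigate the 25-cell taxi location grid (goal
announced each episode, −1 per step / +20 at the goal for evaluation only):

```r
r <- run_experiment("taxi_locations_only", episodes = 150, seed = 7)
glance(r)
#>                  task seed n_episodes total_steps convergence_episode
#> 1 taxi_locations_only    7        150        1348                 100
#>   steps_to_convergence final_ma_eval final_ma_steps
#> 1                 1096           14.45          5.55
```

After ~1100 random-ish steps of latent learning the agent converges; the
final hundred episodes average 5.55 steps to the goal (evaluation reward
14.45 ≈ 20 − 5.55), i.e. near-shortest grid routes. `tidy(r)` returns the
per-episode log; `autoplot(r)` draws the reward curve;
`tidy(r$agent)` exports the learned conductance graph, whose thresholded
edges reproduce the grid adjacency.

The full benchmarks run the same way: `run_experiment("taxi", seed = 1)`
(sparse-reward Taxi, 500 states), `"voronoi"` / `"voronoi_two_goal"`
(announced targets in a procedurally generated world), `"maggot"` (the
four-protocol conditioning experiment), and `"qlearn_taxi"` /
`"qlearn_voronoi"` for the baseline. A thin CLI wrapper lives at
`inst/cli/dynroute`.

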