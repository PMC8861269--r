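# activeforage

Discrete-state **active inference** agents for spatial foraging, with
simulated neurophysiology. The package is for computational neuroscientists
and behavioral modellers who want a self-contained, reproducible simulator
of goal-directed navigation and epistemic (novelty-driven) exploration on a
grid world, together with the neuronal-process readouts — firing-rate
rasters, local field potentials, dopamine traces, theta-band dynamics — that
the belief-updating scheme implies.

## The model in brief

The agent entertains a POMDP generative model over a single hidden state
factor, its location on a 10×10 grid, with arrays

* `A` — likelihoods per outcome modality: *where* (location, observed
  unambiguously) and *what* (reward vs. null, generated only at one
  location), optionally parameterized by Dirichlet concentration tables `a`;
* `B` — column-stochastic transition tables for the five actions
  (up, down, left, right, stay; edges map to stay), optionally with counts `b`;
* `C` — log preferences: utilities (3, 0) over reward/null (a ~20:1
  expectation, `exp(3) ≈ 20.09`) plus a graded proximity preference;
* `D`, `E` — initial-state and policy (habit) priors.

**Perception** is gradient descent on variational free energy `F`: with
depolarizations `v` and firing rates `s = softmax(v)`,

    eps = ln(B)·s_prev + ln(Bt)·s_next + ln(A)·o − ln s
    v  ←  v + (eps − mean(eps)) / 4        (16 iterations per time step)

using digamma expectations `E[ln A_ij] = ψ(a_ij) − ψ(Σ_k a_kj)` wherever
Dirichlet counts are attached.

**Planning** scores every depth-4 policy π by expected free energy

    G(π) = risk + ambiguity − novelty

(risk: KL of predicted outcomes from preferences; ambiguity: expected
outcome entropy; novelty: Dirichlet information gain `o·W·s`,
`W = ½(1/a − 1/ā)`), forms the posterior
`Q(π) = softmax(ln E − F − γ G)` with precision `γ = 1/β` updated to the
self-consistent fixed point `β ← β₀ + (Q − Q₀)·G`, and executes the first
action of the winning posterior (receding horizon).

**Learning** accumulates counts, `a ← a + η·o⊗s`, online after every move —
visited locations lose their novelty, which is what drives systematic
exploration of a novel patch.

The planner's hot loop is compiled (RcppArmadillo) and pinned to a plain-R
reference implementation in the tests; exact brute-force enumeration on tiny
models serves as the inference oracle.

## Worked example

Navigation on a known map, entrance at the bottom-left corner (location 91),
target at Manhattan distance 8 (location 55):

```r
library(activeforage)
g <- grid_geometry(10, 10)
model <- build_geocache_model(g, target_location = 55)
world <- grid_world(g, start = 91, reward_location = 55)
nav <- run_navigation_trial(model, world, n_moves = 10)
nav
#> <sim_record> 10 moves on 10x10 grid; start 91, reward 55; first reward at step 8
nav$locations
#>  [1] 91 81 71 61 62 63 64 54 55 55 55
```

The agent takes a shortest path (first reward at step 8 = the Manhattan
distance) and spends the final two steps on the target. Its simulated
physiology:

```r
ep <- ephys_traces(nav)
ep
#> <ephys_traces> 1100 units x 160 iterations (dt = 0.01562 s)
ep$dopamine$event_iterations       # phasic bursts, only at 16-iteration block ends
#> [1]  32  80 112 144 160
ep$spectrogram$frequency[which.max(ep$spectrogram$mean_spectrum)]
#> [1] 4                            # theta peak of the averaged LFP
```

1,100 units = 100 locations × 11 represented time points; under the
250 ms/move calibration the belief-update cycle is a 4 Hz (theta) rhythm.

Epistemic foraging of a novel patch (flat 1/100 Dirichlet prior on the
what-likelihood, uncertain transitions, no proximity preference):

```r
fmodel <- build_geocache_model(g, target_location = 65,
                               dirichlet_prior_scale = 0.01,
                               transition_prior_scale = 2,
                               proximity_weight = 0)
forage <- run_foraging_trial(fmodel, grid_world(g, 55, 65, seed = 1), 30,
                             record_trace = FALSE)
forage
#> <sim_record> 30 moves on 10x10 grid; start 55, reward 65; first reward at step 3
length(forage$visited)                               # novelty-driven coverage
#> [1] 30
sum(forage$a_posterior$what - forage$a_prior$what)   # one count per move
#> [1] 30
```

`run_geocaching_session()` chains the two: navigate to a target, forage the
local patch for the hidden object that marks the next starting point, repeat.
A thin command-line wrapper lives in `inst/scripts/activeforage.R`
(`simulate`, `ephys`, `fixtures` subcommands).

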