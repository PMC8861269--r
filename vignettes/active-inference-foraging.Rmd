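---
title: "Active inference on a grid: model, planning and simulated physiology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Active inference on a grid: model, planning and simulated physiology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`activeforage` simulates discrete-state active inference agents that navigate
a grid toward preferred locations and epistemically forage novel patches,
together with the neuronal-process readouts (firing rates, local field
potentials, dopamine) implied by the belief-updating scheme. This vignette is
the package's account of the model, the numerical choices behind it, and
what the test suite does and does not establish.

## The generative model

The world is a single hidden state factor — the agent's location on an
`n_rows x n_cols` grid (10 x 10 by default, 1-based row-major indices,
"up" decreases the row). Two outcome modalities are generated from it:

* **where** — the current location, observed unambiguously (identity
  likelihood). The agent always knows where it is; what it may not know is
  what each location yields.
* **what** — "reward" or "null". The true process generates reward only at
  one location (the navigation target, or the hidden object of a foraging
  patch).

Five actions (up, down, left, right, stay) move the agent deterministically;
an action that would leave the grid maps to "stay", which keeps every
transition table column-stochastic without an absorbing boundary state.

The model is parameterized by the usual arrays: likelihoods `A` (optionally
with Dirichlet concentration tables `a`), transitions `B` (optionally `b`),
log preferences `C`, an initial-state prior `D` and a habit prior `E` over
policies (uniform by default). Preferences assign utilities 3 and 0 to the
reward and null outcomes, so the agent expects reward about
`exp(3) ~ 20` times more than null, plus a graded proximity preference
`C[where](loc) = -w * ManhattanDistance(loc, target)`. The weight
`w = 0.25` is a design choice: the proximity preference is stated
qualitatively in the task description, and a monotone-in-distance log
preference is its minimal reading; `w` is configurable, including 0. In
foraging patches the proximity preference is disabled (`w = 0`) because the
rewarding location is unknown to the agent — a proximity gradient toward it
would leak the answer into the preferences.

```{r, eval = FALSE}
library(activeforage)
g <- grid_geometry(10, 10)
model <- build_geocache_model(g, target_location = 55)
```

## Inference: gradient descent on variational free energy

Beliefs about the location at each time point, under each policy, are
updated by gradient descent on variational free energy. Writing `v` for the
unnormalized log-belief (the depolarization of the encoding population) and
`s = softmax(v)` for its firing rate, each iteration moves `v` along the
mean-centred state prediction error

```
eps = ln(B) s(prev) + ln(Bt) s(next) + ln(A) o - ln s ,
v <- v + (eps - mean(eps)) / 4 ,
```

with 16 iterations per time step. The messages are: the forward message
through the previous action's transition table (the log initial prior at the
first time point), the backward message through the transposed,
column-renormalized transition table (columns of the transpose that sum to
zero — states unreachable under the action — are replaced by uniform,
i.e. carry no information), and the log likelihood of outcomes already
observed (future time points get no likelihood message). When Dirichlet
counts are attached, all log tables are replaced by their digamma
expectations, `E[ln A_ij] = psi(a_ij) - psi(sum_k a_kj)`. Logs of
probability tables are floored at `exp(-32)` so deterministic zeros stay
finite; digamma expectations are floored at -32 on the same scale.

Two readings of the message `ln B . s` are possible: the expected log
transition `(ln B) %*% s` (a mean-field update) and the log of the predicted
distribution `log(B %*% s)`. We implement the former: on exhaustively
enumerable fixtures it respects the bound `F >= -ln(evidence)` everywhere,
whereas the latter can undershoot the bound, which would break the
free-energy accounting used in policy evaluation.

**What the oracle tests show.** For the model class this package targets —
location observed unambiguously — the mean-field fixed point reproduces
exhaustively enumerated smoothing marginals to ~1e-13 and the free energy
sits essentially on the exact negative log evidence; the test suite checks
50 random 2-3-state fixtures of this class against brute-force enumeration.
The same scheme applied to models with heavily ambiguous likelihoods is a
genuine approximation (mean-field marginals can deviate from exact smoothing
by order 0.1); nothing in this package's tests certifies that regime.

## Planning: expected free energy over enumerated policies

Policies are all `5^depth` ordered action sequences (depth 4 by default),
re-enumerated and re-scored after every executed action; only the first
action of the winning posterior is executed (a receding horizon — 10 or 30
moves exceed the 4-step plan depth). Each policy's window beliefs are run to
their fixed point and scored by

```
G = risk + ambiguity - novelty
```

summed over the window and modalities: risk is the divergence of predicted
outcomes from the (log-softmax) preferences; ambiguity is the expected
outcome entropy given states; novelty is the Dirichlet information gain
`o . W . s`, `W = (1/a - 1/colsum(a)) / 2` — the standard closed-form bound
for discrete schemes, nonnegative, strictly decreasing in every count, and
vanishing as counts saturate. Novelty is attached to the likelihood counts
only; transition uncertainty enters through the digamma-expected messages
(and `b` counts are learned), but no transition-novelty term is added to
`G`. The policy posterior is `Q = softmax(ln E - F - gamma G)`.

The planner's per-move hot loop (all 625 policy windows simultaneously)
runs in compiled code (RcppArmadillo), grouped by the action occupying each
window slot; the test suite pins the kernel to the plain-R reference
implementation to machine precision.

**Belief continuity.** A policy `(a1..a4)` evaluated after executing `u`
continues the window beliefs of its predecessor `(u, a1..a3)` from the
previous cycle, which predicted exactly the same time points from the same
past; the freshly uncovered horizon point starts at the predecessor's
one-step rollout. This warm start leaves fixed points (and hence behavior)
unchanged while making the recorded rasters reflect genuine belief
transients rather than re-initialization artefacts. Beliefs about the
observed past are policy-independent here: all candidate policies share the
executed prefix, and with location observed unambiguously the planned future
cannot retrodictively move pinned past beliefs. Time points beyond the
planning horizon hold the window-end prediction.

## Precision and the dopamine readout

Confidence in beliefs about policies is the precision `gamma = 1/beta` of
the policy softmax. At each step boundary, when a new outcome arrives, the
*previous* cycle's policy set is re-scored against it: the one-step
postdictive free energy of a policy whose first action cannot explain the
newly observed location is large (~32 nats after the log floor), so the
posterior concentrates on observation-consistent policies. The precision
equations are then iterated to their fixed point,

```
Q  = softmax(ln E - F - gamma G)
Q0 = softmax(ln E - gamma G)
beta <- beta_prior + (Q - Q0) . G ,   gamma = 1 / beta  (beta >= 1e-6),
```

so that when observations concentrate `Q` on low-`G` policies, `beta` falls
below its prior and `gamma` rises. The update lands on the last iteration of
each 16-iteration block (step `k` at global iteration `16 k`), so phasic
dopamine — the positive rate of change of `gamma` — occurs only at block
boundaries. This fixed-point form is a design choice: the precision dynamics
are specified here operationally (by the behavior they must produce —
confidence rising as alternatives are eliminated), and under a receding
horizon the re-scoring of the previous policy set against the new outcome is
what carries the evidence, because all *current* candidate policies explain
the shared past equally well.

## Learning

Dirichlet counts accumulate as outcome-state outer products,
`a <- a + eta * o (x) s`, and per executed action
`b[u] <- b[u] + eta * s' (x) s`, with `eta = 1`: each observed move adds
exactly one count of mass per modality (30 counts over a 30-move trial).
Foraging trials update online, after every move — this is what makes visited
locations lose their novelty *within* a trial, the engine of systematic
exploration; a batch mode (one accumulation at trial end over the
model-average beliefs) is available via `learning_config(online = FALSE)`.
There is no forgetting: counts never decay. Learned counts reset for each
new foraging patch (novelty must recur in every new local area); within a
patch they carry forward.

Foraging priors follow the study conditions: `a[what]` uniform at 1/100
(so expected outcomes are 50/50 everywhere and the novelty term is initially
equal across locations) and `b[u] = 2 * B_true[u] + 1e-4` — a mildly
confident transition prior (the scale is not stated in the task description;
2 makes transitions learnable without paralyzing early planning, and the
1e-4 jitter keeps digamma expectations defined on zero cells).

## Simulated electrophysiology

One movement is calibrated to 250 ms, so 16 iterations give a sample every
15.625 ms (64 Hz); one belief-update cycle per move is then a 4 Hz rhythm.
The readouts:

* **Firing-rate raster** — one unit per (location, represented time point),
  holding the policy-averaged state expectation at every iteration; the
  10 x 10 navigation scenario with 10 moves yields 1,100 units over 160
  iterations.
* **LFPs** — per unit, the rate of change of its firing rate. Because the
  model-average rates are normalized within each represented time point,
  the plain mean of these traces cancels by construction; the broadband
  signal used for spectra is therefore the mean rate of change of the
  *depolarizations* (log rates), which is not normalization-constrained.
* **Dopamine** — tonic `gamma` and its positive rate of change (phasic).
* **Theta filtering** — a second-order Butterworth band-pass (2-6 Hz)
  applied forward-backward (zero-phase).
* **Time-frequency maps** — short-time Fourier power, 1 s Hanning windows
  with 75% overlap. Frequencies completing fewer than 2 cycles per window
  are excluded: at this resolution they cannot be distinguished from
  within-window trend, and the slow drift injected by the log floor would
  otherwise masquerade as power near DC.

Under the default calibration the navigation run's averaged LFP spectrum
peaks at 4 Hz, phasic dopamine events sit exactly on block boundaries and
coincide with drops in policy-posterior entropy, and the theta-filtered
trace's trough spacing matches the 16-iteration blocks.

## Numerical and design choices, collected

* Gradient step 1/4, 16 iterations per time step, mean-centred errors
  (softmax gauge freedom).
* Log floor `exp(-32)` for all probability-table logs and digamma
  expectations.
* Backward messages through the transposed, column-renormalized transition
  table; zero columns (unreachable states) become uniform.
* Ties in action selection break by the documented action order
  (up < down < left < right < stay); a seeded sampling mode is available.
* The optional Occam window (`occam_window`) zeroes policies whose log
  posterior trails the maximum by more than the window before averaging and
  selection; it is off by default and defaults are never affected by it.
* The default entrance is the bottom-left corner and the default target sits
  at Manhattan distance 8 — reachable in 8 of 10 moves, leaving two steps at
  the target. Exemplar coordinates are configuration, not constants.

## Problem sizes used by the tests

The property suites run the full 10 x 10 scenarios: 20 seeded start/target
pairs for the shortest-path property, 50 seeded 30-move foraging trials for
discovery (20 of them paired with novelty-ablated runs and reused for the
learning properties), 50 uniform random walks as the chance baseline, and 50
exhaustively enumerated 2-3-state fixtures for the inference oracle. These
sizes give stable means for the stochastic comparisons while keeping a full
suite run in minutes.

## Limitations

* The synthetic environment is deterministic, obstacle-free and
  single-reward; the generative process never consults the agent's beliefs.
  Passing tests say nothing about ambiguous-location regimes, continuous
  space, or volatile (changing) contingencies.
* Policies are enumerated exhaustively (`5^4` by default); deeper horizons
  need pruning or tree search, which this package does not implement.
* Habits (`E`), preferences (`C`) and initial priors (`D`) are not learned.
* The navigation/foraging alternation is orchestrated at the session level;
  there is no explicit hierarchical (two-level) temporal model.
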