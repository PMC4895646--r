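---
title: "A generalized logical model for signaling dynamics: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A generalized logical model for signaling dynamics: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glogsim)
```

## The model and its assumptions

`glogsim` occupies the middle ground between Boolean networks and kinetic
ODE models. Boolean models need no parameters but can only say on/off;
ODE models produce graded dynamics but demand rate constants that are rarely
known for whole pathways. Here each molecular species carries a continuous
activity $X \in [0,1]$ and evolves in discrete, synchronous time:

$$
X_t = (1-d)\,X_{t-1}
 + \Big[1-\prod_i(1-A_i)\Big]\prod_j(1-B_j)\,(1-X_{t-1})
 - \prod_i(1-A_i)\Big[1-\prod_j(1-B_j)\Big]\,X_{t-1}
$$

with $A_i$ ($B_j$) the activating (inhibiting) signals from parent nodes,
each equal to parent activity times edge weight. The three terms are read as
probabilities of independent events: the non-degraded fraction of the active
form; the inactive fraction $(1-X_{t-1})$ recruited because at least one
activating signal fires and no inhibiting signal blocks it; and the active
fraction lost because some inhibiting signal fires unopposed. The
independence reading is why products, not sums, combine parallel inputs —
it also produces the saturating, sigmoid-shaped responses observed for
signaling molecules without any Hill exponents.

Assumptions worth keeping in mind:

* **Synchronous updates.** Every node reads the complete state of the
  previous iteration. An asynchronous mode (update one random node at a
  time) is a known extension but is out of scope here.
* **A single global degradation rate** `d` applies to all nodes. The
  per-iteration loss of active form is the only "clock" in the model;
  iterations are not calibrated to wall-clock minutes.
* **One edge per ordered pair, no self-loops.** Self-dependence is already
  encoded by the $(1-d)X_{t-1}$ term; a self-edge would double-count it.
* **Boolean limit.** With $d = 0$, unit weights and binary states the rule
  is exactly the synchronous Boolean rule "any active activator and no
  active inhibitor switches on; any active inhibitor and no active activator
  switches off; otherwise hold". The test suite verifies this by exhaustive
  enumeration of all $2^n$ states on small random topologies.

## Perturbations through the virtual node

Extracellular perturbations (drugs, ligands, damage stimuli) act through a
virtual node whose activity is pinned at 1, sitting upstream of the
user-designated input nodes. A scheduled event (target, level
$\ell \in [-1,1]$, start/end iteration) materializes as a virtual edge:
$\ell > 0$ an activating edge of weight $\ell$, $\ell < 0$ an inhibiting
edge of weight $|\ell|$ (so $-1$ is full inhibition). Because the virtual
node's activity is 1, the transmitted signal equals $|\ell|$. We take the
inhibiting weight to scale linearly with $|\ell|$; the model family does not
pin this down and linearity is the simplest choice consistent with the
activating side.

Iterations are 1-based: an event with `start = 10` first affects the 10th
update. Events persist indefinitely by default — drug additions are not
withdrawn — but a finite `end` is supported, and at most one event may be
active per (target, iteration). Before an event starts, its target evolves
freely; a receptor therefore decays from its random initial value at rate
`d` until its stimulus arrives, then jumps towards the driven fixed point.

Two closed forms anchor the dynamics and the tests. A node receiving a
constant activating signal $A$ converges to $A/(A+d)$; with $A = 0.8$ and
$d = 0.2$ the plateau is exactly the input level 0.8, and convergence is
immediate because the update becomes $x' = 0.8x + 0.8(1-x)$. A parentless
node follows $X_t = (1-d)^t X_0$ to machine precision.

## Tunable parameters

| Parameter | Units / range | Default | Why |
|---|---|---|---|
| `iterations` | updates, >= 1 | per call (100 for open-ended runs, 32 when aligning to 8 time points) | 32 is used for fitting because most nodes stabilize within ~30 steps and 32 is divisible by 8 |
| `degradation` | fraction/iteration, [0,1] | 0.2 | moderate decay: pre-stimulus receptors visibly relax without freezing the dynamics |
| `clamp` | logical | `TRUE` | the raw rule can exit $[0,1]$ (e.g. $d = 1$ with active inhibition); activities are defined on $[0,1]$, so out-of-range mass is truncated; `FALSE` exposes the raw rule for diagnostics |
| `initial` | `"random"` or vector in $[0,1]^n$ | `"random"` | activities at time 0 are unknown; i.i.d. uniform draws from a seeded generator; fixed vectors support sensitivity studies |
| edge `weight` | [0,1] | user/topology | interaction strength; 0.7–0.8 are typical working values when nothing is known |

## Analysis procedures

**Stable states.** A trajectory is declared stable when the largest
per-node change over the last `window` transitions (default 10) is below
`tol` (default $10^{-4}$). Oscillating attractors — possible in the Boolean
limit — correctly return "not stable".

**Downsampling and goodness of fit.** To compare an $N$-iteration
simulation with $T$ measured time points, the columns at iterations
$N/T, 2N/T, \ldots, N$ are extracted ($N$ must be divisible by $T$; there
is deliberately no interpolation, because mapping simulation steps to real
time is an open problem for this model class and silent warping would hide
it). Fit is Spearman rank correlation with average ranks for ties — the
model predicts trends, not calibrated magnitudes, so only monotone
agreement is meaningful. A constant vector has no rank ordering; the fit is
then reported as `NA`, never coerced to 0.

**Condition fit reports.** A drug-treatment design maps each input node to
a level (applied from iteration 1) or to `"random"`, which means no
extracellular signal at all: the node starts at a seeded random activity
and relaxes under degradation. Each condition is simulated with the same
seed, downsampled, and correlated per protein with the measurements;
measured proteins absent from the network are listed as skipped rather than
failing the run.

**Initial-value sweeps.** The chosen node's start value is varied while all
other nodes keep identical seeded initials. The expected behavior — and
what the acceptance checks assert — is that initial values change the time
to stability but not the stable level, since the driven fixed points do not
depend on the starting state.

**Edge-weight robustness.** Edge weights are usually the least trusted part
of a curated network, so the analysis asks whether trends survive weight
randomization. A background of `n_background` simulations with freshly
sampled weights (default i.i.d. uniform on $[0,1]$; signs and topology
fixed) yields a per-node mean-activity trend; `n_groups` groups of
`group_size` such simulations each yield group trends, and the per-node
Spearman correlations of group trend vs background trend (over all
post-initial iterations) form the reported distribution, ranked by median.
Nodes without incoming edges are excluded — their dynamics cannot depend on
weights. Defaults are 100 background runs and 50 groups of 100.

One design choice was genuinely open: whether group runs should re-draw
initial states independently of the background. We *pair* them instead —
run $j$ of every group and of the background shares a sub-seeded initial
state — so that weight variation is the only systematic difference between
groups (a blocking design). Pairing removes initial-state noise from the
comparison and gives the degenerate sanity case a sharp value: with a
point-mass weight sampler and `group_size == n_background`, every group
trend equals the background trend exactly and all defined correlations are
exactly 1.

## The synthetic-data generators

`generate_network()` samples exactly `n_edges` distinct ordered pairs
uniformly without replacement (no self-loops), assigns signs
Bernoulli(`activating_fraction`) and weights from the sampler, and prefers
in-degree-0 nodes when designating inputs. The default activating fraction
is 0.75: curated signaling maps are predominantly activating. Uniform pair
sampling means in/out-degrees are near-binomial — real pathways are closer to
scale-free with hub kinases — so generated networks exercise the machinery,
not the biology.

`generate_pseudo_measurements()` simulates, downsamples to $T$ points and
adds i.i.d. Gaussian noise truncated at zero, emulating the shape of an
8-time-point phosphoproteomics table already on the simulation's scale.
What it does *not* emulate: measurement-batch structure, missing values,
biological replicate correlation, or any dynamics the simulator itself
cannot produce. Passing the end-to-end recovery tests therefore shows the
pipeline is self-consistent (noiseless data are recovered with correlation
1, and fits degrade monotonically as noise grows through sd 0, 0.05, 0.5),
not that the model fits any particular real dataset.

## Numerical choices and degenerate inputs

* Empty products are 1: no activators means zero activation gain, no
  inhibitors means zero blocking loss, and a parentless node reduces to pure
  degradation. This is the standard convention and matches the observed
  pre-stimulus receptor decay.
* Clamping is applied after each update, per node. In the parameter regimes
  used throughout (moderate `d`, weights below 1) the raw rule stays inside
  $[0,1]$ and clamping is a no-op; it matters only at extremes.
* Weights survive write/read round-trips exactly: the edge-list writer emits
  17 significant digits and the JSON writer is configured likewise.
* Determinism: every stochastic step (initial states, generated networks,
  weight samplers, noise) flows from explicit seeds; a master seed fans out
  into sub-seeds (documented in the code) so sub-analyses can be reproduced
  independently. Identical inputs and seeds give bit-identical trajectories
  and CSVs.
* Zero-length or infeasible requests error early and loudly: 0 iterations,
  `n_edges` above $n(n-1)$, schedules targeting non-input nodes, $N$ not
  divisible by $T$, initial values outside $[0,1]$.

## Problem sizes

The shipped tests run the full robustness design (100 background runs plus
50 groups × 100 runs) on a generated 5-node/13-edge network over 32
iterations, the end-to-end noise study with 20 seeds per noise level on the
bundled 13-node pathway, and a scale check on a generated 500-node /
6124-edge network for 100 iterations — sizes chosen to match the regimes
the model is meant for, from toy pathways to database-scale maps.

## Known limitations

* No mapping from iterations to physical time; aligning simulated steps
  with measured time points uses equal-interval downsampling only.
* Synchronous updating can create artificial oscillations that an
  asynchronous scheme would break.
* Edge weights are inputs, not fitted quantities; learning them from data
  is future work.
* A single global `d` cannot express node-specific turnover rates.
* No SBML/SBML-qual/GINML import; the edge-list and JSON formats are the
  only interfaces.
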