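---
title: "Modelling TLR4-driven early sepsis as a stochastic Boolean network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling TLR4-driven early sepsis as a stochastic Boolean network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

Early Gram-negative sepsis begins with Toll-like receptor 4 (TLR4)
recognising bacterial lipopolysaccharide (LPS). The downstream host response
— monocyte, macrophage, neutrophil, NK, dendritic, endothelial, platelet,
T- and B-cell activation, the pro- and anti-inflammatory cytokine
repertoire, complement, and the coagulation cascade — is rich in qualitative
interaction knowledge but poor in kinetic parameters, which makes a logical
(Boolean) model the natural formalism. `sepsisBN` ships a 42-node Boolean
network of this response. Each node holds a binary state; an update rule
combines the states of its regulators with AND (`&`), OR (`|`) and NOT
(`!`). Four nodes serve as clinical surrogate endpoints: *Phagocytosis* and
the membrane attack complex (*MAC*) for the ability to clear bacteria, and
*Thrombosis* and angiopoietin-2 (*Ang2*) for coagulopathy and vascular
leakage, the organ-damage side of sepsis.

Biological events differ in latency, so the rule language supports
*threshold* (delay) terms: `THR_X[tag]` is true only when `X` has been
active at every one of the previous `d` committed time steps, where `d` is
the delay attached to `tag`. The shipped delays are 2 steps for bacterial
clearance, late phagocytosis, apoptosis, tissue-factor production and MAC
assembly, 1 step for early (neutrophil) phagocytosis, and 3 steps for
anti-inflammatory mediator release (IL-10, sTNF-R, IL-1Ra), whose synthesis
needs an extra signal-transduction stage. For steps before the start of the
simulation the initial state is read in place of history; simulations start
at the onset of infection (`Infection = 1`, everything else 0), so the
pre-history is simply "no response yet".

## Stochastic asynchronous updating

Biological timing is noisy, and deterministic synchronous updating creates
artefactual rigid oscillations. The engine therefore updates
asynchronously, in one of two schemes:

* `random_order` (default): every node is updated once per time step, in a
  fresh uniform random permutation, each update seeing the freshest
  within-step values of its regulators;
* `single_node`: one uniformly chosen node is updated per step, all others
  carry over.

The default was chosen because it makes a "time step" a full network sweep,
which is the scale on which the shipped delay values (1-3 steps) are
meaningful; under `single_node` a delay of 2 steps would compare a node
against an almost frozen network. Both schemes are first-class and the
exact oracle (below) solves both, so their differences are measurable
rather than anecdotal. Threshold terms always read *committed* whole-step
rows, never partial within-step values, so delay semantics do not depend on
the scheme or on a node's position in the permutation.

Interventions are modelled as clamps: a knock-out (KO) holds a node at 0, an
over-expression (OE) at 1, over an arbitrary step range; a clamp starting at
step 0 also overrides the initial state, and clamps dominate both rule
evaluation and polymorphisms. Genetic or functional variability is modelled
as a *polymorphism*: a node with activity $p$ turns on, when its rule is
satisfied, only with probability $p$. Activity 1 bypasses the random number
generator entirely, which gives the useful identity that a 100%-activity
condition is bit-identical to the unaltered model under the same seed.

Every repetition `r` draws from its own generator seeded `seed + r`
(a SplitMix64 stream inside the compiled engine), so runs are reproducible
bit for bit, repetitions are independent, and results never depend on R's
global RNG state. Screens additionally derive one seed per condition from
the master seed plus a stable hash of the condition descriptor, so adding
or reordering conditions never changes existing results. The sensitivity
and timing sweeps instead share one seed across their conditions (common
random numbers): paired comparisons against the baseline then cancel most
Monte-Carlo noise, and a no-op condition (activity 100%, or a clamp
starting beyond the horizon) reproduces the baseline exactly.

## Attractor readout

The readout for every scenario is the per-node percentage of time active
("% activation") over a late window, averaged across repetitions — the
stochastic analogue of reading state sets of attractors. Explicit cycle
detection is deliberately not used: under stochastic updating a trajectory
does not settle into a fixed cycle, and the window time-average converges
to the same Cesàro limit that cycle averaging would produce. Defaults:
burn-in 30 steps, horizon 60 steps, 100 repetitions. Stationarity is
verified by splitting the window in halves and requiring every node's mean
activation to agree between halves within 2 percentage points; failing
that, the horizon doubles (up to 480 steps, enough for the slowest shipped
delay loops while keeping the full screens in the minutes range) and the
profile is re-estimated. A profile still unstable at the cap is returned
flagged, with a warning, rather than silently accepted — a handful of
strongly perturbed conditions (e.g. some IL-10 clamps) oscillate slowly
and legitimately carry the flag.

## Validation against an exact oracle

The package generates small delay-free toy networks (`make_toy_network()`)
whose long-run behaviour is computed exactly by `exact_stationary()`: the
full $2^n$-state transition matrix of the chosen update scheme is built
(averaging over all $n!$ permutations for `random_order`), and the lazy
chain $(I + P)/2$ is power-iterated to $10^{-10}$. The lazy chain shares
the original chain's recurrent classes, their stationary distributions and
the absorption probabilities, but is aperiodic, so its limit equals the
time-average limit the engine estimates — including for periodic motifs
such as the single-node oscillator `A = !A`. The test suite holds the
engine to an $L_\infty$ error below 0.03 at 10,000 repetitions on every
motif under both schemes, and keeps one frozen four-node fixture on which
the two schemes provably differ by more than 0.05, so a scheme-handling
regression cannot pass silently.

The compiled scheduler itself is cross-checked against an independent
pure-R evaluator: trajectories are recorded together with their update
orders and replayed step by step with `eval_expr()`, and must match bit for
bit under both schemes, including mid-simulation clamps.

## The three analyses

*Sensitivity.* `polymorphism_sweep()` scans each of the 13 immune-cell
nodes over activities 0-100% in 10% steps and scores the four endpoints by
relative change, $(\text{perturbed} - \text{baseline})/\text{baseline}$,
against the unaltered profile. `identify_cell_effects()` reads the
full-deactivation end of the sweep with an inclusive 20% cut-off — the same
efficacy threshold the perturbation screens use, so "considerable effect"
means one thing package-wide. One effect sits essentially on that
threshold: fully deactivating monocytes changes Ang2 by about −0.21, so the
monocyte node is reported for both thrombosis (strongly) and Ang2
(marginally), while the distinct influential cells remain the endothelial,
monocyte and platelet nodes.

*Perturbation screens.* `mono_screen()` clamps each screen-set node to 0 or
1; `pair_screen()` evaluates all unordered pairs under every KO/OE
assignment and flags *novel* combination strategies, i.e. pair hits on an
endpoint for which neither constituent mono clamp is a hit;
`antibiotic_screen()` adds a KO clamp on the bacterial node (the antibiotic
surrogate) alone and combined with each screen-set clamp, reporting benefit
both against the untreated baseline and against antibiotics alone. Hits
require at least a 20% relative change in the endpoint's beneficial
direction — a decrease for Thrombosis and Ang2, an increase for MAC and
Phagocytosis — encoded as model metadata, not code. The Perturbation Index
(PI), the perturbed/baseline ratio, is reported alongside with categories
negative (< 0.8), neutral (0.8-1.25) and positive (> 1.25); wherever the
baseline is positive, PI = 1 + relative change. A zero baseline with a
positive perturbed activation has no defined ratio; such rows carry an
`undefined_increase` flag and are excluded from ratio-based hit calling
rather than forced into a number.

The shipped screen set contains the 18 mediator molecules plus the TLR4
receptor. TLR4, though a receptor rather than a secreted mediator, is a
druggable upstream node and a recurring combination-therapy constituent, so
excluding it would hide a clinically interesting class of strategies. NETs
is excluded: neutrophil extracellular traps are an extracellular chromatin
structure rather than a targetable molecule, and the node is a direct
AND-input of the Thrombosis rule, so clamping it is equivalent to clamping
the endpoint itself and would swamp the screen with a trivial "hit". Both
choices live in the metadata sidecar and are one-line edits.

*Timing.* `timing_sweep()` re-runs any condition with its clamps started at
each step of a grid (default 0, 4, 8, 12, 20). Two behaviours emerge from
the model. Mediator-directed perturbations score almost identically whether
started at onset or late, because the attractor window lies beyond the
transient either way. Bacterial clearance is different: removing bacteria
at step 0 leaves the entire network silent, while removal after the
cascade has ignited (roughly step 4 onwards) always relaxes to one and the
same treated attractor regardless of the removal time — early antibiotics
prevent the response, late antibiotics merely truncate the
bacteria-dependent arm (complement, TLR4-driven monocyte activation,
tissue factor), and being later still changes nothing further.

## Problem sizes and limitations

The default analysis scale — 100 repetitions, 60-step horizon with
adaptive doubling, 19 screened nodes, 171 node pairs with four mode
assignments each — keeps the mono screen in seconds and the full pair
screen in a few minutes on one core; the engine evaluates compiled rule
bytecode in C++, so these sizes are comfortable and larger ones scale
linearly.

The toy generator emulates structural motifs (feed-forward chains,
redundant OR-gates, negation loops, delayed links), not sepsis biology: it
validates update semantics, delay handling, clamps and estimator
convergence, so passing its tests certifies the machinery, not the
clinical fidelity of the 42-node model. The model itself inherits the
usual limits of logical modelling: time steps are not calendar time,
binary states cannot express graded cytokine levels, and endpoint nodes
are surrogates, not patient outcomes. Mediator interventions are pure
clamps — dose-response inhibition is out of scope. Where the screens
report borderline values (effects within a few points of the 20%
cut-off), the hit/no-hit call is sensitive to scheme details and should be
read as "near threshold" rather than as a sharp biological distinction.
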