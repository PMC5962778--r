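---
title: "A closed-loop model of infant hand regard: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A closed-loop model of infant hand regard: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The behaviour being modelled

Hand regard — an infant's sustained looking at its own hand, emerging at
about two months — is thought to be the route by which infants come to
recognise their hands and distinguish them from other objects. `handregard`
simulates this developmental process as a closed sensorimotor loop: a small
recurrent network moves two simulated "hands" on a discrete 2-D grid, senses
the consequences, and learns online to bring the hands into the centre of
its visual field. Once trained, the frozen network is probed with altered
visual input to ask whether it treats its hands differently from
distractor objects.

## The world

The movable area is a square grid (default 15 × 15 squares of 4 cm — 60 cm,
the span of outstretched infant arms) that partitions into 3 × 3
proprioceptive blocks of 20 × 20 cm. The field of view is the top 14 rows
(210 squares); its centre is the central 5 × 5-square block. Three kinds of
entity occupy squares: the left hand, the right hand, and one or more
distractor objects ("others"). Every 1000 steps all entities are re-placed
uniformly at random; every 50 steps each distractor takes one uniformly
random 4-neighbourhood step (rejected at its region boundary, so it stays
put there). In the training phase distractors roam the whole area — they
rarely enter the field of view, emulating rearing conditions in which the
infant sees virtually nothing but its own hands; in the test phase they are
placed and kept inside the field of view, which is what makes hand/object
discrimination hard.

Conventions the package fixes where the underlying description is silent:
coordinates are 0-based square indices with origin top-left; the cm frame of
the learning equations has y pointing up, so "upward" decreases the row
index. Hands clamp at the area boundary (they are servo-controlled);
distractor proposals that leave the allowed region are rejected. Hands may
overlap each other or a distractor (no collision rule); a visible hand takes
precedence on a shared square's visual unit. Diagonal hand moves occur when
both axis rules fire, since the axis rules are independent.

## Inputs, network, output

Each step the network receives a 238-unit input vector:

* **Visual** (210 units, one per field-of-view square): value 0.5 on a
  square holding a hand, 0.2 on a square holding a distractor (training
  coding), 0 elsewhere.
* **Proprioceptive** (18 units): the hand's position is sensed only to
  block resolution (±10 cm), as one-hot codes over the nine block centres,
  9 units per hand. Proprioception is always available — hand regard is
  observed in blind infants.
* **Corollary discharge** (10 units): a simplified forward model reports
  only the *direction* of each hand's most recent movement command (four
  direction units plus a no-move unit per hand); distances are always one
  square and are ignored.

The total of 238 is a printed constraint; its decomposition into
210 + 18 + 10 is this package's reconstruction (the source gives only the
total), chosen so the stated signal content reproduces the total exactly.
The active-unit magnitude for proprioceptive and corollary-discharge units
is 1.0 (only visual magnitudes are specified upstream); both are
configurable.

The network is three-layer: 238 inputs → 48 logistic hidden units (fully
recurrent, one step of history) → 8 logistic output units. The hidden layer
is split into two halves. The "agency" half receives every input; the
"ownership" half receives visual and proprioceptive input but **no**
corollary discharge, enforced by a binary mask re-applied after every
update. Whether the two halves are recurrently interconnected is not
specified upstream; the package defaults to full 48 × 48 recurrence
(self-connections included) as the least-committal choice, and the mask
machinery makes alternatives configurable. Output units are pure readouts;
the functional feedback path runs through the environment and the corollary
discharge.

Movement is decoded by a simplified population-vector rule: per hand, four
output units prefer right/up/left/down; per axis, if the opposing units'
activation difference reaches 0.8 the hand moves one square that way,
otherwise it does not move on that axis.

## Learning

Training is feedback-error learning combined with real-time recurrent
learning (RTRL). The displacement of each hand's *perceived* (block-centre)
position from the field-of-view centre is converted into ternary
motor-command errors on the eight output units, e.g. for the left hand

$$e_0 = \frac{(x_0 + d) - x_L}{d}, \qquad e_1 = \frac{(y_0 + d) - y_L}{d},
\qquad e_2 = -e_0, \qquad e_3 = -e_1,$$

with $d$ the 20 cm block pitch and $(x_0 + d, y_0 + d)$ the central block
centre; all errors are −1, 0 or +1 and vanish exactly at the central block.
The overall error is $J = \tfrac12\sum_k e_k^2$. The errors are *injected*
output errors in the Kawato sense: the gradient does not flow through the
environment into the $e_k$ (they are piecewise constant in hand position,
hence non-differentiable). Each step contributes
$\sum_k e_k \, \partial y_k / \partial w$, computed exactly through the
recurrent dynamics by carrying RTRL sensitivities
$\partial h_j(t) / \partial w$ forward in time; contributions are summed
over a 10-step window and applied as $\Delta w = \eta \, g$ every 10 steps.

Choices made where the upstream description is open:

* **Window handling** — the 10-step gradient is *summed* (all error
  information used) rather than subsampled at the 10th step.
* **Learning rate** — unspecified upstream; default $\eta = 0.1$,
  calibrated only by the servo-convergence smoke test (a frozen world with
  no distractor must reach $J = 0$ with both hands in the central block
  well within $10^5$ steps), which it passes with a wide margin.
* **Continuity** — sensitivities and the recurrent state are carried across
  repositioning events; the simulation is one continuous run. The initial
  recurrent state is 0.5 (the logistic of zero net input).
* **Stale sensitivities** — as is standard for online RTRL, sensitivities
  are not recomputed after an update; they continue from the pre-update
  values.

## Success rate and the two phases

Success on a step means at least one hand is inside the centre block
(post-move). During training, success is observed over a $10^4$-step window
at the start of every $5\times10^5$ steps — the 3 h-per-week observation
ratio (3/168) of the infant study the schedule mirrors — and each point is
plotted at the interval midpoint. (Each window's score equals the mean of
its two half-window ratios, the literal "average of two ratios during
$10^4$ successive time steps".) Weight checkpoints are saved every $10^6$
steps. In the test phase, learning is frozen and each saved checkpoint is
probed for $10^5$ steps (100 placements) under seven input codings: cases
1–6 cross the distractor's visual value (0.2 or 0.5) with its count (1, 5
or 20); case 7 equals case 1 but with invisible hands and corollary
discharge silenced, i.e. proprioception-only guidance. Test-phase world
randomness uses its own seed stream, so all cases see the identical
placement sequence at a given seed — a paired design that sharpens the
case-1-vs-7 contrast.

An untrained network cannot reach the 0.8 decoder threshold (outputs stay
near 0.5 under ±0.1 init weights), so the hands never move and the success
rate is the analytic baseline
$1 - (1 - 25/225)^2 \approx 0.210$.

## Post-hoc analyses

* **Cell assemblies** — Hebbian assemblies are detected in the recurrent
  weight matrix as maximal cliques of *reciprocal* positive coupling
  (edge iff $W_{ij} > \theta$ and $W_{ji} > \theta$; default $\theta = 0$).
  This weight-based formalisation stands in for the upstream study's visual
  inspection of activity panels; the relation between activity-based and
  weight-based definitions is left open, which is why $\theta$ is exposed.
  Assembly turnover between checkpoints is one minus the mean best-match
  Jaccard similarity.
* **U-shaped episodes** — after light smoothing (3-point moving average), a
  U-shape is a local-max → local-min → local-max triple whose drop reaches
  `min_depth` (default 0.05); both parameters are sweepable because "wide"
  versus "small-scale" U-shapes are distinguished only verbally upstream.
* **Trajectory metrics** — over a 100-step window: mean turning angle,
  180° reversal count, and net-to-gross displacement ratio, descriptive
  statistics of the circular/zig-zag, general-movement-like excursions; no
  clinical classification is claimed. A per-unit fluctuation index (mean
  absolute step-to-step activation change) flags the strongly fluctuating
  hidden units seen while assemblies reorganise.

## Problem sizes, presets and what the tests show

RTRL costs $O(n_{hid}^2 \cdot n_{weights})$ per step; the full study-scale
run ($5.5\times10^7$ steps × 10 seeds, 48 hidden units) is a cluster-scale
computation. The package therefore ships two presets. `"paper"` carries the
full-scale conditions and is the default reference for constants. The test
suite and the acceptance script run `"scaled"`: a 9 × 9 area with 3 × 3
square blocks (same 3 × 3 block structure, 100 inputs), 16 hidden units,
$10^6$ training steps, windows scaled to the same 0.02 observation ratio.
The closed-loop runner is compiled (RcppArmadillo); a pure-R reference
implementation of every step operation is kept and verified to agree with
the compiled path draw-for-draw, which is the package's main guard against
transcription errors in the learning rule.

What the scaled runs do and do not show: the scaled servo task is easy for
its network — training success rises from the 0.21 baseline to near ceiling
within the first few checkpoints, so the acceptance checks exercise
learning, scheduling, discrimination probing and all printed constants, but
ceiling performance compresses the case-1-vs-7 discrimination gap toward
zero (the ordering is still required, up to Monte-Carlo error) and the
slow, repeated U-shaped dynamics of the full-scale run are not expected to
appear at this scale. The U-shape and assembly detectors are therefore
validated on constructed fixtures and brute-force oracles rather than on
scaled-run output.

The world generator emulates: uniform repositioning, a nearly immobile
distractor, block-quantised proprioception and the restricted visible
environment of the modelled rearing condition. It does not emulate: arm
kinematics or joint-space transforms, neck/eye movement, tactile input,
depth cues, or continuous space — all deliberately outside scope. Passing
tests therefore speak to the closed-loop learning mechanism, not to
kinematic realism.

## Known limitations

* The 238-unit decomposition and the field-of-view shape are inferences
  constrained by the printed total; both are configurable.
* The learning rate, gradient-window handling and hidden-part
  interconnection pattern are package choices (documented above), since
  they are unspecified upstream.
* Checkpoints are JSON: portable and exactly round-tripping, but bulky for
  full-scale 48-unit runs; a binary container would be the natural swap-in
  for cluster use.
* The discrimination result at full scale (a persistent case-1-over-7 gap
  emerging late in training) is only qualitatively probed at desk scale,
  for the reasons above.
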