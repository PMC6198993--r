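---
title: "Priority-rule traffic on leaf-cutting ant trails: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Priority-rule traffic on leaf-cutting ant trails: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The system and the question

Leaf-cutting ants (*Atta*) run bidirectional traffic between their nest and a
leaf source: outbound workers (O) walk towards the source, and inbound
workers return either unladen (U) or carrying a leaf fragment (laden, L).
On a trail narrow enough for a single moving ant, observers see
*de-synchronization*: the stream at any point of the trail alternates
between clusters of inbound and outbound ants, with inbound clusters often
headed by a slow laden ant. On a 5 cm wide trail they instead see a degree
of *lane segregation*: laden ants travel mostly in the central strip while
unladen inbound ants are pushed towards the margins.

`anttraffic` implements a self-propelled particle model asking whether a
small set of pairwise **priority rules**, measured at the level of
individual encounters, suffices to generate both patterns. Ants are reduced
to points with constant type-dependent speed; the only stochastic
ingredients are the Poisson departure times from the two endpoints, the
laden/unladen identity of source departures, and (wide trail) the lateral
entry position.

## The priority rules

An encounter is an interaction between a particle and the nearest particle
ahead of it (in its travel direction) within the interaction radius
$r = 1 + 2\,\Delta t\, s_{OU}$ cm — one body length plus the distance two
unladen ants close in one time step (1.46 cm at the defaults). One matrix
decides who gives way, in priority order $L > O > U$:

| actor \\ encountered | O | U | L |
|---|---|---|---|
| **O** | give way | walk | give way |
| **U** | give way | give way | give way |
| **L** | walk | walk | give way |

`priority_action()` exposes this table. *Giving way* is geometry-specific:
stopping on the narrow trail, turning on the wide trail.

### Narrow trail (1-D)

Position updates follow $x(t+\Delta t) = x(t) + \delta(t)\, s\, h\,
\Delta t$ with heading $h = +1$ (outbound) or $-1$ (inbound), speed
$s_{OU} = 2.3$ cm/s for O and U, $s_L = 1.9$ cm/s for L, and $\delta = 1$
unless the particle gives way this step. Two refinements sit on top of the
base matrix:

* **The cooperative rule.** When an outbound particle first gives way to an
  oncoming laden one it steps aside for $\tau = 0.8 n$ seconds, where $n
  \in \{0,\dots,15\}$ is drawn from the cooperative-passage distribution
  `coop_dist`. While it waits it is *transparent* to inbound traffic, so
  approximately $n$ unladen particles following the laden one slip past
  (an unladen particle needs about one second to pass — the staged check in
  the test suite confirms $n \pm 1$ passers for a point-mass `coop_dist`).
  When the timer expires the particle regains priority over unladen
  particles; the same laden particle cannot retrigger a fresh yield.
* **Rule-1 following.** An unladen particle never attempts to pass a laden
  (or any) particle ahead of it in its own direction; it waits until the
  gap exceeds the interaction radius.

### Wide trail (2-D)

The trail becomes a $300 \times 5$ cm strip with walls at $w = 0$ and
$w = 5$. Headings decompose as $\theta = \theta_d + \theta_I$ with
$\theta_d \in \{0, \pi\}$ the travel direction and $\theta_I \in \{-\pi/2,
0, \pi/2\}$ the interaction term; updates are $x \mathrel{+}= s \cos\theta\,
\Delta t$, $w \mathrel{+}= s \sin\theta\, \Delta t$. A particle given way
keeps $\theta_I = 0$; one that must give way turns, freezing its
longitudinal progress ($\cos(\pm\pi/2) = 0$) and moving laterally by
$s\,\Delta t$. Encounters use Euclidean distance in $(x, w)$ with the same
radius, and the cooperative rule plays no role because nobody stops.

**Turn direction.** We set $\theta_I = +\pi/2$ exactly when $w_i < w_j$
(the avoider is below the particle it yields to) and apply it through the
trigonometric update above. Because $\sin(\pi \pm \pi/2) = \mp 1$, this
single convention moves an *outbound* avoider towards the side the
encountered particle is on, and an *inbound* avoider away from it. The
convention was a genuinely open design point: the four possible sign
pairings were enumerated and simulated, and this is the only one that
produces the observed traffic organization — priority-ordered lane use
with laden ants central — rather than an inverted arrangement in which
outbound ants are ratcheted onto the walls by the central laden stream.
With any "turn away" rule for outbound ants, every laden encounter pushes
an outbound particle further out of the laden band and it ends pinned to a
wall; letting outbound avoiders sidestep towards the laden lane (and pass
on its flank) keeps them central, while inbound unladen ants — which yield
to everything — are progressively displaced outwards. Exact same-type,
same-$w$ ties break by particle id (one up, one down) so lockstep motion
cannot persist.

**Walls.** Lateral motion clamps to $[0, 5]$. A partially clamped turn
still counts as a turn (no longitudinal progress); a turn that the wall
blocks *entirely* (the particle is already at the wall and is told to turn
into it) cannot be executed, and the particle walks instead. Without the
latter rule, wall-pinned inbound particles stall indefinitely and inbound
clusters inflate.

**Control variant.** `avoidance_rule = "stop"` replaces every turn with a
narrow-trail stop (without the cooperative rule). Lane segregation
disappears under this variant, which is the causal control for the role of
turning.

## Arrivals, entries and exits

Each endpoint spawns particles by a Poisson process: every time step,
$k \sim \mathrm{Poisson}(\mu_\text{step})$ new particles appear at the
nest (all O) and at the source (L with probability 0.24, else U). The
user-facing rate `mu` is expressed in the units under which each geometry
was calibrated against observed hourly flows (5418.8 ants/h narrow, 8803
ants/h wide):

* **narrow**: `mu` is ants **per second** per endpoint
  ($\mu_\text{step} = \mu\,\Delta t$), default 1. Demand (7200
  potential entries per hour) then exceeds observed flow only moderately;
  arrivals step onto the trail immediately at their endpoint, and all flow
  limitation is congestion on the trail itself. This choice reproduces the
  three signatures of the reference narrow-trail simulations that a
  saturated, queued entry cannot: a between-replicate flow s.d. close to
  $\sqrt{\text{mean}}$ (the Poisson-count signature, ~73 at the defaults),
  alternating groups of mean size ≈ 4 with an overrepresentation of
  singletons, and maximum group sizes of order 50–100 rather than
  thousands.
* **wide**: `mu` is ants **per time step** per endpoint, default 0.8 (8
  ants/s of demand — an hourly total of 8803 crossings is arithmetically
  impossible at 0.8/s). Demand saturates, so arrivals wait in a FIFO
  queue and the front enters only when no *same-direction* particle it
  would give way to lies within the interaction radius of its entry point
  (with its sampled lateral position); oncoming particles near an entry
  are about to leave the trail and do not occupy it. Throughput is then
  set by entry congestion.

`mu_per_step()` documents the conversion. Wide-trail entries draw
$w(0) \sim \mathcal{N}(2.5,\, 0.8^2)$; draws beyond a wall are replaced by
0.01 or 4.99 cm. A particle exits when it reaches the opposite end; each
traversal is one way (no recirculation).

## What is measured

Every crossing of the trail midpoint ($x = 150$) is logged with time,
particle id, type, direction and (wide) lateral position. The statistics
layer works from that log alone, so empirical logs in the same CSV shape
can be fed through it unchanged:

* `encode_sequence()` maps crossings to $+1$ (O), $-1$ (U), $-2$ (L);
  maximal same-sign runs of this sequence are the **groups**
  (`decompose_groups()`), which alternate direction by construction.
* `group_statistics()` computes the group-size distribution over all
  groups and, over inbound groups only (laden ants exist only inbound):
  the laden share within groups of size $N$, the laden share at position
  $P$, and the share of size-$N$ groups led by a laden ant.
* `zone_proportions()` classifies wide-trail crossings into the central
  zone ($1.25 \le w < 3.75$, half-open) versus the two 1.25 cm margins,
  per type.
* `aggregate_replicates()` produces mean / s.d. / min / max envelopes
  across seeded replicates, omitting (not zero-filling) bins absent from
  a replicate.

```{r}
library(anttraffic)
ex <- run_experiment("wide_turn", n_replicates = 20, base_seed = 1)
glance(ex)
autoplot(ex) # central-zone boxplots by type
```

## Numerical and implementation choices

* **Synchronous update.** All decisions are taken on the start-of-step
  snapshot, then all positions advance; runs are bit-reproducible for a
  fixed seed (replicate $r$ of an experiment uses `base_seed + r - 1`).
* **Nearest governs.** Among several particles ahead within the radius the
  nearest one decides the action (ties by lower id). A consequence worth
  knowing: a particle the actor walks through (e.g. an oncoming unladen
  ant in front of an outbound one) can *shield* it from a give-way
  particle slightly further away, so a high-priority particle may
  occasionally drift past a stalled same-type particle. Making the nearest
  give-way particle govern instead removes this but collapses the narrow
  trail into a permanent jam, so the nearest-particle rule stands. The
  strict no-overtaking property holds for unladen particles, which give
  way to everything.
* **Crossing detection** is a sign change of $x - 150$ between
  consecutive steps (a particle landing exactly on 150 counts); each
  particle crosses at most once.
* **Yield timers** compare times with a $10^{-9}$ s guard against
  floating-point accumulation over 36 000 steps of 0.1 s.
* The engines are C++ (Rcpp) loops over parallel state vectors with an
  $x$-sorted neighbour scan; all randomness flows through R's RNG so
  `set.seed()` controls everything.

## Problem sizes and what the tests show

The packaged checks run 30 narrow and 20 wide hour-long replicates (a few
minutes on one core), matching the tolerance of the reference protocol's
1000-replicate means scaled to the reduced count. Passing them shows the
model reproduces the *organization* of trail traffic — alternating groups
with laden-led inbound clusters on the narrow trail; priority-ordered
central-zone use (L > O > U) that disappears under the stop-rule control
on the wide trail — under the idealizations listed below. They say nothing
about real ants beyond those idealizations: constant speeds and perfect
rule-following, point-like bodies that may overlap, no pheromones, memory
or re-circulation.

## Known limitations

* **The cooperative-passage distribution is a placeholder.** The published
  mechanism uses empirically measured probabilities for $n = 0..15$
  followers benefiting from a laden ant's passage; those numbers are not
  redistributable here. `default_coop_dist()` is a geometric distribution
  with mean ≈ 1, and `run_experiment()` warns when it is in use. The
  narrow-trail flow is sensitive to it: with the placeholder the model
  yields ≈ 6660 crossings/h against the 5347.2 reference value at the
  same rate parameter. Raising the placeholder's mean lowers the flow
  towards the reference (≈ 5730 at mean 3.5) but inflates group sizes and
  their variance well past the observed structure, so the
  group-structure-faithful placeholder is retained and the flow deviation
  is documented rather than tuned away. Users with access to measured
  passage probabilities should pass them as `coop_dist`.
* **Wide-trail flow variance is underdispersed.** The saturated queue
  makes wide-trail throughput nearly deterministic (s.d. ≈ 33 across
  replicates against a reference 97.8); the mean flow and group structure
  are within tolerance, but replicate envelopes on the wide trail are
  tighter than they should be.
* **Laden central-zone use tops out near 0.88**, the central mass of the
  clamped entry distribution: laden particles yield only to (rare,
  same-direction) laden particles, so nothing concentrates them beyond
  their entry spread. The qualitative statement — laden ants are the most
  central type by a wide margin — is robust.
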