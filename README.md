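# anttraffic

Self-propelled particle simulation of bidirectional traffic on leaf-cutting
ant (*Atta*) foraging trails, with the statistics pipeline used to
characterize how that traffic organizes itself.

Three particle types share a 300 cm trail between nest and leaf source:
outbound workers (**O**, speed 2.3 cm/s), inbound unladen workers (**U**,
2.3 cm/s) and inbound laden workers (**L**, 1.9 cm/s, carrying a leaf
fragment). A single pairwise priority matrix — priority order **L > O > U**
— decides who gives way at each encounter (within the interaction radius
`1 + 2·Δt·s_OU = 1.46 cm`):

|  actor \ other  |  O  |  U  |  L  |
|---|---|---|---|
| **O** | give way | walk | give way |
| **U** | give way | give way | give way |
| **L** | walk | walk | give way |

Giving way depends on the trail:

* **Narrow trail (1-D)** — giving way means stopping:
  `x(t+Δt) = x(t) + δ(t)·s·h·Δt` with `δ = 0` while stopped. An outbound
  particle yielding to a laden one additionally steps aside for
  `τ = 0.8·n` s (`n` drawn from the cooperative-passage distribution),
  letting ~`n` trailing unladen particles slip past — the *cooperative
  rule*. The emergent pattern is **de-synchronization**: alternating
  clusters of inbound and outbound crossings, inbound clusters typically
  led by a laden ant.
* **Wide trail (2-D, 5 cm)** — giving way means turning:
  `θ = θ_d + θ_I` with `θ_I = ±π/2` freezing longitudinal progress and
  moving the avoider laterally by `s·Δt`. The emergent pattern is **lane
  segregation**: the proportion of crossings in the central 2.5 cm zone is
  ordered by priority, laden ants most central. A stop-rule control
  variant shows the segregation disappears without turning.

Both endpoints spawn particles by a Poisson process (laden with
probability 0.24 at the source); midpoint crossings are logged and
summarized into signed sequences, same-direction groups, group-size /
laden-position statistics, flow, and per-type central-zone proportions,
with seeded replicate batches and mean/s.d./min/max envelopes.

## Worked example

One hour of narrow-trail traffic at the calibrated arrival rate:

```r
library(anttraffic)

cfg <- sim_config("narrow", seed = 1)
run <- run_narrow(cfg)
glance(run)
#> # A tibble: 1 × 8
#>   geometry n_crossings flow_per_hour spawned exited on_trail queued
#>   <chr>          <int>         <dbl>   <dbl>  <dbl>    <dbl>  <dbl>
#> 1 narrow          6542          6542    7149   6026     1123      0
```

6542 ants crossed the midpoint in the hour; every spawned ant is accounted
for (`spawned = exited + on_trail + queued`). The crossing log is a tibble
(`tidy(run)`), and its run-length structure is the de-synchronization
signal:

```r
st <- group_statistics(decompose_groups(run$crossings))
st
#> <group_stats> 1508 groups over 6542 crossings; mean size 4.34, max 53
```

Traffic alternates in groups averaging ~4 ants (largest 53) rather than
mixing head-on. A replicate batch of the wide-trail model shows the lane
structure:

```r
ex <- run_experiment("wide_turn", n_replicates = 5, base_seed = 1)
ex$aggregate$zone_props
#> # A tibble: 3 × 6
#>   type    mean      sd    min    max n_replicates
#>   <chr>  <dbl>   <dbl>  <dbl>  <dbl>        <int>
#> 1 L     0.884  0.00806 0.879  0.898             5
#> 2 O     0.877  0.0188  0.854  0.901             5
#> 3 U     0.0225 0.00313 0.0184 0.0262            5
```

88% of laden crossings are central against 2% of unladen ones; outbound
ants sit between (the L–O gap widens over more replicates). `autoplot(ex)`
draws the per-type boxplots, `plot_group_statistics(ex)` the four group
statistics with min–max envelopes.

A thin command-line front end wraps the same functions:

```sh
inst/exec/anttraffic simulate --geometry narrow --seed 1 --out crossings.csv
inst/exec/anttraffic stats --log crossings.csv --out summary.json
inst/exec/anttraffic experiment wide_turn --replicates 20 --base-seed 1 --out-dir out/
```

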