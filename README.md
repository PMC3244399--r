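# crushmi

Crowd-evacuation simulation with an information-theoretic crush detector.

Fatal crowd crushes develop when ordered ("laminar") pedestrian flow breaks
down into turbulence: people change speed and course to compete for exit
capacity, contact forces build, and compressive loads reach injurious
levels. Explicit Newtonian force monitoring detects this directly but is
expensive and only available inside force-resolving simulators; human
inspection of simulation output is cheap but subjective. `crushmi`
implements a third route: a **passive, information-theoretic order
parameter** computed from nothing but agent trajectories, validated
against an explicit contact-force monitor computed in the same simulation.

The package is aimed at evacuation-modelling researchers and
safety-engineering practitioners who want an objective, cheap crush
indicator for agent-based simulation studies (and, ultimately, for
trajectory data from any source).

## The method

**Order parameter.** For two discrete variables A and B, the mutual
information

```
I(A; B) = Σ_ab p(a,b) · log2 [ p(a,b) / (p(a) p(b)) ]      (bits)
```

is zero iff A and B are independent. For a crowd we take, once per second,
every ordered pair of distinct agents present at each simulation step of
the window, and pool the pairs' discretized coordinate values into one
joint histogram per variable — x, y (equal-width bins over the arena) and
heading θ (bins over (−π, π]). Ordered flow, in which agents move in a
synchronised fashion, yields dependent pairs and high MI; turbulent flow
yields independent pairs and MI at the estimator's bias floor
`(B−1)²/(2N ln 2)`. Falling MI therefore signals the breakdown of order —
the onset of crush — without touching any force computation.

**Ground truth.** The simulator is a social-forces model with the
high-density contact law: agents are driven toward their target exit by
`m(v0·ê − v)/τ`, repel each other psychologically with
`A·exp((r_ij − d_ij)/B)·n̂`, and, when bodies overlap (`d_ij < r_ij`),
exchange a contact force

```
f_ij = [ k (r_ij − d_ij) − c (Δv·n̂) ] n̂ + κ (r_ij − d_ij) (Δv·t̂) t̂
```

(radial restoring + normal damping + sliding friction; walls and obstacles
are treated as zero-radius, zero-velocity individuals at the nearest wall
point, with the same constants). The per-agent contact-force magnitude,
averaged over the population and over each 100-step second, is the
explicit crush signal the MI reading is validated against.

**Scenarios.** A benchmark room (20 m × 10 m, central obstacle, east exit,
west entrance) is run in two modes: *normal* (20 initial agents, inflow 10
agents/s, desired speed ≈ 1.25 m/s) and *evacuation* (inflow 30 agents/s,
desired speed ≈ 2 m/s — the structure is overwhelmed). A generic four-exit
"club" scenario adds per-exit route knowledge (probabilistic and
exact-count rules) and timed door closure.

## Worked example

```r
library(crushmi)

normal <- run_replicates(build_benchmark("normal"),     n = 3, base_seed = 1)
evac   <- run_replicates(build_benchmark("evacuation"), n = 3, base_seed = 101)

glance(normal)
#>   scenario         n_replicates mean_mi_bits mean_force_N total_exited
#> 1 benchmark-normal            3     0.000265    0.0000254         3107
glance(evac)
#>   scenario             n_replicates mean_mi_bits mean_force_N total_exited
#> 1 benchmark-evacuation            3     0.000105         41.6         9760

correlate_mi_force(evac)
#> Pearson r = -0.1944, two-tailed p = 0.000206, n = 360
```

Reading the numbers: under normal usage the room carries essentially no
contact force (2.5e-5 N mean) and a steady MI plateau (≈ 1.4e-4 bits after
t = 60 s at the default 8-bin discretizer). Overwhelming the structure
triples the inflow and collapses the order parameter (steady MI ≈ 4.8e-5
bits, a factor ≈ 3 below normal) while the mean contact force rises by
four orders of magnitude to ≈ 42 N, with per-agent peaks in the kN range.
Pooling the per-second (MI, force) readings of the evacuation ensemble
gives a significantly negative Pearson correlation: low MI co-occurs with
high force, which is exactly what makes MI usable as a passive early-crush
indicator. `autoplot(evac)` draws the MI and force series; 
`plot_mi_force_scatter(evac)` draws the scatter with the fitted line.

A thin CLI wraps the same functions:

```sh
inst/cli/micrush scenario --kind benchmark --mode evacuation --out ev.json
inst/cli/micrush run --spec ev.json --replicates 10 --seed 1 --out out/
inst/cli/micrush analyze --in out/ --correlate
```

## Package layout

- `R/geometry.R` — arena primitives (walls, convex obstacles, doors) and
  the routing rule (nearest known open exit).
- `R/forces.R` — the force laws as documented reference functions.
- `src/engine.cpp` — the production physics core (cell-list neighbour
  search, semi-implicit Euler, inflow/absorption, passive per-step
  occupancy recording).
- `R/mi.R` — discretizers, the plug-in MI estimator, pooled pairwise
  population MI, per-second readings.
- `R/force_monitor.R` — contact-force readings (net-vector and scalar-sum
  statistics).
- `R/scenarios.R`, `R/fixtures.R` — study scenarios, exit-knowledge
  assignment, and synthetic laminar/turbulent/Gaussian trajectory tables.
- `R/experiment.R`, `R/plots.R` — replicate ensembles, correlation
  analysis, report bundles, ggplot2 figures.
- `vignettes/crush-detection.Rmd` — the methods vignette (model,
  estimator, parameter choices, limitations).
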