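---
title: "Detecting crowd crush with a mutual-information order parameter"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting crowd crush with a mutual-information order parameter}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`crushmi` couples a 2-D social-forces evacuation simulator to two
per-second monitors: an explicit Newtonian contact-force monitor (the
expensive ground truth) and a passive mutual-information (MI) order
parameter computed from positions and headings alone. This vignette
documents the model, the estimator, the parameter choices, and what the
test battery does and does not establish.

## The pedestrian model

Each agent is a circular body (radius r, mass m) with a desired speed
`v0` and relaxation time `τ`. Per time step the net force on agent i is

* **driving**: `m (v0 ê − v) / τ`, with `ê` the unit vector towards the
  goal point — the nearest point of the target exit segment (shrunk at
  both ends by one body radius so agents do not aim at door jambs). An
  agent with no open target simply brakes (`v0 = 0` limit).
* **psychological repulsion** from every other agent:
  `A exp((r_ij − d_ij)/B) n̂_ij`, with `d_ij` the centre distance,
  `r_ij` the combined radii and `n̂_ij` the unit vector from j to i.
* **contact force**, active only when bodies overlap (`d_ij < r_ij`):
  a radial restoring term `k (r_ij − d_ij) n̂`, a dissipative normal
  damping term `−c ((v_i − v_j)·n̂) n̂`, and a sliding-friction term
  `κ (r_ij − d_ij) ((v_j − v_i)·t̂) t̂`, where `t̂` is `n̂` rotated +90°.
  The damping term is implemented with the dissipative sign — it opposes
  the relative normal velocity, removing energy on approach and on
  separation alike — and the pair force is exactly antisymmetric, so the
  total internal force over the population sums to zero to round-off.
* **wall and obstacle forces**: every solid segment (boundary pieces,
  partitions, obstacle edges, closed doors) is treated as a zero-radius,
  zero-velocity individual located at the nearest wall point, with the
  same contact constants. We additionally apply the standard psychological
  wall repulsion `A exp((r − d)/B) n̂` from the nearest wall point; without
  it agents scrape along walls unrealistically. Contact statistics count
  only the contact terms, never the psychological ones.

Obstacle avoidance is purely emergent: routing is a straight drive towards
the nearest known open exit (Euclidean distance to the door midpoint, ties
broken by the lexicographically smallest exit id for reproducibility), and
deflection around obstacles arises from the repulsion forces. No
line-of-sight or path planning is modelled; that is a deliberate scope
decision, adequate for convex obstacles and the single-room and club-stub
geometries shipped here, and clearly inadequate for maze-like floorplans.

### Constants

| symbol | meaning | default | units |
|---|---|---|---|
| k | radial (body) force constant | 1.2e5 | kg s⁻² |
| κ | sliding friction constant | 2.4e5 | kg m⁻¹ s⁻¹ |
| c | normal damping constant | 500 | kg s⁻¹ |
| A | psychological repulsion magnitude | 2000 | N |
| B | psychological repulsion range | 0.08 | m |
| τ | relaxation time | 0.5 | s |
| m | body mass | U(60, 90) | kg |
| r | body radius | U(0.25, 0.30) | m |
| v0 | desired speed, normal / evacuation | U(1.0, 1.5) / U(1.75, 2.25) | m s⁻¹ |

These are the values conventionally used with the high-density contact
extension of the social-forces model; all are configurable through
`force_constants()` and the scenario's `agent_params`. A conventional
1500 N level — the order of magnitude at which sustained compression
becomes life-threatening — is drawn on force plots as an annotation only;
no injury outcome is modelled.

### Integration and numerics

* **Time step** dt = 0.01 s, so 100 steps make exactly one 1-second
  recording window for both monitors.
* **Semi-implicit Euler** with a hard speed clamp at `v_max = 5 m/s`. The
  contact stiffness gives a pair frequency `sqrt(2k/m) ≈ 60 rad/s`, so
  `ω·dt ≈ 0.6` per contact: marginal but stable in practice because of the
  clamp and the damping; a `substeps` argument subdivides the physics step
  if a stiffer configuration needs it (recordings stay on the dt grid).
* **Interaction cutoff** 2.0 m in the engine's cell-list pass: the social
  force at that range is below 1e-4 N at the default constants, and
  contact terms always lie far inside it. The documented R force
  functions apply no cutoff; an engine-versus-R cross-check in the test
  suite bounds the difference.
* **Heading** θ is `atan2(vy, vx)` whenever speed exceeds 0.05 m/s and is
  carried over below that floor, so θ stays well defined for the detector
  in a jam. Initial headings point at the target exit.
* **Degenerate geometry**: coincident agent centres get a deterministic
  pseudo-random direction hashed from the id pair, so runs remain exactly
  reproducible; zero-length segments are rejected at construction.
* **Inflow** uses a fractional credit accumulator (`credit += rate·dt`,
  spawn on each whole unit, with 1e-9 slack against float drift), so a
  rate of 10 s⁻¹ over 5 s yields exactly 50 agents. Spawn positions are
  uniform along the entrance segment, offset inward by one body radius;
  positions overlapping an agent or wall are retried up to 20 times and
  then deferred to the next step, which caps the effective inflow at the
  entrance's physical capacity in a jam.
* **Absorption**: an agent whose body disk overlaps its (open) target exit
  segment is removed and time-stamped for the leaving profile. Closed
  doors are solid walls. When a target door closes, affected agents
  re-target their nearest known open exit, or the scenario's fallback
  exit, at the next 1-second boundary (door solidity and absorption are
  exact per step; only re-targeting has reading granularity, and all
  shipped closure times are whole seconds).

## The detector

Three variables are analysed per agent: x, y, and heading θ. Speed is
deliberately ignored — it varies little at high density. Per 1-second
window (100 steps), for each variable:

1. every agent value at every step is discretized into `B = 8` equal-width
   bins (x, y over the arena bounds; θ over (−π, π], wrapped cyclically so
   ±π land in the same bin; out-of-range values clamp to the edge bins);
2. every **ordered pair of distinct agents** present at a step contributes
   one `(bin_i, bin_j)` sample; all samples of the window are pooled into
   a single B×B joint histogram (ordered pairs make the joint symmetric,
   so the reading cannot depend on pair orientation);
3. the plug-in MI of that histogram is the window's reading for the
   variable, and `mi_mean_bits` averages the three variables.

The per-step occupancy counts are the sufficient statistic for this
pooling: the ordered-pair joint is `crossprod(W) − diag(colSums(W))` for a
steps-by-bins count matrix `W`, so the estimator costs O(steps·B²)
regardless of population size. The detector reads state and never writes
it — trajectories are bit-identical with the detector on or off.

Choices worth making explicit:

* **Pooling vs per-step averaging.** "MI each step, averaged over the
  window" admits two readings. We pool pairs across the window by default:
  a single step is one frozen configuration whose all-pairs histogram is a
  near-product (rank-one plus a deleted diagonal), so per-step MI is an
  O(1/n) finite-population artefact in every crowd state and carries
  almost no order information; pooling across the window instead measures
  the coherent motion of the occupancy distribution within the second,
  which is exactly the laminar/turbulent distinction. Both modes are
  implemented (`detector_options(mode = "average_per_step")`).
* **B = 8 bins** keeps the plug-in bias `(B−1)²/(2N ln 2)` negligible at
  crowd-sized pair counts (N ≈ 10⁵–10⁷ per window) while leaving enough
  resolution to see occupancy shifts. `mi_bias_bound()` gives the bias,
  and `mi_null_quantile()` the chi-square null quantile used as the
  calibrated "indistinguishable from independence" threshold: the null
  *mean* of the estimator equals the bias bound, so a threshold must sit
  at an upper quantile, not at the mean.
* **Validity.** A reading needs a population; windows whose mean agent
  count is below `n_min = 10` are flagged invalid and carry no MI.
* **Pair budget.** Above 2e6 pooled pairs per window the joint histogram
  is multinomially subsampled (seeded). With the closed-form pooling this
  is a noise bound rather than a cost bound; it is kept so that readings
  are comparable with an explicit pair-enumeration implementation.
* **Scale of the readings.** With pooled all-pairs sampling the absolute
  MI level is small (1e-5–1e-3 bits in the shipped scenarios) and depends
  on population size and window length. The detector is therefore used
  comparatively — normal vs overloaded, before vs after onset — not as an
  absolute threshold in bits. The component MIs are also reported
  separately (`mi_x_bits`, `mi_y_bits`, `mi_theta_bits`); note that a
  perfectly aligned crowd has *zero* heading entropy and hence zero
  heading MI, which is why the mean over three components, not θ alone,
  is the headline reading.

## The force monitor

The contact force suffered by an individual is the sum of the contact
contributions from other individuals and structural components. Two
per-agent statistics are recorded each step: the norm of the net
contact-force vector, and the scalar sum of contact magnitudes. They
differ exactly in the symmetric-squeeze case: two opposing 1200 N
contacts cancel to 0 N net while compressing with 2400 N. Net magnitude
is the primary series (`mean_force_N`); the scalar sum
(`mean_scalar_force_N`) is emitted alongside because crush injury follows
compression even when net force cancels. Readings average the population
mean over each 100-step window; empty-population steps contribute zero.

## Scenarios and the synthetic generator

`build_benchmark(mode)` produces the single-room validation topology:
20 m × 10 m, an 8 m exit centred on the east wall, an identical entrance
on the west wall, and a 2 m × 4 m central obstacle that disrupts the flow.
Normal mode starts 20 agents at the west end with inflow 10 s⁻¹;
evacuation mode raises inflow to 30 s⁻¹ and the desired speed to
≈ 2 m s⁻¹, overwhelming the exit capacity. The room dimensions, door
width and obstacle size are package choices (config-overridable): the
door is wide enough that 10 s⁻¹ flows freely and 30 s⁻¹ jams, which is
the contrast the benchmark exists to exhibit.

`build_club()` is a deliberately generic four-exit, partitioned arena
(24 m × 18 m) carrying the representative evacuation mechanics: 450
patrons, everyone knows the main door, 50% the bar door, 25% the stage
door, exactly 12 the kitchen door; the stage door becomes impassable at
30 s; the main door is the fallback. The geometry is invented — partitions
are short stubs with wide gaps so straight-line routing stays feasible —
and only the mechanics above are meaningful defaults. Knowledge rules are
independent Bernoulli draws per agent and exit (probability rules) or a
uniformly random subset of exactly the stated size (exact-count rules);
agents left knowing nothing are granted the fallback exit.

`fixture_trajectory()` generates trajectory tables with *known* order
structure, in the simulator's own CSV dialect so detector tests exercise
the production reader: `laminar` (a compact platoon in parallel lanes —
identical headings, x-occupancy translating coherently through the bins),
`turbulent` (positions and headings resampled independently every step),
and `gaussian` (two agents with bivariate-normal x values at correlation
ρ, giving the closed form `−½ log2(1 − ρ²)` to test against). What these
fixtures emulate is the ordered/disordered dichotomy and a known-MI
reference; what they do not emulate is real pedestrian kinematics,
congestion, or measurement noise — passing the fixture battery shows the
estimator is correct and calibrated, not that any particular real crowd
will separate as cleanly as the benchmark does.

## What the test battery computes

The suite checks, among others: estimator-oracle agreement (plug-in MI vs
an independent brute-force double sum, 1000 random tables, 1e-12 bits),
the Gaussian closed form within 10% at ρ ∈ {0.3, 0.6, 0.9} (N = 1e5
pairs, B = 32), the turbulence null below 0.05 bits and margin-shuffle
collapse below the chi-square null quantile, the contact-law unit value
(1200 N at 1 cm overlap), exact pairwise antisymmetry, per-step count
conservation, wall integrity (no penetration beyond 0.05 m on the
benchmark under normal usage; sustained jam pressure in the overload
scenario can compress bodies harder — that is crush, not an integrator
failure), bit-identical replay under a fixed seed, and the benchmark
contrast itself: 10 replicates per mode at 120 s — the package's
statistical problem size for this comparison — give steady-state
(t > 60 s) MI higher under normal flow with non-overlapping 95% CIs, mean
contact force at least an order of magnitude higher under evacuation, and
a significantly negative pooled Pearson correlation between per-second MI
and force readings in the evacuation ensemble (`scripts/acceptance.R`
reports the same quantities as JSON).

## Known limitations

* Circular bodies only; no rotational dynamics, no three-circle torsos,
  no vertical stacking — contact forces in extreme piles are therefore
  conservative.
* No fire, smoke, toxicity or visibility coupling; door closure is a
  timed event, not an environmental process.
* No route re-planning under congestion: agents hold their exit choice
  until it closes. Congestion response is purely mechanical.
* The pooled-pairs MI is a *relative* order parameter: its absolute scale
  shifts with population size, bin count and window length, so thresholds
  must be calibrated per scenario family (the chi-square null quantile is
  the principled floor).
* Per-region MI maps (crush localisation) and k-nearest-neighbour or
  kernel MI estimators are out of scope.
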