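---
title: "Eco-evolutionary assembly and invasion of mutualistic networks: models and methods"
author: "mutnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Eco-evolutionary assembly and invasion of mutualistic networks: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

mutnet simulates how bipartite mutualistic networks — pollination- or seed
dispersal-like communities of animal and plant morphospecies — emerge from
trait evolution, and how the emerged networks respond to the introduction of
an alien species. This vignette documents the model, the numerical choices,
and the design decisions behind the package, in enough detail that a reader
can judge what the simulations do and do not show.

## The ecological model

Each morphospecies is identified by a single quantitative trait (think
proboscis length or body size for animals, corolla-tube or fruit size for
plants) and a population density. Densities follow Lotka-Volterra dynamics
with three ingredients, all trait-mediated:

* **Resource access.** The carrying capacity of a morph is a Gaussian
  function of its trait, peaking at the guild's resource optimum
  (`x_Amax = 3` for animals with maximum `k_A = 400`; `y_Pmax = 2`,
  `k_P = 300` for plants) with width `sigma_A` (= `sigma_P`).
* **Competition.** Morphs of the same guild compete with Gaussian intensity
  `exp(-Δ²/2σ_C²)` in their trait difference: limiting similarity.
* **Mutualism.** An animal-plant pair produces a benefit
  `c·exp(-(x-y)²/2σ_m²)` (`c = 0.1`): assortative interactions with
  tolerance `sigma_m`. The realized gain passes through a Holling type II
  functional response (handling time `h = 0.1`) weighted by an *adaptive
  interaction preference*: a morph prefers partners that are both abundant
  and well-matched, normalized by the density-weighted mean benefit among
  the partner's suitors. Preferences therefore depend only on density
  ratios, not absolute abundances.

Growth rates are defined for zero-density morphs too; that value is exactly
the invasion fitness of a rare type in the environment set by the residents.

### Carrying-capacity normalization

The Gaussian carrying capacity can be read in two ways: an unnormalized
Gaussian whose maximum is exactly `k_A`, or a normalized Gaussian *density*
whose maximum rescales with `1/(σ_A√2π)`. mutnet defaults to the
unnormalized form — the description of morphs "accessing resources at a
maximum level k_A" only holds there, and it matches the classical
competition-model lineage this model descends from. With widths swept up to
`e ≈ 2.72`, the normalized form would entangle `k` and `σ_A` and shift the
diversification thresholds. The normalized variant remains available via
`model_params(normalized_K = TRUE)`.

## Ecological equilibria

`integrate_dynamics()` advances the dynamics with an adaptive Dormand-Prince
5(4) Runge-Kutta scheme *on log-densities*, which preserves positivity
without clipping (relative tolerance 1e-8). `find_equilibrium()` integrates
in growing chunks until the relative rate test
`max_i |dN_i/dt| < tol·max(N_i, 1)` passes (default `tol = 1e-9`,
`t_max = 1e5`), then polishes with damped Newton iterations on `N·f(N) = 0`
down to machine precision. The polish matters: the branching conditions
below are second finite differences of invasion fitness with steps of 1e-4,
so equilibrium errors of order 1e-9 would otherwise dominate the
curvatures. Morphs whose density falls below 1e-8 are removed (and an
introduced alien falling below it counts as a failed invasion). Morphs
whose traits are pushed far outside the viable range have carrying
capacities that underflow to zero; the integrator caps the log-density
slope at ±1e3 so such morphs crash to a density floor without collapsing
the step size.

## Trait evolution and network assembly

Traits evolve by the canonical equation of adaptive dynamics,
`dx_i/dt = m·Ñ_i·g_i`, with mutation scaling `m = 1e-3` and selection
gradient `g_i` computed by central differences (step 1e-6) of the invasion
fitness of rare mutants around each resident. `evolve_to_singularity()`
alternates equilibrium solving with adaptive Euler steps of this flow: the
step is capped so no trait moves more than 0.02 per step, grows
geometrically while progress is smooth, and backs off when the dominant
gradient component overshoots (sign reversal with growing magnitude).
Directional selection is considered ceased when `max |m·Ñ·g| < 1e-7` per
unit time.

After a branching event the trait dynamics become stiff — freshly split
pairs diverge quickly while the whole trait pattern drifts almost
neutrally — and the explicit flow crawls. Once the canonical flow is past
its divergence peak, the package therefore finishes the approach with a
damped Newton root-solve on the stacked selection gradients (ecologically
re-equilibrated at every evaluation, line search on `|g|`). A Newton
solution is rejected if it would collapse separated morphs onto each other
or reorder traits, so it cannot undo a branching; the explicit flow remains
the fallback.

Large assemblies under weak competition kernels additionally carry a
quasi-neutral mode: the whole morph pattern can translate along the trait
axis with almost no restoring force, so the canonical speed plateaus around
`1e-4`–`1e-3` while each morph sits within about `g/curvature ≈ 1e-4` trait
units of its local fitness optimum — the pattern is converged, only its slow
centering drift remains. When the Newton finisher cannot improve such a
state, it is accepted as singular under a documented soft tier: canonical
speed below `1e-3` *and* raw gradients below `0.1` (`soft = TRUE` on the
result). Branching conditions and disruptiveness evaluated there are
insensitive to the residual drift because the fitness curvatures are orders
of magnitude steeper than the remaining gradients.

At a singularity, `branching_conditions()` evaluates, per morph, the three
classical requirements for evolutionary branching by finite differences
(second-derivative step 1e-4):

1. *convergence stability* — the derivative of the selection gradient with
   respect to the resident trait (with ecological re-equilibration inside
   the perturbation) is negative; applied per morph as a diagonal test,
   not as the full cross-morph Jacobian;
2. *disruptive selection* — positive curvature of invasion fitness in the
   mutant trait;
3. *mutual invasibility* — the sum of resident- and mutant-trait curvatures
   is positive.

Morphs passing all three split: the daughter appears at `trait + 0.01` with
10% of the parent's density, the parent keeps 90%, so density is conserved
at the instant of branching. All qualifying morphs of both guilds split in
the same event — the only reading under which four events can yield `2^4`
morphs per guild. With `c = 0` the model collapses to the classical
single-guild competition model, where branching occurs exactly when
`σ_C < σ_A`; the test suite uses this closed-form regime as an oracle.

`assemble_network()` starts from one animal and one plant placed 0.5 trait
units below their resource optima at half carrying capacity (a neutral
choice: the starting point only needs to exercise directional selection
visibly, and assembly outcomes are equilibria of the flow) and repeats
evolve → test → split until the target number of events (4, 5, 6 for
small/medium/large networks) or until no morph qualifies. An event only
counts if the split survives to the next singularity; morphs that collapse
back onto each other (within 1e-3 trait units) are merged, which keeps
marginal, non-viable splits from inflating the morph count.

## The synthetic ensemble

`generate_ensemble()` is the package's data source: it sweeps the three
kernel widths `σ_C`, `σ_m`, `σ_A (= σ_P)` over the multiplicative ladder
`e^-3 … e` with step `e^1/4` (17 values), samples combinations in a seeded
random order, and keeps polymorphic, converged assemblies until the
requested quotas of size classes are filled. Discarded are: monomorphic
outcomes, runs whose singularity search fails, and runs leaving fewer than
two morphs in either guild (no bipartite network to analyze). A run that
stops short of its target but exactly matches a smaller unfilled class is
kept for that class.

What the generator emulates is the model's own study design — communities
shaped by the same dynamics that are later probed by invasions. What it
does *not* emulate are features of real pollination webs: sampling effort,
phenological turnover, heterogeneous generalization among natives (all
natives share one `σ_m`), spatial structure, and demographic noise.
Passing tests therefore validate the implementation and its internal
logic, not the model's fidelity to any particular empirical network.

## Network architecture metrics

The quantitative interaction matrix `Q` holds the symmetrized type II
recruitment between each animal-plant pair at equilibrium; entries below
1e-8 are exact zeros. Four weighted metrics summarize it:

* **SPE (H2')** — interaction specialization: the Shannon entropy of `Q`
  standardized between its marginal-constrained extremes. The minimum
  entropy is found by a greedy largest-remaining-cell packing with 100
  seeded randomized tie-break restarts (the exact minimization is a hard
  transportation problem; the greedy heuristic is the one the index's
  reference implementation uses). Computed on real-valued strengths, no
  integer discretization.
* **CON** — quantitative connectance: marginal-weighted effective partner
  counts `2^H` per row and column (the quantitative linkage density),
  divided by species richness.
* **NEST (WNODF)** — weighted nestedness based on overlap and decreasing
  fill: ordered pairs contribute only when both the marginal total and the
  fill strictly decrease (ties sorted stably, strict comparisons with
  tolerance 1e-12), scoring the share of the lower line's cells that are
  positive yet smaller than the upper line's. Completely filled matrices
  score 0 by construction — a property of this metric, visible in the
  ensemble for very generalist (large `σ_m`) networks.
* **MOD** — Barber-style weighted bipartite modularity, maximized by
  simulated annealing over joint module labels (node moves plus module
  merges; geometric cooling, T₀ = 1, ratio 0.995, 10⁴ steps, best of 5
  seeded restarts). The annealing parameters of the hierarchical reference
  algorithm are not published; these defaults are documented and every MOD
  value carries its seed. The objective is identical, so MOD values are
  comparable up to search noise (≈0.02 on the rank-one null).

## Stability, invasion, invasibility

* **RES** — `ln|λ|` of the dominant Jacobian eigenvalue at the preinvasion
  equilibrium, with the Jacobian computed by central differences on the
  exact right-hand side (step `max(1e-6, 1e-6·N)`), preferences
  re-evaluated inside each perturbation. "Dominant" is read as the largest
  real part (the rate-of-return eigenvalue); the largest-modulus variant is
  a flag.
* **ROB** — topological robustness: both guilds pooled, removed from the
  largest marginal total downward; species left with no partners go
  secondarily extinct, cascading; ROB is the fraction removed when more
  than half of all species are gone. The cascade is topological, not
  dynamical, matching the removal procedure this metric cites.
* **DIS** — disruptiveness: the invasion-fitness curvature at the singular
  animal traits, averaged over animal morphs (the summed variant is a
  flag). Positive DIS marks branching-prone, evolutionarily unstable
  communities.
* **Invasion trials** (`run_invasion_trial()`): an alien *animal* is added
  with trait `min + rtv·(max − min)` of the native animal traits, its own
  tolerance `glr·σ_m`, and total propagules equal to a fraction (5/10/25%)
  of the mean native animal density, delivered by one of five schedules
  (once-off; two equal pulses; three increasing 20/30/50%; three
  decreasing 50/30/20%; five equal pulses — pulses 5 time units apart,
  instantaneous). Traits are frozen; only ecology runs, to t = 25, where
  invasiveness `INVn = ln(final/propagules)` and impact
  `IMP = |ln(native final/initial)|` are measured on the animal guild. A
  "time step" is one model time unit. An alien finishing below 1e-8 is
  floored at 1e-8 inside the logarithm and flagged failed, keeping INVn
  finite and order-consistent. The alien's competition kernel and carrying
  capacity are the native ones — `glr` rescales only the mutualistic
  tolerance, which is what generalization means here.
* **INVb** — invasibility: the share of successful trials over 9 evenly
  spaced `rtv` values spanning the native range at `glr = 1` (the trial
  count is a design choice made for consistency with the 9×9 scenario
  grid). The ensemble correlation analysis additionally uses one reference
  trial per network whose alien carries the density-weighted mean native
  trait.

## Ensemble statistics

`metrics_table()` yields one row per network with the ten metrics
{SPE, CON, NEST, MOD, RES, ROB, DIS, INVb, INVn, IMP}.
`spearman_matrix()` computes tie-corrected Spearman correlations with
p-values (constant columns produce missing values, never zeros).
`cluster_metrics()` embeds the metrics by classical MDS of `d = 1 − r`
(the untransformed correlation; `1 − |r|` is a flag) in two dimensions —
matching the usual two-dimensional MDS representation — and selects the
smallest k whose between-cluster variance share exceeds 95% over seeded
k-means (50 restarts). `hierarchical_clusters()` runs average-linkage
clustering on the same distance and scores each cluster by an *ordinary*
bootstrap over networks: the share of resamples reproducing exactly that
member set. This is a deliberate, documented divergence from multiscale
(AU) bootstrapping; the support threshold stays at 0.95. Ordinary
bootstrap proportions are biased low relative to AU p-values, so cluster
support here is conservative.

## Problem sizes and determinism

The package's reference study (`scripts/acceptance.R`,
`run_full_study()`) uses a reduced ensemble of about 100 networks — 70
small and 30 medium — sampled from the full σ ladder, with the 10%
once-off propagule as the default invasion setting; the medium networks
additionally run the full 9×9 trait-by-generalization grid. This size
keeps a desk-scale run in minutes while leaving the rank correlations
stable in sign; the full three-class, 1000-network design is the same code
with larger quotas (an overnight run). Every stochastic component — sweep
sampling, H2min tie-breaks, annealing, k-means, bootstrap — draws from an
explicit seed, and assembly itself is deterministic, so any study is
reproducible bit-for-bit from its manifest.

## Known limitations

* The canonical flow is deterministic; mutation-limited stochastic trait
  substitution and polymorphic trait distributions are out of scope.
* Aliens are animals only (the model is guild-symmetric), and no evolution
  occurs during or after introduction.
* The Newton finisher locates the singularity the explicit flow is
  converging to; pathological parameter sets where the flow cycles would
  be reported as non-converged rather than resolved.
* Secondary extinctions in ROB are purely topological; a dynamical
  cascade could differ on weakly connected networks.
* WNODF is 0 on completely filled matrices, so NEST carries no signal for
  the most generalist parameter combinations.
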