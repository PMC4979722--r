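# mutnet

Eco-evolutionary assembly, architecture and invasibility of bipartite
mutualistic networks.

## What this package is for

Ecologists studying biological invasions in mutualistic communities
(pollination, seed dispersal) face a chicken-and-egg problem: the trait
structure of a native community is itself the outcome of ecological and
evolutionary dynamics, yet most invasion models treat resident traits as
fixed inputs. `mutnet` closes that loop. It grows bipartite
animal–plant networks from a single ancestral pair by adaptive-dynamics
trait evolution, then uses the grown networks as recipients for alien
introductions, and asks which properties of invader and community predict
invasion success and impact.

The model couples, for every animal morph `i` (density `A_i`, trait `x_i`)
and plant morph `j` (density `P_j`, trait `y_j`):

* logistic growth with a Gaussian, trait-mediated carrying capacity
  `K_A(x) = k_A exp(-(x - x_Amax)^2 / 2σ_A^2)`;
* Gaussian competition within guilds,
  `γ(x_i, x_k) = exp(-(x_i - x_k)^2 / 2σ_C^2)` (limiting similarity);
* assortative mutualism `b(x, y) = c·exp(-(x - y)^2 / 2σ_m^2)` through a
  Holling type II functional response with adaptive interaction
  preferences `w` (partners that are abundant *and* well matched are
  preferred):

  `dA_i/(A_i dt) = r_A − r_A Σ_k γ(x_i,x_k) A_k / K_A(x_i) + Σ_j b_ij w_ij P_j / (1 + h Σ_j w_ij P_j)`

  and symmetrically for plants.

Traits evolve by the canonical equation `dx_i/dt = m_A Ã_i g_i` (selection
gradient `g_i` of rare-mutant invasion fitness); at evolutionary
singularities the classical branching conditions (convergence stability,
disruptive selection, mutual invasibility) decide whether a morph splits.
Four, five or six branching events give small / medium / large networks.

On the assembled networks the package computes the quantitative
architecture metrics **H2′ specialization, weighted connectance, WNODF
nestedness, Barber bipartite modularity**, the stability metrics
**resilience** (dominant Jacobian eigenvalue), **robustness**
(generalist-first removal with secondary-extinction cascades) and
**disruptiveness** (mean invasion-fitness curvature), and runs **invasion
trials**: an alien animal with chosen relative trait value (`rtv`),
generalization ratio (`glr`), propagule size and introduction schedule,
measured after 25 time units as invasiveness `INVn` and impact `IMP`;
**invasibility** `INVb` is the success share over a trait grid spanning
the native range.

## Worked example

```r
library(mutnet)

# grow a small (4-event) network in a diversification-prone corner of the
# kernel space
p <- model_params(sigma_C = exp(-3), sigma_m = exp(-0.75), sigma_A = exp(0.25))
net <- assemble_network(p, target_events = 4)
net
#> Assembled network: 4 branching events (target 4), target_reached
#> Mutualistic community: 16 animal / 16 plant morphs

Q <- interaction_strength_matrix(net$community)
m <- architecture_metrics(Q, seed = 1)
unlist(m[c("SPE", "CON", "NEST", "MOD")])
#>       SPE       CON      NEST       MOD
#> 0.1071416 0.3512838 0.0000000 0.2559772

resilience(net$community)   #> 0.2955007
robustness(Q)               #> 0.53125
invasibility(net$community) #> 0.7777778

tr <- run_invasion_trial(net$community,
                         invasion_scenario(rtv = 0.5, glr = 1,
                                           propagule_fraction = 0.1, mode = 4))
tr
#> Invasion trial: INVn = 0.9379 (success), IMP = 0.01477, native declined
```

Reading the output: the community diversified into 16 morphs per guild;
its interaction matrix is moderately modular (MOD 0.26) and weakly
specialized (H2′ 0.11; σ_m here is fairly generalist, which also makes
WNODF 0 — a completely filled weighted matrix is unnested by
construction). Seven of nine alien trait positions can invade
(INVb 0.78). The mid-range alien introduced as three decreasing pulses
multiplies its propagules by e^0.94 ≈ 2.6 by t = 25 while depressing total
native animal density by about 1.5% (IMP is the |log| of that change).

The ensemble layer repeats this across the kernel sweep
(`generate_ensemble()`, `metrics_table()`, `spearman_matrix()`,
`cluster_metrics()`, `hierarchical_clusters()`, or `run_full_study()` for
the whole pipeline with CSV/JSON outputs). A thin command-line wrapper
with `metrics`, `invade` and `ensemble` subcommands is installed at
`inst/cli/mutnet.R`.

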