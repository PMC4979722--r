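test_that("a resident clone is selectively neutral", {
  for (seed in c(7, 21)) {
    eq <- find_equilibrium(random_community(seed))
    comm <- eq$community
    f <- invasion_fitness(eq, "animal", comm$animals$traits)
    expect_true(all(abs(f) < 1e-6))
  }
  # the contract is enforced
  p <- model_params()
  off <- community(guild_state(3, 1), guild_state(2, 1), p)
  expect_error(invasion_fitness(off, "animal", 3), "equilibrium")
})

test_that("invasion fitness reflects the ESS regime of the reduced model", {
  p <- model_params(c = 0, sigma_C = 1.5, sigma_A = 1)  # sigma_C > sigma_A: ESS
  eq <- find_equilibrium(community(guild_state(3, 10), guild_state(2, 10), p))
  expect_lt(invasion_fitness(eq, "animal", 3 + 0.3), 0)
  expect_lt(invasion_fitness(eq, "animal", 3 - 0.3), 0)
  # far outside the viable range fitness is strongly negative
  expect_lt(invasion_fitness(eq, "animal", 3 + 10), -1)
})

test_that("selection gradients point toward the resource optimum", {
  p <- model_params(c = 0)
  eq <- find_equilibrium(community(guild_state(2.2, 10), guild_state(2, 10), p))
  expect_gt(selection_gradient(eq)$animals, 0)
  eq2 <- find_equilibrium(community(guild_state(3, 10), guild_state(2, 10), p))
  expect_lt(abs(selection_gradient(eq2)$animals), 1e-8)
  # numeric oracle: gradient equals slope of the brute-force fitness curve
  eqm <- find_equilibrium(random_community(31))
  g <- selection_gradient(eqm)$animals[1]
  h <- 1e-5
  x1 <- eqm$community$animals$traits[1]
  slope <- (invasion_fitness(eqm, "animal", x1 + h) -
            invasion_fitness(eqm, "animal", x1 - h)) / (2 * h)
  expect_equal(g, slope, tolerance = 1e-4)
})

test_that("the canonical flow finds the reduced-model singularity", {
  p <- model_params(c = 0, sigma_C = 0.6, sigma_A = 1)
  s <- evolve_to_singularity(community(guild_state(1.8, 50),
                                       guild_state(1.5, 50), p))
  expect_true(s$converged)
  expect_equal(s$community$animals$traits, 3, tolerance = 1e-4)
  expect_equal(s$community$plants$traits, 2, tolerance = 1e-4)
})

test_that("doubling the mutation rate halves the time to the singularity", {
  p1 <- model_params(c = 0, sigma_C = 1.5, sigma_A = 1)  # ESS: pure approach
  p2 <- model_params(c = 0, sigma_C = 1.5, sigma_A = 1, m_A = 2e-3, m_P = 2e-3)
  s1 <- evolve_to_singularity(community(guild_state(2.2, 50),
                                        guild_state(1.4, 50), p1))
  s2 <- evolve_to_singularity(community(guild_state(2.2, 50),
                                        guild_state(1.4, 50), p2))
  expect_true(s1$converged && s2$converged)
  expect_equal(s2$time / s1$time, 0.5, tolerance = 1e-6)
})

test_that("branching conditions recover the classical competition regimes", {
  # sigma_C < sigma_A: convergence-stable fitness minimum, branching
  pb <- model_params(c = 0, sigma_C = 0.5, sigma_A = 1)
  sb <- evolve_to_singularity(community(guild_state(2.6, 50),
                                        guild_state(1.6, 50), pb))
  bc <- branching_conditions(sb)
  a <- bc[bc$guild == "animal", ]
  expect_true(a$convergent && a$disruptive && a$coexisting)
  # curvature of the reduced model: r (1/sigma_C^2 - 1/sigma_A^2)
  expect_equal(a$curv_mutant, 1 / 0.25 - 1, tolerance = 1e-3)
  # sigma_C > sigma_A: ESS, no disruptive selection
  pe <- model_params(c = 0, sigma_C = 1.4, sigma_A = 1)
  se <- evolve_to_singularity(community(guild_state(2.6, 50),
                                        guild_state(1.6, 50), pe))
  be <- branching_conditions(se)
  expect_true(all(be$convergent))
  expect_false(any(be$disruptive))
})

test_that("branching splits follow the +0.01 / 10% / 90% rule", {
  p <- model_params()
  comm <- community(guild_state(3, 100), guild_state(2, 60), p)
  out <- apply_branching(comm, data.frame(guild = "animal", index = 1))
  expect_equal(out$animals$traits, c(3, 3.01))
  expect_equal(out$animals$densities, c(90, 10))
  expect_equal(sum(out$animals$densities), 100)  # density conserved
  expect_equal(out$plants$densities, 60)
  # no qualifying morphs: identity
  expect_identical(apply_branching(comm, NULL), comm)
  # both guilds can split in the same event
  out2 <- apply_branching(comm, data.frame(guild = c("animal", "plant"),
                                           index = c(1, 1)))
  expect_length(out2$animals$traits, 2)
  expect_length(out2$plants$traits, 2)
  # daughters receive fresh ids, distinct within each guild
  expect_false(anyDuplicated(out2$animals$ids) > 0)
  expect_false(anyDuplicated(out2$plants$ids) > 0)
})

test_that("assembly is deterministic and respects morph-count bounds", {
  p <- model_params(sigma_C = exp(-3), sigma_m = exp(-0.75),
                    sigma_A = exp(0.25))
  a1 <- assemble_network(p, target_events = 2)
  a2 <- assemble_network(p, target_events = 2)
  expect_identical(a1$community$animals$traits, a2$community$animals$traits)
  expect_identical(a1$community$plants$densities, a2$community$plants$densities)
  expect_equal(a1$n_events, 2)
  for (g in list(a1$community$animals, a1$community$plants)) {
    expect_gte(length(g$traits), 2)
    expect_lte(length(g$traits), 2^a1$n_events)
  }
  # the final state is at ecological equilibrium and a singularity
  expect_lt(mutnet:::residual_of(a1$community), 1e-8)
  r <- mutnet:::stacked_rate(a1$community)$rate
  expect_lt(max(abs(r)), 1e-6)
})

test_that("the ESS regime yields a monomorphic (discarded) assembly", {
  p <- model_params(c = 0, sigma_C = 1.5, sigma_A = 1)
  a <- assemble_network(p, target_events = 4)
  expect_true(a$monomorphic)
  expect_equal(a$n_events, 0)
})

test_that("assembly logs trajectories and events coherently", {
  a <- fixture_network()
  expect_equal(a$n_events, 4)
  expect_s3_class(a$trajectory, "data.frame")
  expect_true(all(c("time", "morph_id", "guild", "trait") %in%
                  names(a$trajectory)))
  expect_false(is.unsorted(vapply(a$events, function(e) e$time[1], 0)))
  # morphs per guild bounded by 2^events
  expect_lte(length(a$community$animals$traits), 16)
  expect_gte(length(a$community$animals$traits), 2)
})

test_that("ensemble generation fills quotas with provenance", {
  ens <- generate_ensemble(c(small = 2), seed = 42)
  expect_s3_class(ens, "mutnet_ensemble")
  expect_length(ens, 2)
  for (log in ens) {
    expect_equal(log$size_class, "small")
    expect_equal(log$n_events, 4)
    expect_gte(length(log$community$animals$traits), 2)
    expect_gte(length(log$community$plants$traits), 2)
    expect_false(is.null(log$params))
  }
  # reproducible from the seed
  ens2 <- generate_ensemble(c(small = 2), seed = 42)
  expect_identical(ens[[1]]$community$animals$traits,
                   ens2[[1]]$community$animals$traits)
})
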