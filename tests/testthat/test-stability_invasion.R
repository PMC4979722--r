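test_that("resilience equals ln|dominant eigenvalue| of the Jacobian", {
  # single logistic morph: J = -r
  p1 <- model_params(c = 0, r_A = 1)
  eq1 <- find_equilibrium(community(guild_state(3, 10), guild_state(2, 10), p1))
  expect_equal(resilience(eq1$community), 0, tolerance = 1e-6)
  pe <- model_params(c = 0, r_A = exp(1), r_P = exp(1))
  eqe <- find_equilibrium(community(guild_state(3, 10), guild_state(2, 10), pe))
  expect_equal(resilience(eqe$community), 1, tolerance = 1e-6)
  # dominant = largest real part, cross-checked against eigen()
  eq2 <- find_equilibrium(random_community(13))
  ev <- eigen(jacobian(eq2$community), only.values = TRUE)$values
  expect_equal(resilience(eq2$community),
               log(Mod(ev[which.max(Re(ev))])), tolerance = 1e-10)
  # far-from-equilibrium states with positive eigenvalues are rejected
  tiny <- community(guild_state(3, 0.01), guild_state(2, 0.01),
                    model_params())
  expect_error(resilience(tiny), "stable")
})

test_that("robustness follows the generalist-first removal cascade", {
  # star: removing the hub loses everyone
  star <- matrix(c(1, 1, 1), 1, 3)
  expect_equal(robustness(star), 1 / 4)
  # uniform 2x2 needs two removals
  expect_equal(robustness(matrix(1, 2, 2)), 0.5)
  # exact agreement with brute force on random small-integer matrices
  set.seed(17)
  for (k in 1:200) {
    n <- sample(2:4, 1); m <- sample(2:4, 1)
    Q <- matrix(sample(0:3, n * m, replace = TRUE), n, m)
    if (sum(Q) == 0) next
    expect_equal(robustness(Q), ref_robustness(Q))
  }
  rb <- robustness(matrix(rexp(12), 3, 4))
  expect_gt(rb, 0); expect_lte(rb, 1)
})

test_that("disruptiveness measures fitness curvature at the singularity", {
  # synthetic calibration of the finite-difference curvature
  expect_equal(mutnet:::curvature_fd(function(x) (x - 1.3)^2, 1.3), 2,
               tolerance = 1e-6)
  # branching regime: fitness minimum, DIS > 0
  pb <- model_params(c = 0, sigma_C = 0.5, sigma_A = 1)
  sb <- evolve_to_singularity(community(guild_state(2.7, 50),
                                        guild_state(1.7, 50), pb))
  expect_gt(disruptiveness(sb$community), 0)
  # ESS regime: fitness maximum, DIS < 0
  pe <- model_params(c = 0, sigma_C = 1.5, sigma_A = 1)
  se <- evolve_to_singularity(community(guild_state(2.7, 50),
                                        guild_state(1.7, 50), pe))
  expect_lt(disruptiveness(se$community), 0)
  # sum variant aggregates instead of averaging
  expect_equal(disruptiveness(sb$community, aggregate = "sum"),
               disruptiveness(sb$community))  # single animal morph
  # off-singularity communities are rejected
  off <- find_equilibrium(community(guild_state(2.2, 50),
                                    guild_state(1.7, 50), pb))
  expect_error(disruptiveness(off$community), "singularity")
})

test_that("introduction schedules deliver the five propagule modes", {
  s4 <- introduction_schedule(4, 10)
  expect_equal(s4$time, c(0, 5, 10))
  expect_equal(s4$amount, c(5, 3, 2))
  s5 <- introduction_schedule(5, 10)
  expect_equal(s5$time, c(0, 5, 10, 15, 20))
  expect_equal(s5$amount, rep(2, 5))
  for (mode in 1:5)
    expect_equal(sum(introduction_schedule(mode, 7.3)$amount), 7.3)
  expect_error(introduction_schedule(6, 1), "unknown")
  expect_error(introduction_schedule(1, 0), "> 0")
})

test_that("a clone alien is quasi-neutral and freezes native traits", {
  net <- fixture_network()$community
  xr <- range(net$animals$traits)
  i <- which.max(net$animals$densities)
  rtv <- (net$animals$traits[i] - xr[1]) / diff(xr)
  tr <- run_invasion_trial(net, invasion_scenario(rtv, glr = 1,
                                                  propagule_fraction = 1e-3))
  expect_lt(abs(tr$INVn), 0.02)
  # tiny propagule, vanishing impact
  expect_lt(tr$IMP, 1e-3)
  # native traits are frozen; the alien is appended last
  expect_identical(tr$community$animals$traits[seq_along(net$animals$traits)],
                   net$animals$traits)
  expect_equal(tr$community$alien_index, length(net$animals$traits) + 1L)
  # INVn invariant to splitting the propagule for a neutral alien
  tr5 <- run_invasion_trial(net, invasion_scenario(rtv, glr = 1,
                                                   propagule_fraction = 1e-3,
                                                   mode = 5))
  expect_lt(abs(tr$INVn - tr5$INVn), 0.02)
})

test_that("aliens far outside the native range are trivial", {
  net <- fixture_network()$community
  tr <- run_invasion_trial(net, invasion_scenario(rtv = 8, glr = 1,
                                                  propagule_fraction = 0.1))
  expect_false(tr$success)
  expect_true(tr$failed)
  expect_lt(tr$IMP, 1e-4)
})

test_that("the scenario grid and invasibility behave combinatorially", {
  net <- fixture_network()$community
  g <- invasiveness_impact_grid(net, rtv_grid = seq(0, 1, length.out = 3),
                                glr_grid = 5^seq(-1, 1, length.out = 3))
  expect_equal(nrow(g), 9)
  expect_true(all(g$IMP >= 0))
  expect_equal(g$success, g$INVn > 0)
  # default glr grid is log-symmetric around exactly 1
  glr <- 5^seq(-1, 1, length.out = 9)
  expect_equal(glr[5], 1)
  ib <- invasibility(net, seq(0, 1, length.out = 9))
  expect_true(ib %in% ((0:9) / 9))
  # deterministic
  expect_identical(ib, invasibility(net, seq(0, 1, length.out = 9)))
})

test_that("the reference invasion record uses the density-weighted trait", {
  net <- fixture_network()$community
  rec <- ensemble_invasion_record(net)
  expect_equal(rec$alien_trait,
               weighted.mean(net$animals$traits, net$animals$densities))
  expect_identical(rec$success, rec$INVn > 0)
  # symmetric equal-density pair: plain arithmetic mean
  p <- model_params(sigma_C = 1.4)
  comm <- find_equilibrium(community(guild_state(c(2.8, 3.2), c(40, 40)),
                                     guild_state(2, 50), p))$community
  comm$animals$densities <- rep(mean(comm$animals$densities), 2)
  rec2 <- ensemble_invasion_record(comm)
  expect_equal(rec2$alien_trait, mean(comm$animals$traits))
})
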