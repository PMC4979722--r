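test_that("integration reproduces the logistic closed form", {
  p <- model_params(c = 0)
  K <- 400
  comm <- community(guild_state(3, K / 2), guild_state(2, 300), p)
  for (tt in c(1, 3, 6)) {
    out <- integrate_dynamics(comm, tt)
    expect_equal(out$animals$densities, K / (1 + exp(-tt)), tolerance = 1e-7)
  }
})

test_that("the all-zero state is absorbing and recording works", {
  p <- model_params()
  comm <- community(guild_state(c(2, 3), c(0, 0)), guild_state(2, 0), p)
  out <- integrate_dynamics(comm, 10)
  expect_equal(out$animals$densities, c(0, 0))
  rec <- integrate_dynamics(community(guild_state(3, 10), guild_state(2, 10),
                                      model_params()),
                            5, record = TRUE, record_dt = 1)
  expect_s3_class(rec$trajectory, "data.frame")
  expect_setequal(unique(rec$trajectory$time), 0:5)
  expect_true(all(rec$trajectory$density >= 0))
})

test_that("adaptive integration agrees with a fine-step Euler oracle", {
  p <- model_params(sigma_m = 0.5)
  comm <- community(guild_state(2.6, 50), guild_state(2.2, 40), p)
  fast <- integrate_dynamics(comm, 4)
  slow <- euler_integrate(comm, 4, dt = 2e-4)
  expect_equal(fast$animals$densities, slow$animals$densities,
               tolerance = 5e-4)
  expect_equal(fast$plants$densities, slow$plants$densities,
               tolerance = 5e-4)
})

test_that("densities never become negative during integration", {
  for (seed in c(2, 9, 23)) {
    comm <- random_community(seed)
    out <- integrate_dynamics(comm, 50)
    expect_true(all(out$animals$densities > 0))
    expect_true(all(out$plants$densities > 0))
  }
})

test_that("find_equilibrium reaches the logistic fixed point", {
  p <- model_params(c = 0)
  eq <- find_equilibrium(community(guild_state(2.4, 5), guild_state(2, 5), p))
  expect_true(eq$converged)
  expect_equal(eq$community$animals$densities,
               carrying_capacity(2.4, "animal", p), tolerance = 1e-9)
  expect_lte(eq$residual, 1e-9)
})

test_that("a community that lost its plants relaxes to pure competition", {
  p <- model_params(sigma_C = 1.2)  # c > 0 but no partners left
  comm <- community(guild_state(c(2.7, 3.3), c(50, 50)),
                    guild_state(numeric(0), numeric(0)), p)
  eq <- find_equilibrium(comm)
  expect_true(eq$converged)
  # reduced model: gamma %*% A = K at coexistence
  x <- eq$community$animals$traits
  gam <- outer(x, x, function(a, b) exp(-(a - b)^2 / (2 * p$sigma_C^2)))
  K <- carrying_capacity(x, "animal", p)
  expect_equal(as.numeric(gam %*% eq$community$animals$densities), K,
               tolerance = 1e-8)
})

test_that("equilibrium satisfies the relative rate contract", {
  eq <- find_equilibrium(random_community(5), tol = 1e-9)
  expect_true(eq$converged)
  f <- percapita_growth(eq$community)
  N <- c(eq$community$animals$densities, eq$community$plants$densities)
  expect_lt(max(abs(N * c(f$animals, f$plants)) / pmax(N, 1)), 1e-8)
})

test_that("prune_extinct removes sub-threshold morphs and tracks the alien", {
  p <- model_params()
  comm <- community(guild_state(c(1, 2, 3), c(5, 1e-9, 2)),
                    guild_state(2, 10), p)
  pruned <- prune_extinct(comm)
  expect_equal(pruned$animals$densities, c(5, 2))
  expect_equal(pruned$animals$ids, c(1L, 3L))
  # all above threshold: identity
  expect_identical(prune_extinct(pruned)$animals, pruned$animals)
  # alien below threshold: marker cleared, flagged as failed invasion
  alien <- community(guild_state(c(1, 2), c(5, 1e-12)), guild_state(2, 10), p,
                     alien_index = 2L, alien_sigma_m = 0.3)
  pr <- prune_extinct(alien)
  expect_true(is.na(pr$alien_index))
  expect_true(isTRUE(attr(pr, "failed_invasion")))
  # alien above threshold: index remapped past removed natives
  alien2 <- community(guild_state(c(1, 2, 3), c(1e-12, 5, 7)),
                      guild_state(2, 10), p,
                      alien_index = 3L, alien_sigma_m = 0.3)
  expect_equal(prune_extinct(alien2)$alien_index, 2L)
})

test_that("jacobian matches analytic derivatives of reduced models", {
  p <- model_params(c = 0)
  # single logistic morph at K: d/dA [r A (1 - A/K)] = -r
  eq <- find_equilibrium(community(guild_state(3, 10), guild_state(2, 10), p))
  J <- jacobian(eq$community)
  expect_equal(J[1, 1], -1, tolerance = 1e-6)
  expect_true(is_asymptotically_stable(eq$community))
  # two competing morphs: J_kl = -r N_k gamma_kl / K_k at equilibrium
  p2 <- model_params(c = 0, sigma_C = 1.5)
  eq2 <- find_equilibrium(community(guild_state(c(2.6, 3.4), c(50, 50)),
                                    guild_state(numeric(0), numeric(0)), p2))
  x <- eq2$community$animals$traits; N <- eq2$community$animals$densities
  gam <- outer(x, x, function(a, b) exp(-(a - b)^2 / (2 * p2$sigma_C^2)))
  K <- carrying_capacity(x, "animal", p2)
  Ja <- -outer(N / K, rep(1, 2)) * gam
  expect_equal(jacobian(eq2$community), Ja, tolerance = 1e-6)
  expect_lt(max(Re(eigen(jacobian(eq2$community))$values)), 0)
})

test_that("equilibria match a fine-step Euler run to 4 significant digits", {
  for (seed in c(3, 14)) {
    comm <- random_community(seed)
    eq <- find_equilibrium(comm)
    ref <- euler_integrate(comm, 1000, dt = 5e-3)
    keep <- ref$animals$densities > 1e-6  # oracle run may retain dying morphs
    expect_equal(eq$community$animals$densities,
                 ref$animals$densities[keep][seq_along(eq$community$animals$densities)],
                 tolerance = 1e-4)
  }
})
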