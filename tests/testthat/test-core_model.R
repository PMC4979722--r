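test_that("competition kernel is a Gaussian of trait difference", {
  expect_equal(competition_kernel(0, 0.7), 1)
  # half-maximum at delta = sigma*sqrt(2 ln 2)
  expect_equal(competition_kernel(0.7 * sqrt(2 * log(2)), 0.7), 0.5)
  expect_equal(competition_kernel(-0.3, 0.7), competition_kernel(0.3, 0.7))
  expect_gt(competition_kernel(1, 1e3), 1 - 1e-5)
  expect_error(competition_kernel(1, 0), "positive")
  expect_error(competition_kernel(1, -2), "positive")
})

test_that("carrying capacity peaks at the resource optimum", {
  p <- model_params()
  expect_equal(carrying_capacity(3, "animal", p), 400)
  expect_equal(carrying_capacity(2, "plant", p), 300)
  d <- 0.8
  expect_equal(carrying_capacity(3 + d, "animal", p),
               carrying_capacity(3 - d, "animal", p))
  expect_lt(carrying_capacity(3 + 50 * p$sigma_A, "animal", p), 1e-12)
  pn <- model_params(normalized_K = TRUE)
  expect_equal(carrying_capacity(3, "animal", pn),
               400 / (pn$sigma_A * sqrt(2 * pi)))
})

test_that("mutualistic benefit is assortative with tolerance sigma_m", {
  p <- model_params()
  expect_equal(mutualistic_benefit(1.4, 1.4, p), 0.1)
  expect_equal(mutualistic_benefit(p$sigma_m * sqrt(2 * log(2)), 0, p), 0.05)
  expect_equal(mutualistic_benefit(1, 2, p), mutualistic_benefit(2, 1, p))
  expect_lt(mutualistic_benefit(1, 1.5, p, sigma_m = 1e-4), 1e-300)
})

test_that("interaction preferences normalize by the partner's suitors", {
  p <- model_params()
  # a single animal gets preference 1 for every plant
  comm1 <- community(guild_state(2.5, 50), guild_state(c(2, 3), c(10, 40)), p)
  expect_equal(unname(interaction_preference(comm1)$w_AP), matrix(1, 1, 2))
  # animals sharing one trait: benefit constant in k cancels
  comm2 <- community(guild_state(c(2.5, 2.5), c(10, 30)),
                     guild_state(c(2, 3), c(10, 40)), p)
  expect_equal(unname(interaction_preference(comm2)$w_AP), matrix(1, 2, 2))
  # direct arithmetic: A = [1, 3], benefit column [0.1, 0.05] -> w = [1.6, 0.8]
  y <- 2
  x2 <- y + p$sigma_m * sqrt(2 * log(2))  # half-maximum benefit
  comm3 <- community(guild_state(c(y, x2), c(1, 3)), guild_state(y, 10), p)
  w <- interaction_preference(comm3)$w_AP
  expect_equal(unname(w[, 1]), c(1.6, 0.8), tolerance = 1e-12)
  # zero partner densities -> preference 0, not an error
  comm4 <- community(guild_state(2.5, 50), guild_state(2.5, 0), p)
  expect_equal(unname(interaction_preference(comm4)$w_PA), matrix(0, 1, 1))
})

test_that("per-capita growth matches an independent plain-R implementation", {
  for (seed in 1:8) {
    comm <- random_community(seed)
    got <- percapita_growth(comm)
    want <- ref_growth(comm)
    expect_equal(got$animals, want$animals, tolerance = 1e-12)
    expect_equal(got$plants, want$plants, tolerance = 1e-12)
  }
})

test_that("with c = 0 growth reduces to logistic competition", {
  p <- model_params(c = 0, sigma_C = 2)
  comm <- community(guild_state(c(3, 3), c(30, 50)), guild_state(2, 10), p)
  f <- percapita_growth(comm)
  # equal traits: kernel collapses to 1 -> f = r (1 - (A1+A2)/K)
  expect_equal(f$animals, rep(1 - 80 / 400, 2), tolerance = 1e-12)
  # single morph at equilibrium density
  comm2 <- community(guild_state(2.4, carrying_capacity(2.4, "animal", p)),
                     guild_state(2, 10), p)
  expect_equal(percapita_growth(comm2)$animals, 0, tolerance = 1e-12)
})

test_that("growth is defined for zero-density morphs (rare-type fitness)", {
  p <- model_params()
  comm <- community(guild_state(c(3, 2.8), c(100, 0)),
                    guild_state(2, 50), p)
  f <- percapita_growth(comm)
  expect_length(f$animals, 2)
  expect_true(all(is.finite(f$animals)))
})

test_that("interaction strength matrix follows the symmetrized functional response", {
  # 1x1 toy: A = P = 10, matched traits (b = c = 0.1), w = 1, h = 0.1 -> q = 5
  p <- model_params()
  comm <- community(guild_state(2.2, 10), guild_state(2.2, 10), p)
  Q <- interaction_strength_matrix(comm)
  expect_equal(unname(Q[1, 1]), 5, tolerance = 1e-12)
  # zero density partner -> zero strength
  comm0 <- community(guild_state(2.2, 0), guild_state(2.2, 10), p)
  expect_equal(unname(interaction_strength_matrix(comm0)[1, 1]), 0)
  # entries below the threshold are stored as exactly zero
  commt <- community(guild_state(2.2, 1e-4), guild_state(2.2, 1e-4), p)
  expect_identical(unname(interaction_strength_matrix(commt)[1, 1]), 0)
  expect_identical(dimnames(Q), list("A1", "P1"))
})

test_that("interaction matrix is transpose-consistent under guild swap", {
  p <- model_params(k_A = 350, k_P = 350, x_Amax = 2.5, y_Pmax = 2.5)
  set.seed(4)
  xA <- 2.5 + runif(3, -0.3, 0.3); xP <- 2.5 + runif(2, -0.3, 0.3)
  A <- runif(3, 10, 60); P <- runif(2, 10, 60)
  Q <- interaction_strength_matrix(community(guild_state(xA, A),
                                             guild_state(xP, P), p))
  Qsw <- interaction_strength_matrix(community(guild_state(xP, P),
                                               guild_state(xA, A), p))
  expect_equal(unname(unclass(Q)), t(unname(unclass(Qsw))), tolerance = 1e-12)
  expect_true(all(Q >= 0))
})

test_that("preferences depend only on density ratios", {
  comm <- random_community(11)
  w1 <- interaction_preference(comm)
  comm$animals$densities <- comm$animals$densities * 7.3
  comm$plants$densities <- comm$plants$densities * 7.3
  w2 <- interaction_preference(comm)
  expect_equal(w1$w_AP, w2$w_AP, tolerance = 1e-12)
  expect_equal(w1$w_PA, w2$w_PA, tolerance = 1e-12)
})

test_that("parameter validation rejects impossible values", {
  expect_error(model_params(sigma_m = 0), "positive")
  expect_error(model_params(h = -1), "non-negative")
  expect_error(model_params(k_A = 0), "positive")
  expect_error(guild_state(c(1, 2), 5), "equal length")
  expect_error(guild_state(1, -2), ">= 0")
  expect_error(community(guild_state(1, 2), guild_state(2, 3),
                         model_params(), alien_index = 3,
                         alien_sigma_m = 0.1), "out of range")
})
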