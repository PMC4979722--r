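# Independent reference implementations used as oracles, deliberately
# written in plain R directly from the model definitions, sharing no code
# with the package internals.

# per-capita growth rates, straight from the equations
ref_growth <- function(comm) {
  p <- comm$params
  xA <- comm$animals$traits; xP <- comm$plants$traits
  A <- comm$animals$densities; P <- comm$plants$densities
  n <- length(xA); m <- length(xP)
  smA <- rep(p$sigma_m, n)
  if (!is.na(comm$alien_index)) smA[comm$alien_index] <- comm$alien_sigma_m
  KA <- p$k_A * exp(-(xA - p$x_Amax)^2 / (2 * p$sigma_A^2))
  KP <- p$k_P * exp(-(xP - p$y_Pmax)^2 / (2 * p$sigma_P^2))
  fA <- numeric(n); fP <- numeric(m)
  for (i in seq_len(n))
    fA[i] <- p$r_A - p$r_A * sum(exp(-(xA[i] - xA)^2 / (2 * p$sigma_C^2)) * A) / KA[i]
  for (j in seq_len(m))
    fP[j] <- p$r_P - p$r_P * sum(exp(-(xP[j] - xP)^2 / (2 * p$sigma_C^2)) * P) / KP[j]
  if (p$c > 0 && n > 0 && m > 0) {
    b <- matrix(0, n, m)
    for (i in seq_len(n)) for (j in seq_len(m))
      b[i, j] <- p$c * exp(-(xA[i] - xP[j])^2 / (2 * smA[i]^2))
    SA <- sum(A); SP <- sum(P)
    for (i in seq_len(n)) {
      num <- 0; sat <- 0
      for (j in seq_len(m)) {
        den <- sum(A * b[, j])
        w <- if (den > 0 && SA > 0) b[i, j] * SA / den else 0
        num <- num + b[i, j] * w * P[j]; sat <- sat + w * P[j]
      }
      fA[i] <- fA[i] + num / (1 + p$h * sat)
    }
    for (j in seq_len(m)) {
      num <- 0; sat <- 0
      for (i in seq_len(n)) {
        den <- sum(P * b[i, ])
        w <- if (den > 0 && SP > 0) b[i, j] * SP / den else 0
        num <- num + b[i, j] * w * A[i]; sat <- sat + w * A[i]
      }
      fP[j] <- fP[j] + num / (1 + p$h * sat)
    }
  }
  list(animals = fA, plants = fP)
}

# fixed-step Euler integration of dN/dt = N f(N)
euler_integrate <- function(comm, t_end, dt = 1e-3) {
  for (s in seq_len(round(t_end / dt))) {
    f <- ref_growth(comm)
    comm$animals$densities <- comm$animals$densities * (1 + dt * f$animals)
    comm$plants$densities <- comm$plants$densities * (1 + dt * f$plants)
  }
  comm
}

# brute-force robustness: literal removal simulation on the 0/1 structure
ref_robustness <- function(Q) {
  n <- nrow(Q); m <- ncol(Q); tot <- n + m
  deg <- c(rowSums(Q), colSums(Q))
  ord <- order(deg, decreasing = TRUE)
  aliveA <- rep(TRUE, n); aliveP <- rep(TRUE, m)
  removed <- 0
  for (s in ord) {
    if (s <= n) { if (!aliveA[s]) next; aliveA[s] <- FALSE }
    else { if (!aliveP[s - n]) next; aliveP[s - n] <- FALSE }
    removed <- removed + 1
    repeat {
      changed <- FALSE
      for (i in which(aliveA))
        if (!any(Q[i, aliveP] > 0)) { aliveA[i] <- FALSE; changed <- TRUE }
      for (j in which(aliveP))
        if (!any(Q[aliveA, j] > 0)) { aliveP[j] <- FALSE; changed <- TRUE }
      if (!changed) break
    }
    if (tot - sum(aliveA) - sum(aliveP) > tot / 2) return(removed / tot)
  }
  removed / tot
}

# small random viable community near the resource optima
random_community <- function(seed, n = NULL, m = NULL) {
  set.seed(seed)
  if (is.null(n)) n <- sample(2:4, 1)
  if (is.null(m)) m <- sample(2:4, 1)
  p <- model_params(sigma_C = runif(1, 0.3, 1.2),
                    sigma_A = runif(1, 1, 2.5),
                    sigma_m = runif(1, 0.2, 1))
  community(guild_state(p$x_Amax + sort(runif(n, -1, 1)), runif(n, 20, 150)),
            guild_state(p$y_Pmax + sort(runif(m, -1, 1)), runif(m, 20, 150)),
            p)
}

# one assembled network, shared across test files (built once)
.fixture_env <- new.env()
fixture_network <- function() {
  if (is.null(.fixture_env$net)) {
    .fixture_env$net <- assemble_network(
      model_params(sigma_C = exp(-3), sigma_m = exp(-0.75),
                   sigma_A = exp(0.25)),
      target_events = 4)
  }
  .fixture_env$net
}
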