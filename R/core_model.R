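#' Gaussian competition kernel
#'
#' Competition between two morphs of the same guild decays with their trait
#' difference: `exp(-delta^2 / (2 sigma_C^2))`. Identical traits compete at
#' full strength 1; the kernel is symmetric in the sign of `delta`.
#'
#' @param delta trait difference (vectorized).
#' @param sigma_C competition kernel width (> 0).
#' @return competition weights in (0, 1].
#' @export
#' @examples
#' competition_kernel(0, 0.5)                    # 1
#' competition_kernel(0.5 * sqrt(2 * log(2)), 0.5)  # half-maximum
competition_kernel <- function(delta, sigma_C) {
  if (!is.numeric(sigma_C) || length(sigma_C) != 1L || sigma_C <= 0)
    stop("sigma_C must be a single positive number")
  exp(-delta^2 / (2 * sigma_C^2))
}

#' Trait-mediated carrying capacity
#'
#' The resource accessibility of a morph is a Gaussian function of its trait,
#' maximal at the guild's resource optimum (`x_Amax` for animals, `y_Pmax`
#' for plants). By default the Gaussian is unnormalized, so the maximum
#' equals the scale constant `k_A` (or `k_P`) exactly; with
#' `params$normalized_K = TRUE` the normalized Gaussian density is used
#' instead (maximum `k / (sigma * sqrt(2*pi))`).
#'
#' @param x trait value(s).
#' @param guild `"animal"` or `"plant"`.
#' @param params a [model_params()] object.
#' @return carrying capacities (density units).
#' @export
#' @examples
#' carrying_capacity(3, "animal", model_params())  # 400 at the optimum
carrying_capacity <- function(x, guild = c("animal", "plant"), params) {
  guild <- match.arg(guild)
  validate_params(params)
  if (guild == "animal") {
    k <- params$k_A; x0 <- params$x_Amax; s <- params$sigma_A
  } else {
    k <- params$k_P; x0 <- params$y_Pmax; s <- params$sigma_P
  }
  norm <- if (params$normalized_K) 1 / (s * sqrt(2 * pi)) else 1
  k * norm * exp(-(x - x0)^2 / (2 * s^2))
}

#' Mutualistic benefit between an animal and a plant
#'
#' Assortative interactions: matched traits yield the maximal benefit `c`,
#' decaying as a Gaussian of the trait difference with tolerance `sigma_m`.
#'
#' @param x animal trait(s).
#' @param y plant trait(s).
#' @param params a [model_params()] object.
#' @param sigma_m optional override of the tolerance (used for alien morphs
#'   carrying a private generalization level).
#' @return benefit rates in (0, c].
#' @export
mutualistic_benefit <- function(x, y, params, sigma_m = NULL) {
  if (is.null(sigma_m)) sigma_m <- params$sigma_m
  if (any(sigma_m <= 0)) stop("sigma_m must be positive")
  params$c * exp(-(x - y)^2 / (2 * sigma_m^2))
}

# benefit matrix with per-animal tolerances (n x m)
benefit_matrix <- function(comm) {
  xA <- comm$animals$traits; xP <- comm$plants$traits
  sm <- sigma_m_animals(comm)
  d2 <- outer(xA, xP, "-")^2
  comm$params$c * exp(-d2 / (2 * sm^2))  # sm recycles down columns = per row i
}

#' Adaptive interaction preferences
#'
#' The preference of animal `i` for plant `j` is its benefit relative to the
#' density-weighted mean benefit that plant `j` receives from all its animal
#' suitors: `w_AiPj = b_ij * sum_k(A_k) / sum_k(A_k b_kj)`; the plant-side
#' matrix mirrors the expression with plant densities. Preferences therefore
#' depend only on density ratios. Columns whose partner guild has zero total
#' density or zero total benefit get preference 0 (no feasible interaction).
#'
#' @param community a [community()] object.
#' @return list with `w_AP` (n x m) and `w_PA` (m x n) preference matrices.
#' @export
interaction_preference <- function(community) {
  comm <- as_community(community)
  n <- n_animals(comm); m <- n_plants(comm)
  b <- benefit_matrix(comm)
  A <- comm$animals$densities; P <- comm$plants$densities
  SA <- sum(A); SP <- sum(P)
  w_AP <- matrix(0, n, m); w_PA <- matrix(0, m, n)
  if (n && m) {
    denomA <- as.numeric(crossprod(b, A))  # per plant j
    denomP <- as.numeric(b %*% P)          # per animal i
    okA <- denomA > 0 & SA > 0
    okP <- denomP > 0 & SP > 0
    if (any(okA))
      w_AP[, okA] <- b[, okA, drop = FALSE] * SA /
        matrix(denomA[okA], n, sum(okA), byrow = TRUE)
    if (any(okP))
      w_PA[, okP] <- t(b[okP, , drop = FALSE]) * SP /
        matrix(denomP[okP], m, sum(okP), byrow = TRUE)
  }
  list(w_AP = w_AP, w_PA = w_PA)
}

#' Per-capita growth rates of all morphs
#'
#' Evaluates the right-hand side of the population dynamics: intrinsic
#' growth, trait-mediated logistic competition, and mutualistic gain through
#' a Holling type II functional response with adaptive preferences. Defined
#' for zero-density morphs as well, where it equals the invasion fitness of
#' a rare type in the environment set by the others.
#'
#' @param community a [community()] object.
#' @return list with numeric vectors `animals` (f_A) and `plants` (f_P).
#' @export
percapita_growth <- function(community) {
  comm <- as_community(community)
  r <- cpp_rates(comm$animals$densities, comm$plants$densities,
                 comm$animals$traits, comm$plants$traits,
                 sigma_m_animals(comm), unclass(comm$params))
  list(animals = r$fA, plants = r$fP)
}

#' Quantitative interaction-strength matrix
#'
#' The strength of the interaction between animal `i` and plant `j` is the
#' symmetrized nonlinear functional-response term: the mean of the number of
#' animal `i` individuals recruited from interacting with plant `j` and the
#' number of plant `j` individuals recruited from animal `i`, per time unit.
#' Entries below `params$q_threshold` (default 1e-8) are stored as exactly 0.
#' Intended for communities at (or near) ecological equilibrium.
#'
#' @param community a [community()] object.
#' @return an n x m matrix of class `mutnet_Q` with dimnames `A1..An`,
#'   `P1..Pm` following the community morph order.
#' @export
interaction_strength_matrix <- function(community) {
  comm <- as_community(community)
  Q <- cpp_interaction_matrix(comm$animals$densities, comm$plants$densities,
                              comm$animals$traits, comm$plants$traits,
                              sigma_m_animals(comm), unclass(comm$params),
                              comm$params$q_threshold)
  dimnames(Q) <- list(paste0("A", seq_len(nrow(Q))), paste0("P", seq_len(ncol(Q))))
  class(Q) <- c("mutnet_Q", class(Q))
  Q
}
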