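# Quantitative network-architecture metrics on the interaction-strength
# matrix: H2' specialization, weighted connectance, WNODF nestedness, and
# Barber-style weighted bipartite modularity.

# run code under a fixed seed without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", .GlobalEnv, inherits = FALSE)
  old <- if (had) get(".Random.seed", .GlobalEnv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, .GlobalEnv)
    else suppressWarnings(rm(".Random.seed", envir = .GlobalEnv))
  })
  set.seed(seed)
  force(code)
}

check_Q <- function(Q) {
  Q <- unclass(as.matrix(Q))
  if (!is.numeric(Q) || length(Q) == 0) stop("Q must be a non-empty numeric matrix")
  if (any(Q < 0)) stop("Q must be non-negative")
  if (sum(Q) <= 0) stop("Q has zero total interaction strength")
  Q
}

shannon <- function(p, base = exp(1)) {
  p <- p[p > 0]
  -sum(p * log(p, base = base))
}

# minimal marginal-preserving entropy by greedy largest-remaining-cell
# allocation with randomized tie-breaks
h2min_greedy <- function(r, c, n_restarts = 100) {
  best <- Inf
  for (rep in seq_len(n_restarts)) {
    rr <- r; cc <- c; H <- 0
    repeat {
      i_ok <- which(rr > 1e-15); j_ok <- which(cc > 1e-15)
      if (!length(i_ok) || !length(j_ok)) break
      alloc <- outer(rr[i_ok], cc[j_ok], pmin)
      amax <- max(alloc)
      cand <- which(alloc >= amax - 1e-15, arr.ind = TRUE)
      pick <- cand[sample.int(nrow(cand), 1L), ]
      i <- i_ok[pick[1]]; j <- j_ok[pick[2]]
      a <- min(rr[i], cc[j])
      H <- H - a * log(a)
      rr[i] <- rr[i] - a; cc[j] <- cc[j] - a
    }
    if (H < best) best <- H
  }
  best
}

#' Network-level specialization H2'
#'
#' Standardizes the Shannon entropy of the interaction-strength distribution
#' between the maximum (`H2max`, the entropy of the outer product of the
#' marginals, i.e. no specialization beyond abundance) and the minimum
#' (`H2min`, the least entropy achievable under the same marginals, found by
#' a seeded greedy largest-remaining-cell packing):
#' `H2' = (H2max - H2) / (H2max - H2min)`, clamped to `[0, 1]`. A 1x1 (or
#' otherwise contrast-free) matrix returns 0 by convention.
#'
#' @param Q non-negative interaction matrix with positive total.
#' @param n_restarts randomized tie-break restarts of the H2min packing.
#' @param seed seed for the tie-breaks.
#' @return H2' in `[0, 1]`.
#' @export
specialization_H2 <- function(Q, n_restarts = 100, seed = 1) {
  Q <- check_Q(Q)
  p <- Q / sum(Q)
  H2 <- shannon(p)
  H2max <- shannon(rowSums(p)) + shannon(colSums(p))
  H2min <- with_seed(seed, h2min_greedy(rowSums(p), colSums(p), n_restarts))
  if (H2max - H2min < 1e-12) return(0)
  min(1, max(0, (H2max - H2) / (H2max - H2min)))
}

#' Weighted (quantitative) connectance
#'
#' The quantitative linkage density -- the marginal-weighted mean of the
#' effective number of partners `2^H` (Shannon entropy, base 2) of each row
#' and column -- divided by the number of species:
#' `CON = LDq / (n + m)` with
#' `LDq = 1/2 * (sum_j C_j/F * 2^H(col j) + sum_i R_i/F * 2^H(row i))`.
#' Invariant to rescaling `Q` by a positive constant.
#'
#' @param Q non-negative interaction matrix with positive total.
#' @return weighted connectance.
#' @export
connectance_weighted <- function(Q) {
  Q <- check_Q(Q)
  FF <- sum(Q)
  R <- rowSums(Q); C <- colSums(Q)
  eff_rows <- vapply(seq_len(nrow(Q)), function(i)
    if (R[i] > 0) 2^shannon(Q[i, ] / R[i], base = 2) else 0, 0)
  eff_cols <- vapply(seq_len(ncol(Q)), function(j)
    if (C[j] > 0) 2^shannon(Q[, j] / C[j], base = 2) else 0, 0)
  LDq <- 0.5 * (sum(C / FF * eff_cols) + sum(R / FF * eff_rows))
  LDq / (nrow(Q) + ncol(Q))
}

#' Weighted nestedness (WNODF)
#'
#' Nestedness based on overlap and decreasing fill for quantitative
#' matrices. Rows (and, independently, columns) are sorted by decreasing
#' marginal totals (ties keep the original order); an ordered pair (u above
#' v) contributes only when u's marginal total *and* fill are strictly
#' greater than v's, scoring the percentage of v's filled cells whose value
#' is positive but strictly smaller than u's in the same position; all other
#' pairs score 0. WNODF is the mean over all row pairs and column pairs,
#' in `[0, 100]`.
#'
#' @param Q non-negative interaction matrix, at least 2 x 2.
#' @param tol strict-inequality tolerance on real-valued strengths.
#' @return WNODF in `[0, 100]`.
#' @export
wnodf <- function(Q, tol = 1e-12) {
  Q <- check_Q(Q)
  if (nrow(Q) < 2 || ncol(Q) < 2)
    stop("WNODF needs at least 2 rows and 2 columns")
  pair_scores <- function(M) {
    tot <- rowSums(M); fill <- rowSums(M > 0)
    M <- M[order(tot, decreasing = TRUE), , drop = FALSE]
    tot <- sort(tot, decreasing = TRUE)
    fill <- rowSums(M > 0)
    k <- nrow(M); sc <- numeric(0)
    for (u in seq_len(k - 1)) {
      for (v in (u + 1):k) {
        if (tot[u] > tot[v] + tol && fill[u] > fill[v] && fill[v] > 0) {
          idx <- M[v, ] > 0
          sc <- c(sc, 100 * sum(M[v, idx] < M[u, idx] - tol & M[u, idx] > 0) / sum(idx))
        } else sc <- c(sc, 0)
      }
    }
    sc
  }
  mean(c(pair_scores(Q), pair_scores(t(Q))))
}

#' Weighted bipartite modularity (Barber-style, simulated annealing)
#'
#' Maximizes `MOD = sum_ij (q_ij/F - R_i C_j / F^2) * delta(module_i,
#' module_j)` over joint module assignments of animals and plants, via
#' simulated annealing with geometric cooling (node moves and module
#' merges), best of `n_restarts` seeded restarts. Deterministic given the
#' seed.
#'
#' @param Q non-negative interaction matrix with positive total.
#' @param seed RNG seed for the annealing.
#' @param n_restarts independent restarts.
#' @param steps annealing steps per restart.
#' @param T0 initial temperature.
#' @param cooling geometric cooling ratio per step.
#' @return list with `M` (the modularity), `modules` (integer labels for
#'   animals and plants), and the `seed` used.
#' @export
modularity_weighted <- function(Q, seed = 1, n_restarts = 5, steps = 1e4,
                                T0 = 1, cooling = 0.995) {
  Q <- check_Q(Q)
  res <- with_seed(seed, cpp_modularity_sa(Q, as.integer(steps), T0, cooling,
                                           as.integer(n_restarts)))
  labs <- c(res$labels_animals, res$labels_plants)
  relab <- match(labs, unique(labs))
  n <- nrow(Q)
  list(M = res$M,
       modules = list(animals = relab[seq_len(n)], plants = relab[-seq_len(n)]),
       seed = seed)
}

#' All four architecture metrics of a network
#'
#' @param Q non-negative interaction matrix (see
#'   [interaction_strength_matrix()]).
#' @param seed seed for the stochastic searches (H2min packing, modularity
#'   annealing).
#' @param ... passed to [modularity_weighted()].
#' @return list with `SPE` (H2'), `CON`, `NEST` (WNODF), `MOD`, the module
#'   assignment, and the seed.
#' @export
architecture_metrics <- function(Q, seed = 1, ...) {
  mod <- modularity_weighted(Q, seed = seed, ...)
  list(SPE = specialization_H2(Q, seed = seed),
       CON = connectance_weighted(Q),
       NEST = wnodf(Q),
       MOD = mod$M, modules = mod$modules, seed = seed)
}
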