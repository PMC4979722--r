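#' Integrate the population dynamics
#'
#' Advances the community densities under `dN/dt = N f(N)` using an adaptive
#' Runge-Kutta (Dormand-Prince 5(4)) scheme on log-densities, which keeps
#' every density strictly positive without clipping. Morphs starting at zero
#' density stay at zero (absorbing) and are carried through unchanged.
#'
#' @param community a [community()] object.
#' @param t_span duration of model time to integrate (> 0).
#' @param record if `TRUE`, return a sampled time series as well.
#' @param record_dt sampling interval for the recorded trajectory.
#' @param rtol,atol integrator tolerances on log-densities.
#' @return if `record = FALSE`, the community with updated densities;
#'   otherwise a list with `community` and `trajectory`, the latter a long
#'   data frame (time, morph_id, guild, density).
#' @export
integrate_dynamics <- function(community, t_span, record = FALSE,
                               record_dt = 1, rtol = 1e-8, atol = 1e-10) {
  comm <- as_community(community)
  if (!is.numeric(t_span) || t_span <= 0) stop("t_span must be > 0")
  A <- comm$animals$densities; P <- comm$plants$densities
  posA <- A > 0; posP <- P > 0
  if (!any(posA) && !any(posP)) {  # all-zero: absorbing state
    if (!record) return(comm)
    return(list(community = comm, trajectory = trajectory_frame(comm, 0)))
  }
  rts <- if (record) seq(0, t_span, by = record_dt) else NULL
  res <- cpp_integrate(A[posA], P[posP],
                       comm$animals$traits[posA], comm$plants$traits[posP],
                       sigma_m_animals(comm)[posA], unclass(comm$params),
                       0, t_span, rtol, atol, FALSE, 0, rts)
  if (res$status == 2)
    stop("integration failure (step-size collapse) at t = ", signif(res$t, 6),
         "; last valid state retained in the error condition",
         call. = FALSE)
  out <- comm
  out$animals$densities[posA] <- res$A
  out$plants$densities[posP] <- res$P
  if (!record) return(out)
  rec <- res$record  # rows: times, cols: positive morphs (animals then plants)
  nA <- sum(posA)
  traj <- do.call(rbind, lapply(seq_along(res$record_t), function(s) {
    tcomm <- comm
    tcomm$animals$densities[posA] <- rec[s, seq_len(nA)]
    tcomm$plants$densities[posP] <- rec[s, nA + seq_len(sum(posP))]
    trajectory_frame(tcomm, res$record_t[[s]])
  }))
  list(community = out, trajectory = traj)
}

trajectory_frame <- function(comm, time) {
  data.frame(
    time = time,
    morph_id = c(comm$animals$ids, comm$plants$ids),
    guild = rep(c("animal", "plant"),
                c(n_animals(comm), n_plants(comm))),
    density = c(comm$animals$densities, comm$plants$densities))
}

#' Find the ecological equilibrium of a community
#'
#' Integrates the population dynamics until the relative rate test
#' `max_i |dN_i/dt| < tol * max(N_i, 1)` is satisfied (with a damped Newton
#' polish once the residual is small) or `t_max` model time is spent. Morphs
#' falling below the extinction threshold are pruned en route.
#'
#' @param community a [community()] object.
#' @param tol equilibrium tolerance of the relative rate test.
#' @param t_max maximal model time to spend.
#' @param use_newton enable the Newton polish (recommended).
#' @return an object of class `mutnet_equilibrium`: list with `community`
#'   (equilibrium densities, extinct morphs removed), `converged`,
#'   `residual`, and `time_integrated`.
#' @export
#' @examples
#' p <- model_params(c = 0)
#' eq <- find_equilibrium(community(guild_state(3, 10), guild_state(2, 10), p))
#' eq$community$animals$densities  # = K_A(3) = 400
find_equilibrium <- function(community, tol = 1e-9, t_max = 1e5,
                             use_newton = TRUE) {
  comm <- as_community(community)
  if (tol <= 0) stop("tol must be > 0")
  comm <- prune_extinct(comm)
  t_used <- 0
  repeat {
    A <- comm$animals$densities; P <- comm$plants$densities
    if (length(A) + length(P) == 0) {
      return(structure(list(community = comm, converged = TRUE, residual = 0,
                            time_integrated = t_used),
                       class = "mutnet_equilibrium"))
    }
    posA <- A > 0; posP <- P > 0
    res <- cpp_find_eq(A[posA], P[posP],
                       comm$animals$traits[posA], comm$plants$traits[posP],
                       sigma_m_animals(comm)[posA], unclass(comm$params),
                       tol, t_max - t_used, 1e-8, 1e-10, use_newton)
    comm$animals$densities[posA] <- res$A
    comm$plants$densities[posP] <- res$P
    t_used <- t_used + res$t
    pruned <- prune_extinct(comm)
    if (n_animals(pruned) != n_animals(comm) || n_plants(pruned) != n_plants(comm)) {
      comm <- pruned
      if (res$converged) next  # re-solve without the extinct morphs
    } else comm <- pruned
    if (res$converged || t_used >= t_max) {
      return(structure(list(community = comm,
                            converged = isTRUE(res$converged),
                            residual = res$residual,
                            time_integrated = t_used),
                       class = "mutnet_equilibrium"))
    }
  }
}

#' @export
print.mutnet_equilibrium <- function(x, ...) {
  cat(sprintf("Equilibrium (converged: %s, residual: %.3g, t = %.4g)\n",
              x$converged, x$residual, x$time_integrated))
  print(x$community)
  invisible(x)
}

#' Remove extinct morphs
#'
#' Drops every morph whose density is below the extinction threshold
#' (default 1e-8), remapping indices. If the alien falls below the threshold
#' its marker is cleared and the community is flagged with
#' `attr(, "failed_invasion")`.
#'
#' @param community a [community()] object.
#' @return the pruned community.
#' @export
prune_extinct <- function(community) {
  comm <- as_community(community)
  thr <- comm$params$extinction_threshold
  keepA <- comm$animals$densities >= thr
  keepP <- comm$plants$densities >= thr
  if (all(keepA) && all(keepP)) return(comm)
  failed <- FALSE
  if (!is.na(comm$alien_index)) {
    if (!keepA[comm$alien_index]) {
      comm$alien_index <- NA_integer_
      comm$alien_sigma_m <- NA_real_
      failed <- TRUE
    } else {
      comm$alien_index <- sum(keepA[seq_len(comm$alien_index)])
    }
  }
  comm$animals <- lapply(comm$animals, `[`, keepA)
  comm$plants <- lapply(comm$plants, `[`, keepP)
  if (failed) attr(comm, "failed_invasion") <- TRUE
  comm
}

#' Community Jacobian at the current densities
#'
#' Central finite differences of the full right-hand side `N_k f_k` with
#' respect to each density `N_l` (step `max(1e-6, 1e-6 * N_l)`), with the
#' adaptive preference matrices recomputed inside every perturbation since
#' they depend on densities. Rows/columns are ordered animals then plants.
#'
#' @param community a [community()] object with strictly positive densities.
#' @return an (n+m) x (n+m) matrix.
#' @export
jacobian <- function(community) {
  comm <- as_community(community)
  if (any(c(comm$animals$densities, comm$plants$densities) <= 0))
    stop("jacobian requires strictly positive densities")
  cpp_jacobian(comm$animals$densities, comm$plants$densities,
               comm$animals$traits, comm$plants$traits,
               sigma_m_animals(comm), unclass(comm$params))
}

#' Is the community asymptotically stable?
#'
#' `TRUE` iff every eigenvalue of the community Jacobian has negative real
#' part. Meaningful at an ecological equilibrium.
#'
#' @param community a [community()] object at equilibrium.
#' @return logical flag.
#' @export
is_asymptotically_stable <- function(community) {
  ev <- eigen(jacobian(community), only.values = TRUE)$values
  max(Re(ev)) < 0
}
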