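# Trait evolution by the canonical equation of adaptive dynamics:
# singularity search, branching conditions, branching mechanics, and the
# parameter-sweep ensemble generator that produces native recipient networks.

# Batched invasion fitness of rare mutants: zero-density morphs do not feed
# back on anyone (preferences weigh densities), so evaluating many candidate
# mutants in one rates call equals one-at-a-time evaluation.
mutant_fitness <- function(comm, guild, traits, sigma_m = NULL) {
  nt <- length(traits)
  if (nt == 0) return(numeric(0))
  if (guild == "animal") {
    sm_new <- if (is.null(sigma_m)) rep(comm$params$sigma_m, nt) else rep(sigma_m, nt)
    r <- cpp_rates(c(comm$animals$densities, rep(0, nt)),
                   comm$plants$densities,
                   c(comm$animals$traits, traits),
                   comm$plants$traits,
                   c(sigma_m_animals(comm), sm_new),
                   unclass(comm$params))
    r$fA[n_animals(comm) + seq_len(nt)]
  } else {
    r <- cpp_rates(comm$animals$densities,
                   c(comm$plants$densities, rep(0, nt)),
                   comm$animals$traits,
                   c(comm$plants$traits, traits),
                   sigma_m_animals(comm),
                   unclass(comm$params))
    r$fP[n_plants(comm) + seq_len(nt)]
  }
}

residual_of <- function(comm) {
  f <- percapita_growth(comm)
  N <- c(comm$animals$densities, comm$plants$densities)
  if (!length(N)) return(0)
  max(abs(N * c(f$animals, f$plants)) / pmax(N, 1))
}

#' Invasion fitness of a rare mutant
#'
#' Per-capita growth rate of a zero-density mutant with the given trait in
#' the environment set by the resident community at its ecological
#' equilibrium (preferences are recomputed with the mutant present at
#' density zero). A clone of a resident has fitness zero up to the
#' equilibrium tolerance.
#'
#' @param community a [community()] or [find_equilibrium()] result at
#'   ecological equilibrium.
#' @param guild `"animal"` or `"plant"`.
#' @param mutant_trait trait value(s) of the rare mutant.
#' @param check verify the equilibrium contract (residual < 1e-6).
#' @return invasion fitness, one value per mutant trait.
#' @export
invasion_fitness <- function(community, guild = c("animal", "plant"),
                             mutant_trait, check = TRUE) {
  guild <- match.arg(guild)
  comm <- as_community(community)
  if (check && residual_of(comm) > 1e-6)
    stop("community is not at ecological equilibrium (residual > 1e-6); ",
         "run find_equilibrium() first")
  mutant_fitness(comm, guild, mutant_trait)
}

#' Selection gradients of all resident morphs
#'
#' Central-difference derivative of the invasion fitness with respect to the
#' mutant trait, evaluated at each resident trait.
#'
#' @param community a community at ecological equilibrium.
#' @param step finite-difference step on the trait axis.
#' @return list with numeric vectors `animals` and `plants`.
#' @export
selection_gradient <- function(community, step = 1e-6) {
  comm <- as_community(community)
  grad1 <- function(guild, x) {
    k <- length(x)
    if (!k) return(numeric(0))
    f <- mutant_fitness(comm, guild, c(x + step, x - step))
    (f[seq_len(k)] - f[k + seq_len(k)]) / (2 * step)
  }
  list(animals = grad1("animal", comm$animals$traits),
       plants = grad1("plant", comm$plants$traits))
}

# Merge same-guild morphs whose traits have collapsed onto each other
# (within tol): sum densities, keep the denser morph's id and a
# density-weighted mean trait. Degenerate near-clones are dynamically
# neutral, so merging preserves the dynamics while keeping the morph list
# well-separated.
merge_close_morphs <- function(comm, tol = 1e-3) {
  merge_guild <- function(g) {
    k <- length(g$traits)
    if (k < 2) return(g)
    o <- order(g$traits)
    tr <- g$traits[o]; de <- g$densities[o]; id <- g$ids[o]
    i <- 1
    while (i < length(tr)) {
      if (tr[i + 1] - tr[i] < tol) {
        wsum <- de[i] + de[i + 1]
        tr[i] <- if (wsum > 0) (tr[i] * de[i] + tr[i + 1] * de[i + 1]) / wsum else tr[i]
        id[i] <- if (de[i + 1] > de[i]) id[i + 1] else id[i]
        de[i] <- wsum
        tr <- tr[-(i + 1)]; de <- de[-(i + 1)]; id <- id[-(i + 1)]
      } else i <- i + 1
    }
    list(traits = tr, densities = de, ids = id)
  }
  comm$animals <- merge_guild(comm$animals)
  comm$plants <- merge_guild(comm$plants)
  comm
}

# stacked canonical rates m*N*g and gradients for all morphs
stacked_rate <- function(comm) {
  g <- selection_gradient(comm)
  list(g = g,
       rate = c(comm$params$m_A * comm$animals$densities * g$animals,
                comm$params$m_P * comm$plants$densities * g$plants))
}

set_traits <- function(comm, x) {
  nA <- n_animals(comm)
  comm$animals$traits <- x[seq_len(nA)]
  comm$plants$traits <- x[nA + seq_len(n_plants(comm))]
  comm
}

# Damped Newton on the stacked selection gradient g(x) = 0, with ecological
# re-equilibration inside every evaluation. Used to finish the approach to a
# singularity once the canonical flow is close (the trait dynamics become
# stiff after branching: fast pair-splitting modes coexist with a
# near-neutral drift of the whole trait pattern).
trait_newton <- function(comm, grad_tol, eq_tol, max_iter = 12, fd_step = 1e-5,
                         dx_cap = 0.1) {
  nA <- n_animals(comm); nP <- n_plants(comm); d <- nA + nP
  eval_at <- function(cm, x) {
    eq <- find_equilibrium(set_traits(cm, x), tol = eq_tol)
    if (!eq$converged || n_animals(eq$community) != nA ||
        n_plants(eq$community) != nP) return(NULL)
    c(list(comm = eq$community), stacked_rate(eq$community))
  }
  x0 <- c(comm$animals$traits, comm$plants$traits)
  # a Newton jump must not collapse freshly diverged pairs or reorder traits
  sane <- function(xn) {
    a <- xn[seq_len(nA)]; p <- xn[nA + seq_len(nP)]
    a0 <- x0[seq_len(nA)]; p0 <- x0[nA + seq_len(nP)]
    chk <- function(v, v0) {
      if (length(v) < 2) return(TRUE)
      o <- order(v0)
      gaps <- diff(v[o]); gaps0 <- diff(v0[o])
      all(gaps[gaps0 > 2e-3] > 1e-3) && !is.unsorted(v[o])
    }
    chk(a, a0) && chk(p, p0)
  }
  x <- x0
  cur <- eval_at(comm, x)
  if (is.null(cur)) return(NULL)
  g0 <- max(abs(c(cur$g$animals, cur$g$plants)))
  for (it in seq_len(max_iter)) {
    gs <- c(cur$g$animals, cur$g$plants)
    if (max(abs(cur$rate)) < grad_tol) return(cur$comm)
    # fail fast: a converging Newton halves |g| within a few iterations
    if (it == 4 && max(abs(gs)) > 0.5 * g0) return(NULL)
    J <- matrix(NA_real_, d, d)
    for (l in seq_len(d)) {
      xp <- x; xp[l] <- xp[l] + fd_step
      pert <- eval_at(cur$comm, xp)
      if (is.null(pert)) return(NULL)
      J[, l] <- (c(pert$g$animals, pert$g$plants) - gs) / fd_step
    }
    dx <- tryCatch(solve(J, -gs), error = function(e) NULL)
    if (is.null(dx) || !all(is.finite(dx))) return(NULL)
    if (max(abs(dx)) > dx_cap) dx <- dx * dx_cap / max(abs(dx))
    ok <- FALSE
    for (half in 1:6) {  # line search on |g|
      if (!sane(x + dx)) { dx <- dx / 2; next }
      cand <- eval_at(cur$comm, x + dx)
      if (!is.null(cand) &&
          max(abs(c(cand$g$animals, cand$g$plants))) < max(abs(gs))) {
        x <- x + dx; cur <- cand; ok <- TRUE; break
      }
      dx <- dx / 2
    }
    if (!ok) return(NULL)
  }
  if (max(abs(cur$rate)) < grad_tol && sane(x)) cur$comm else NULL
}

#' Evolve a community to an evolutionary singularity
#'
#' Alternates ecological equilibration with Euler steps of the canonical
#' equation `dx_i/dt = m * N_i * g_i` until directional selection ceases
#' (`max |m N g| < grad_tol` per unit time). The trait time step adapts: it
#' is capped so no trait moves more than `dx_max` per step, grows
#' geometrically while progress is smooth, and backs off on overshoot
#' (gradient reversal with growing magnitude). Morphs that collapse onto
#' each other are merged; extinct morphs are pruned at every equilibrium.
#'
#' @param community a viable [community()] object.
#' @param grad_tol singularity tolerance on `max |m N g|`.
#' @param max_steps maximal number of trait steps.
#' @param dx_max maximal trait displacement per step.
#' @param eq_tol ecological equilibrium tolerance.
#' @param grad_tol_soft fallback tolerance: large communities with a weak
#'   competition kernel carry a quasi-neutral drift mode of the whole trait
#'   pattern whose restoring force is orders of magnitude below `grad_tol`;
#'   when the flow has slowed below this level and the Newton finisher
#'   cannot improve it, directional selection is treated as ceased (the
#'   result carries `soft = TRUE`).
#' @param record keep the trait trajectory (time, morph_id, guild, trait).
#' @return an object of class `mutnet_singularity`: the community at the
#'   singular traits and equilibrium densities, the selection gradients,
#'   convergence flag, steps and model time used, and the trajectory.
#' @export
evolve_to_singularity <- function(community, grad_tol = 1e-7,
                                  max_steps = 2000, dx_max = 0.02,
                                  eq_tol = 1e-9, grad_tol_soft = 1e-3,
                                  record = TRUE) {
  comm <- as_community(community)
  eq <- find_equilibrium(comm, tol = eq_tol)
  if (!eq$converged || n_animals(eq$community) == 0 ||
      n_plants(eq$community) == 0)
    return(structure(list(community = eq$community, converged = FALSE,
                          steps = 0L, time = 0, trajectory = NULL),
                     class = "mutnet_singularity"))
  comm <- merge_close_morphs(eq$community)

  traj <- if (record) vector("list", 64) else NULL
  tlen <- 0L
  push <- function(time, cm) {
    tlen <<- tlen + 1L
    if (tlen > length(traj)) traj[[2 * tlen]] <<- NULL
    traj[[tlen]] <<- data.frame(
      time = time,
      morph_id = c(cm$animals$ids, cm$plants$ids),
      guild = rep(c("animal", "plant"), c(n_animals(cm), n_plants(cm))),
      trait = c(cm$animals$traits, cm$plants$traits))
  }

  rate_of <- function(cm, g) {
    c(cm$params$m_A * cm$animals$densities * g$animals,
      cm$params$m_P * cm$plants$densities * g$plants)
  }

  g <- selection_gradient(comm)
  rate <- rate_of(comm, g)
  time <- 0; dt_prev <- NULL; steps <- 0L; converged <- FALSE
  newton_gate <- Inf  # retry Newton only after the rate has halved again
  rate_peak <- max(abs(rate), 0)
  steps_since <- 0L  # steps since the last structural change
  soft <- FALSE
  check_rate <- Inf  # stall bailout: require 20% progress per 500 steps
  if (record) push(time, comm)

  while (steps < max_steps) {
    rmax <- max(abs(rate), 0)
    if (rmax < grad_tol) { converged <- TRUE; break }
    if (steps > 0 && steps %% 500L == 0L) {
      if (rmax > 0.8 * check_rate) break  # crawling without progress
      check_rate <- rmax
    }
    rate_peak <- max(rate_peak, rmax)
    # once the canonical flow is past its divergence peak and decelerating,
    # finish with Newton on g(x) = 0 (the post-branching trait dynamics are
    # stiff and the explicit flow crawls)
    if (steps_since >= 30 && rmax < newton_gate &&
        (rmax < rate_peak / 2 || steps_since %% 300 == 0)) {
      polished <- trait_newton(comm, grad_tol, eq_tol)
      newton_gate <- rmax / 2
      if (!is.null(polished)) {
        comm <- polished
        g <- selection_gradient(comm)
        rate <- rate_of(comm, g)
        converged <- TRUE
        if (record) push(time, comm)
        break
      }
      if (rmax < grad_tol_soft &&
          max(abs(c(g$animals, g$plants))) < 0.1) {
        # flat quasi-neutral basin: the morph pattern is converged and only
        # its slow centering drift remains; accept as singular
        converged <- TRUE; soft <- TRUE
        break
      }
    }
    kstar <- which.max(abs(rate))
    dt_prop <- dx_max / rmax
    dt <- if (is.null(dt_prev)) min(dt_prop, 1 / rmax * dx_max) else min(2 * dt_prev, dt_prop)
    accepted <- FALSE
    for (try in 1:8) {
      cand <- comm
      nA <- n_animals(comm)
      dx <- rate * dt
      cand$animals$traits <- cand$animals$traits + dx[seq_len(nA)]
      cand$plants$traits <- cand$plants$traits + dx[nA + seq_len(n_plants(comm))]
      eq <- find_equilibrium(cand, tol = eq_tol)
      if (!eq$converged) { dt <- dt / 4; next }
      if (n_animals(eq$community) == 0 || n_plants(eq$community) == 0) {
        # a guild died out: the parameter combination is not viable
        return(structure(list(community = eq$community, converged = FALSE,
                              steps = steps, time = time, trajectory = NULL),
                         class = "mutnet_singularity"))
      }
      cand <- merge_close_morphs(eq$community)
      changed <- (n_animals(cand) != n_animals(comm)) ||
                 (n_plants(cand) != n_plants(comm))
      g2 <- selection_gradient(cand)
      rate2 <- rate_of(cand, g2)
      if (!changed) {
        overshoot <- max(abs(rate2)) > rmax &&
          sign(rate2[kstar]) != sign(rate[kstar]) && rate[kstar] != 0
        if (overshoot && dt > 1e-8 / max(rmax, 1e-12)) { dt <- dt / 4; next }
      }
      comm <- cand; g <- g2; rate <- rate2
      time <- time + dt
      dt_prev <- if (changed) NULL else dt
      if (changed) {
        steps_since <- 0L; rate_peak <- 0; newton_gate <- Inf
        check_rate <- Inf
      } else steps_since <- steps_since + 1L
      accepted <- TRUE
      break
    }
    steps <- steps + 1L
    if (!accepted) break
    if (record) push(time, comm)
  }

  if (!converged && max(abs(rate), 0) < grad_tol_soft &&
      max(abs(c(g$animals, g$plants))) < 0.1) {
    converged <- TRUE; soft <- TRUE  # steps exhausted inside the flat basin
  }
  structure(list(community = comm, gradients = g, converged = converged,
                 soft = soft, steps = steps, time = time,
                 trajectory = if (record) do.call(rbind, traj[seq_len(tlen)]) else NULL),
            class = "mutnet_singularity")
}

#' @export
print.mutnet_singularity <- function(x, ...) {
  cat(sprintf("Evolutionary singularity (converged: %s, %d trait steps, t = %.4g)\n",
              x$converged, x$steps, x$time))
  print(x$community)
  invisible(x)
}

#' Evolutionary branching conditions at a singularity
#'
#' For each morph at a singular trait, tests the three branching conditions
#' by central finite differences: convergence stability (the per-morph
#' diagonal derivative of the selection gradient with respect to the
#' resident trait, with ecological re-equilibration inside the
#' perturbation, is negative), disruptive selection (the invasion-fitness
#' curvature in the mutant trait is positive), and mutual invasibility
#' (the sum of resident- and mutant-trait curvatures is positive).
#'
#' @param singularity a [evolve_to_singularity()] result (or a community at
#'   a singularity).
#' @param d2_step finite-difference step for the second derivatives.
#' @param eq_tol ecological equilibrium tolerance for the re-equilibrated
#'   resident perturbations.
#' @return data frame with one row per morph: `guild`, `index`, `id`,
#'   `trait`, `convergent`, `disruptive`, `coexisting`, and the two
#'   curvatures `curv_mutant`, `curv_resident`.
#' @export
branching_conditions <- function(singularity, d2_step = 1e-4, eq_tol = 1e-9) {
  comm <- as_community(if (inherits(singularity, "mutnet_singularity"))
    singularity$community else singularity)
  rows <- list()
  for (guild in c("animal", "plant")) {
    gs <- if (guild == "animal") comm$animals else comm$plants
    k <- length(gs$traits)
    if (!k) next
    f0 <- mutant_fitness(comm, guild, gs$traits)
    fp <- mutant_fitness(comm, guild, gs$traits + d2_step)
    fm <- mutant_fitness(comm, guild, gs$traits - d2_step)
    curv_mut <- (fp - 2 * f0 + fm) / d2_step^2
    for (i in seq_len(k)) {
      pert <- function(delta) {
        cm <- comm
        if (guild == "animal") cm$animals$traits[i] <- cm$animals$traits[i] + delta
        else cm$plants$traits[i] <- cm$plants$traits[i] + delta
        eq <- find_equilibrium(cm, tol = eq_tol)
        eq$community
      }
      cp <- pert(d2_step); cm_ <- pert(-d2_step)
      gp <- selection_gradient(cp); gm <- selection_gradient(cm_)
      gi <- function(g, cmx) {
        v <- if (guild == "animal") g$animals else g$plants
        idx <- if (guild == "animal") match(gs$ids[i], cmx$animals$ids)
               else match(gs$ids[i], cmx$plants$ids)
        if (is.na(idx)) NA_real_ else v[idx]
      }
      dgdx <- (gi(gp, cp) - gi(gm, cm_)) / (2 * d2_step)
      # resident-trait curvature of the mutant's fitness at the singular trait
      frp <- mutant_fitness(cp, guild, gs$traits[i])
      frm <- mutant_fitness(cm_, guild, gs$traits[i])
      curv_res <- (frp - 2 * f0[i] + frm) / d2_step^2
      rows[[length(rows) + 1L]] <- data.frame(
        guild = guild, index = i, id = gs$ids[i], trait = gs$traits[i],
        convergent = is.finite(dgdx) && dgdx < 0,
        disruptive = curv_mut[i] > 0,
        coexisting = curv_res + curv_mut[i] > 0,
        curv_mutant = curv_mut[i], curv_resident = curv_res)
    }
  }
  do.call(rbind, rows)
}

#' Split morphs at a branching point
#'
#' Each branching morph spawns a daughter at `trait + 0.01` holding 10% of
#' the parent density while the parent keeps 90%; total density is conserved
#' at the instant of branching.
#'
#' @param community the community at the singularity.
#' @param morphs data frame with columns `guild` and `index` selecting the
#'   morphs to split (e.g. the qualifying rows of
#'   [branching_conditions()]), or `NULL` for none.
#' @param offset daughter trait offset.
#' @return the community with daughters appended (per guild, in order).
#' @export
apply_branching <- function(community, morphs, offset = 0.01) {
  comm <- as_community(community)
  if (is.null(morphs) || nrow(morphs) == 0) return(comm)
  next_id <- max(c(0L, comm$animals$ids, comm$plants$ids)) + 1L
  for (guild in c("animal", "plant")) {
    idx <- morphs$index[morphs$guild == guild]
    if (!length(idx)) next
    gs <- if (guild == "animal") comm$animals else comm$plants
    for (i in idx) {
      gs$traits <- c(gs$traits, gs$traits[i] + offset)
      gs$densities <- c(gs$densities, 0.1 * gs$densities[i])
      gs$ids <- c(gs$ids, next_id)
      next_id <- next_id + 1L
      gs$densities[i] <- 0.9 * gs$densities[i]
    }
    if (guild == "animal") comm$animals <- gs else comm$plants <- gs
  }
  comm
}

#' Assemble a native mutualistic network by repeated evolutionary branching
#'
#' Starts from a monomorphic pair (one animal, one plant, slightly below
#' their resource optima at half carrying capacity), evolves to the
#' evolutionary singularity, splits every morph that satisfies all three
#' branching conditions, and repeats. One *event* is a round in which at
#' least one morph splits and the extra morph survives to the next
#' singularity. Assembly stops after `target_events` events or when no
#' morph qualifies; the returned community is at a singularity and at
#' ecological equilibrium.
#'
#' @param params a [model_params()] object.
#' @param target_events number of branching events (4, 5, 6 for the small,
#'   medium, large size classes; any positive count is accepted).
#' @param seed stored for provenance (assembly itself is deterministic).
#' @param grad_tol,max_steps,dx_max,eq_tol passed to
#'   [evolve_to_singularity()].
#' @param record keep trait trajectories.
#' @return an object of class `mutnet_assembly`: final `community`,
#'   `n_events`, per-event bookkeeping in `events`, the `trajectory`,
#'   `params`, `seed`, and flags `converged` (all singularity searches
#'   converged) and `monomorphic` (no branching at all).
#' @export
assemble_network <- function(params = model_params(), target_events = 4,
                             seed = NULL, grad_tol = 1e-7, max_steps = 2000,
                             dx_max = 0.02, eq_tol = 1e-9, record = TRUE) {
  stopifnot(target_events >= 1)
  comm <- community(
    guild_state(params$x_Amax - 0.5,
                carrying_capacity(params$x_Amax - 0.5, "animal", params) / 2),
    guild_state(params$y_Pmax - 0.5,
                carrying_capacity(params$y_Pmax - 0.5, "plant", params) / 2),
    params)
  comm$plants$ids <- 2L  # unique ids across guilds for trajectory plotting

  events <- list(); trajs <- list(); t_off <- 0; n_events <- 0L
  sing <- evolve_to_singularity(comm, grad_tol, max_steps, dx_max, eq_tol,
                                record = record)
  if (record && !is.null(sing$trajectory)) {
    tr <- sing$trajectory; tr$time <- tr$time + t_off; trajs[[1]] <- tr
  }
  t_off <- t_off + sing$time
  fail <- function(reason) {
    structure(list(community = sing$community, n_events = n_events,
                   events = events, trajectory = bind_traj(trajs),
                   params = params, seed = seed, target_events = target_events,
                   converged = FALSE, monomorphic = n_events == 0L,
                   stop_reason = reason),
              class = "mutnet_assembly")
  }
  if (!sing$converged) return(fail("no_singularity"))

  while (n_events < target_events) {
    bc <- branching_conditions(sing, eq_tol = eq_tol)
    q <- bc[bc$convergent & bc$disruptive & bc$coexisting, , drop = FALSE]
    if (nrow(q) == 0) break
    pre_total <- n_animals(sing$community) + n_plants(sing$community)
    branched <- apply_branching(sing$community, q)
    sing2 <- evolve_to_singularity(branched, grad_tol, max_steps, dx_max,
                                   eq_tol, record = record)
    if (!sing2$converged) {
      # the post-split flow stalled; fall back to the last good singularity,
      # which is a complete, valid assembly of the events reached so far
      stopped <- "singularity_stall"
      break
    }
    if (record && !is.null(sing2$trajectory)) {
      tr <- sing2$trajectory; tr$time <- tr$time + t_off
      trajs[[length(trajs) + 1L]] <- tr
    }
    t_off <- t_off + sing2$time
    post_total <- n_animals(sing2$community) + n_plants(sing2$community)
    sing <- sing2
    if (post_total > pre_total) {
      n_events <- n_events + 1L
      events[[n_events]] <- data.frame(
        round = n_events, guild = q$guild, parent_id = q$id,
        parent_trait = q$trait, daughter_trait = q$trait + 0.01,
        time = t_off)
    } else { stopped <- "no_branching"; break }
  }
  if (!exists("stopped", inherits = FALSE))
    stopped <- if (n_events == target_events) "target_reached" else "no_branching"

  structure(list(community = sing$community, gradients = sing$gradients,
                 n_events = n_events, events = events,
                 trajectory = bind_traj(trajs), params = params, seed = seed,
                 target_events = target_events, converged = TRUE,
                 monomorphic = n_events == 0L, stop_reason = stopped),
            class = "mutnet_assembly")
}

bind_traj <- function(trajs) {
  if (!length(trajs)) return(NULL)
  do.call(rbind, trajs)
}

#' @export
print.mutnet_assembly <- function(x, ...) {
  cat(sprintf("Assembled network: %d branching events (target %d), %s\n",
              x$n_events, x$target_events, x$stop_reason))
  print(x$community)
  invisible(x)
}

#' Generate an ensemble of native networks across the kernel sweep
#'
#' Samples combinations of the three kernel widths (`sigma_C`, `sigma_m`,
#' `sigma_A = sigma_P`) from the multiplicative ladder `e^-3 ... e` (step
#' `e^0.25`, 17 values) in a seeded random order, assembles a network for
#' each, and keeps polymorphic, converged runs until the requested quota of
#' each size class is reached. Size classes map to branching events: small =
#' 4, medium = 5, large = 6. Runs ending monomorphic, non-converged, or
#' with fewer than 2 morphs in either guild (no bipartite network) are
#' discarded; a run stopping short of its target but exactly matching a
#' smaller unfilled class is kept for that class.
#'
#' @param sizes named integer vector, e.g. `c(small = 10, medium = 5)`.
#' @param sweep the kernel-width ladder.
#' @param seed RNG seed for the sampling order.
#' @param params_base parameter set whose non-kernel entries are kept.
#' @param max_attempts cap on assembly attempts.
#' @param verbose print progress.
#' @param ... passed to [assemble_network()].
#' @return list of `mutnet_assembly` logs (class `mutnet_ensemble`), each
#'   with a `size_class` element.
#' @export
generate_ensemble <- function(sizes = c(small = 10),
                              sweep = exp(seq(-3, 1, by = 0.25)),
                              seed = 1, params_base = model_params(),
                              max_attempts = 2000, verbose = FALSE, ...) {
  ev_map <- c(small = 4L, medium = 5L, large = 6L)
  stopifnot(all(names(sizes) %in% names(ev_map)), all(sizes >= 0))
  quota <- sizes
  set.seed(seed)
  combos <- expand.grid(sigma_C = sweep, sigma_m = sweep, sigma_A = sweep)
  combos <- combos[sample(nrow(combos)), , drop = FALSE]
  logs <- list(); attempt <- 0L
  for (r in seq_len(nrow(combos))) {
    if (all(quota == 0)) break
    attempt <- attempt + 1L
    if (attempt > max_attempts) break
    target <- max(ev_map[names(quota)[quota > 0]])
    p <- params_base
    p$sigma_C <- combos$sigma_C[r]
    p$sigma_m <- combos$sigma_m[r]
    p$sigma_A <- combos$sigma_A[r]
    p$sigma_P <- combos$sigma_A[r]
    log <- assemble_network(p, target_events = target, seed = seed, ...)
    if (!log$converged || log$monomorphic) next
    if (n_animals(log$community) < 2 || n_plants(log$community) < 2) next
    cls <- names(ev_map)[match(log$n_events, ev_map)]
    if (is.na(cls) || !cls %in% names(quota) || quota[cls] == 0) next
    log$size_class <- cls
    logs[[length(logs) + 1L]] <- log
    quota[cls] <- quota[cls] - 1L
    if (verbose)
      message(sprintf("[%d] %s network (events=%d) sC=%.3f sm=%.3f sA=%.3f; remaining: %s",
                      length(logs), cls, log$n_events, p$sigma_C, p$sigma_m,
                      p$sigma_A, paste(names(quota), quota, collapse = " ")))
  }
  if (!length(logs))
    stop("ensemble generation yielded no polymorphic networks; ",
         "widen the sweep or raise max_attempts")
  structure(logs, class = "mutnet_ensemble")
}
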