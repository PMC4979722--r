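# Stability metrics (resilience, robustness, disruptiveness), the
# invasion-trial engine (alien introduction schedules, invasiveness and
# impact), and network invasibility.

#' Network resilience
#'
#' `RES = ln |lambda|` where `lambda` is the dominant eigenvalue of the
#' community Jacobian at the (preinvasion) equilibrium. "Dominant" defaults
#' to the eigenvalue with the largest real part (rate-of-return reading);
#' `dominant = "modulus"` selects the largest-modulus eigenvalue instead.
#'
#' @param community a community at a stable equilibrium.
#' @param dominant eigenvalue selection rule.
#' @return resilience (log of the modulus of the dominant eigenvalue).
#' @export
resilience <- function(community, dominant = c("real_part", "modulus")) {
  dominant <- match.arg(dominant)
  ev <- eigen(jacobian(community), only.values = TRUE)$values
  if (max(Re(ev)) >= 1e-8)
    stop("community is not at a stable equilibrium (max Re(eigenvalue) >= 0)")
  lam <- if (dominant == "real_part") ev[which.max(Re(ev))]
         else ev[which.max(Mod(ev))]
  log(Mod(lam))
}

#' Topological robustness to species removal
#'
#' Species of both guilds are pooled and removed one at a time from the most
#' generalist (largest marginal interaction total) to the most specialist.
#' After each removal, species left with no remaining partners go
#' secondarily extinct, cascading to a fixed point. Robustness is the
#' fraction of species that had to be *removed* for more than 50% of all
#' species to be lost.
#'
#' @param Q non-negative interaction matrix.
#' @return ROB in (0, 1].
#' @export
robustness <- function(Q) {
  Q <- check_Q(Q)
  n <- nrow(Q); m <- ncol(Q); total <- n + m
  deg <- c(rowSums(Q), colSums(Q))
  ord <- order(deg, decreasing = TRUE)  # stable: ties keep original order
  alive <- rep(TRUE, total)  # animals 1..n, plants n+1..n+m
  adj <- Q > 0
  cascade <- function(alive) {
    repeat {
      a <- alive[seq_len(n)]; p <- alive[n + seq_len(m)]
      dead_rows <- which(a)[!(rowSums(adj[which(a), which(p), drop = FALSE]) > 0)]
      dead_cols <- which(p)[!(colSums(adj[which(a), which(p), drop = FALSE]) > 0)]
      if (!length(dead_rows) && !length(dead_cols)) return(alive)
      alive[dead_rows] <- FALSE
      alive[n + dead_cols] <- FALSE
    }
  }
  removed <- 0L
  for (s in ord) {
    if (!alive[s]) next  # already secondarily extinct
    alive[s] <- FALSE
    removed <- removed + 1L
    if (any(alive)) alive <- cascade(alive)
    if (total - sum(alive) > total / 2) return(removed / total)
  }
  removed / total
}

# second derivative of a function by central differences
curvature_fd <- function(f, x, step = 1e-4) {
  (f(x + step) - 2 * f(x) + f(x - step)) / step^2
}

#' Disruptiveness: strength of disruptive selection
#'
#' The curvature of the invasion fitness in the mutant trait at each singular
#' animal trait, aggregated over all animal morphs (mean by default; the sum
#' variant is available). Positive values mark evolutionary instability
#' (branching-prone communities).
#'
#' @param community a community at an evolutionary singularity (equilibrium
#'   densities, vanishing selection gradients).
#' @param aggregate `"mean"` (default) or `"sum"` over animal morphs.
#' @param d2_step finite-difference step.
#' @param check verify the singularity contract.
#' @param singular_tol tolerance on `max |m N g|` for the contract check.
#' @return DIS.
#' @export
disruptiveness <- function(community, aggregate = c("mean", "sum"),
                           d2_step = 1e-4, check = TRUE,
                           singular_tol = 1e-3) {
  aggregate <- match.arg(aggregate)
  comm <- as_community(community)
  if (n_animals(comm) == 0) stop("no animal morphs")
  if (check) {
    g <- selection_gradient(comm)
    rate <- c(comm$params$m_A * comm$animals$densities * g$animals,
              comm$params$m_P * comm$plants$densities * g$plants)
    if (max(abs(rate)) > singular_tol)
      stop("community is not at an evolutionary singularity ",
           "(max |m N g| = ", signif(max(abs(rate)), 3), ")")
  }
  x <- comm$animals$traits
  f0 <- mutant_fitness(comm, "animal", x)
  fp <- mutant_fitness(comm, "animal", x + d2_step)
  fm <- mutant_fitness(comm, "animal", x - d2_step)
  curv <- (fp - 2 * f0 + fm) / d2_step^2
  if (aggregate == "mean") mean(curv) else sum(curv)
}

#' Propagule introduction schedule
#'
#' The five ways of delivering a total propagule density `T`:
#' mode 1 -- once-off at t = 0; mode 2 -- two equal pulses (t = 0, 5);
#' mode 3 -- three increasing pulses of 20%, 30%, 50% (t = 0, 5, 10);
#' mode 4 -- three decreasing pulses of 50%, 30%, 20%; mode 5 -- five equal
#' pulses of 20% (t = 0, 5, 10, 15, 20). Pulses are instantaneous density
#' additions separated by five time units.
#'
#' @param mode schedule id, 1-5.
#' @param total total propagule density (> 0).
#' @return data frame with columns `time` and `amount` (summing to `total`).
#' @export
introduction_schedule <- function(mode, total) {
  if (!is.numeric(total) || total <= 0) stop("total propagule density must be > 0")
  if (!mode %in% 1:5) stop("unknown introduction mode: ", mode)
  sched <- switch(mode,
    `1` = data.frame(time = 0, amount = total),
    `2` = data.frame(time = c(0, 5), amount = total * c(0.5, 0.5)),
    `3` = data.frame(time = c(0, 5, 10), amount = total * c(0.2, 0.3, 0.5)),
    `4` = data.frame(time = c(0, 5, 10), amount = total * c(0.5, 0.3, 0.2)),
    `5` = data.frame(time = c(0, 5, 10, 15, 20), amount = rep(total * 0.2, 5)))
  sched
}

#' Invasion scenario
#'
#' Defines one alien introduction: the alien's relative trait value `rtv`
#' (0 = lowest native animal trait, 1 = highest; values outside `[0, 1]`
#' probe traits beyond the native range), its generalization-level ratio
#' `glr` multiplying the native mutualistic tolerance, the total propagule
#' density as a fraction of the mean native animal density, the introduction
#' mode, and the measurement time.
#'
#' @param rtv relative trait value.
#' @param glr generalization-level ratio (> 0).
#' @param propagule_fraction fraction of the mean native animal density
#'   (reference levels: 0.05, 0.10, 0.25).
#' @param mode introduction schedule id (1-5).
#' @param measurement_time when invasiveness and impact are measured.
#' @return an object of class `mutnet_scenario`.
#' @export
invasion_scenario <- function(rtv, glr = 1, propagule_fraction = 0.1,
                              mode = 1, measurement_time = 25) {
  stopifnot(is.numeric(rtv), length(rtv) == 1L, is.finite(rtv))
  if (glr <= 0) stop("glr must be > 0")
  if (propagule_fraction <= 0) stop("propagule_fraction must be > 0")
  if (!mode %in% 1:5) stop("unknown introduction mode: ", mode)
  structure(list(rtv = rtv, glr = glr,
                 propagule_fraction = propagule_fraction, mode = mode,
                 measurement_time = measurement_time),
            class = "mutnet_scenario")
}

#' Run one invasion trial
#'
#' Introduces an alien animal morph into a native community at its
#' preinvasion equilibrium. The alien trait is mapped from `rtv` onto the
#' native animal trait range (or set explicitly via `alien_trait`), its
#' mutualistic tolerance is `glr` times the native one, and the total
#' propagule density (`propagule_fraction` times the mean native animal
#' density) is delivered per the introduction schedule. All traits are
#' frozen; only the ecological dynamics run, to the measurement time.
#' Invasiveness is `INVn = ln(alien final density / total propagules)`;
#' impact is `IMP = |ln(native animal total at measurement / preinvasion)|`.
#' An alien ending below the extinction threshold is floored at 1e-8 for the
#' logarithm and the trial marked failed.
#'
#' @param native a native community (or equilibrium) with both guilds
#'   non-empty, at its preinvasion equilibrium.
#' @param scenario an [invasion_scenario()].
#' @param alien_trait optional explicit alien trait (overrides `rtv`).
#' @param record keep the density time series (sampled every time unit).
#' @param rtol,atol integrator tolerances.
#' @return an object of class `mutnet_invasion`: `INVn`, `IMP`, `success`
#'   (INVn > 0), `native_decline`, `failed`, densities before/after, the
#'   alien definition, and optionally `trajectory`.
#' @export
run_invasion_trial <- function(native, scenario, alien_trait = NULL,
                               record = FALSE, rtol = 1e-8, atol = 1e-10) {
  comm <- as_community(native)
  stopifnot(inherits(scenario, "mutnet_scenario"))
  if (n_animals(comm) == 0 || n_plants(comm) == 0)
    stop("native community must have both guilds non-empty")
  if (!is.na(comm$alien_index)) stop("native community already contains an alien")

  xr <- range(comm$animals$traits)
  if (is.null(alien_trait))
    alien_trait <- xr[1] + scenario$rtv * (xr[2] - xr[1])
  alien_sigma <- scenario$glr * comm$params$sigma_m
  total <- scenario$propagule_fraction * mean(comm$animals$densities)
  sched <- introduction_schedule(scenario$mode, total)

  native_initial <- sum(comm$animals$densities)
  inv <- comm
  inv$animals$traits <- c(inv$animals$traits, alien_trait)
  inv$animals$densities <- c(inv$animals$densities, 0)
  inv$animals$ids <- c(inv$animals$ids, max(inv$animals$ids) + 1L)
  inv$alien_index <- n_animals(inv)
  inv$alien_sigma_m <- alien_sigma

  times <- sort(unique(c(sched$time, scenario$measurement_time)))
  trajs <- if (record) list() else NULL
  t_now <- 0
  for (s in seq_along(times)) {
    tt <- times[s]
    pulse <- sched$amount[abs(sched$time - tt) < 1e-12]
    if (length(pulse))
      inv$animals$densities[inv$alien_index] <-
        inv$animals$densities[inv$alien_index] + sum(pulse)
    t_next <- if (s < length(times)) times[s + 1] else scenario$measurement_time
    if (t_next > tt) {
      res <- integrate_dynamics(inv, t_next - tt, record = record,
                                record_dt = 1, rtol = rtol, atol = atol)
      if (record) {
        tr <- res$trajectory; tr$time <- tr$time + tt
        trajs[[length(trajs) + 1L]] <- tr
        inv <- res$community
      } else inv <- res
    }
    t_now <- t_next
    if (tt >= scenario$measurement_time) break
  }

  alien_final <- inv$animals$densities[inv$alien_index]
  native_final <- sum(inv$animals$densities[-inv$alien_index])
  failed <- alien_final < comm$params$extinction_threshold
  INVn <- log(max(alien_final, 1e-8) / total)
  IMP <- abs(log(native_final / native_initial))
  structure(list(
    INVn = INVn, IMP = IMP, success = INVn > 0,
    native_decline = native_final < native_initial, failed = failed,
    alien_trait = alien_trait, alien_sigma_m = alien_sigma,
    propagules = total, alien_final = alien_final,
    native_initial = native_initial, native_final = native_final,
    native_change_pct = 100 * (native_final - native_initial) / native_initial,
    scenario = scenario, community = inv,
    trajectory = if (record) do.call(rbind, trajs) else NULL),
    class = "mutnet_invasion")
}

#' @export
print.mutnet_invasion <- function(x, ...) {
  cat(sprintf("Invasion trial: INVn = %.4f (%s), IMP = %.4g, native %s\n",
              x$INVn, if (x$success) "success" else "failure", x$IMP,
              if (x$native_decline) "declined" else "did not decline"))
  invisible(x)
}

#' Invasiveness/impact over the trait-by-generalization grid
#'
#' Runs the full factorial of alien relative trait values and
#' generalization-level ratios (defaults: 9 evenly spaced `rtv` in `[0, 1]`
#' by 9 log-spaced `glr` in `[1/5, 5]`, whose centre is exactly 1).
#'
#' @param native native community at equilibrium.
#' @param rtv_grid,glr_grid scenario grids.
#' @param propagule_fraction,mode,measurement_time shared scenario settings.
#' @return data frame with one row per (rtv, glr): INVn, IMP, success,
#'   native_decline, native_change_pct, failed.
#' @export
invasiveness_impact_grid <- function(native,
                                     rtv_grid = seq(0, 1, length.out = 9),
                                     glr_grid = 5^seq(-1, 1, length.out = 9),
                                     propagule_fraction = 0.1, mode = 1,
                                     measurement_time = 25) {
  comm <- as_community(native)
  grid <- expand.grid(rtv = rtv_grid, glr = glr_grid)
  out <- lapply(seq_len(nrow(grid)), function(k) {
    tr <- run_invasion_trial(comm, invasion_scenario(
      grid$rtv[k], grid$glr[k], propagule_fraction, mode, measurement_time))
    data.frame(rtv = grid$rtv[k], glr = grid$glr[k], INVn = tr$INVn,
               IMP = tr$IMP, success = tr$success,
               native_decline = tr$native_decline,
               native_change_pct = tr$native_change_pct, failed = tr$failed)
  })
  do.call(rbind, out)
}

#' Network invasibility
#'
#' The proportion of successful invasions (positive invasiveness) among
#' aliens whose traits span the native animal trait range (default: the
#' 9-point `rtv` grid) with the native generalization level (`glr = 1`).
#'
#' @param native native community at equilibrium.
#' @param rtv_grid trait grid spanning the native range.
#' @param propagule_fraction,mode scenario settings.
#' @return INVb in `[0, 1]`.
#' @export
invasibility <- function(native, rtv_grid = seq(0, 1, length.out = 9),
                         propagule_fraction = 0.1, mode = 1) {
  comm <- as_community(native)
  succ <- vapply(rtv_grid, function(r) {
    run_invasion_trial(comm, invasion_scenario(
      r, 1, propagule_fraction, mode))$success
  }, logical(1))
  mean(succ)
}

#' Reference invasion record for ensemble correlations
#'
#' A single trial whose alien carries the density-weighted mean native
#' animal trait and the native generalization level (`glr = 1`); returns the
#' invasiveness and impact entering the cross-network correlation analysis.
#'
#' @param native native community at equilibrium.
#' @param propagule_fraction,mode scenario settings.
#' @return list with `INVn`, `IMP`, `native_decline`, `success`.
#' @export
ensemble_invasion_record <- function(native, propagule_fraction = 0.1,
                                     mode = 1) {
  comm <- as_community(native)
  xbar <- sum(comm$animals$traits * comm$animals$densities) /
    sum(comm$animals$densities)
  tr <- run_invasion_trial(comm,
                           invasion_scenario(0, 1, propagule_fraction, mode),
                           alien_trait = xbar)
  list(INVn = tr$INVn, IMP = tr$IMP, native_decline = tr$native_decline,
       success = tr$success, alien_trait = xbar)
}
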