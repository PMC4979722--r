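#' Model parameter set
#'
#' Bundles every constant of the eco-evolutionary model: intrinsic growth
#' rates, handling time, carrying-capacity scale constants and optima, the
#' Gaussian kernel widths (resource access, competition, mutualistic trait
#' tolerance), the maximal mutualistic benefit, mutation-rate scalings of the
#' canonical equation, and the numerical thresholds for extinction and for
#' treating an interaction strength as zero.
#'
#' The reference values (`r_A = r_P = 1`, `h = 0.1`, `k_A = 400`, `k_P = 300`,
#' `x_Amax = 3`, `y_Pmax = 2`, `c = 0.1`, `m_A = m_P = 1e-3`) are the model's
#' standard parameterization; the kernel widths default to a combination known
#' to diversify repeatedly (`sigma_A = e^0.75`, `sigma_C = e^-3`,
#' `sigma_m = e^-2.25`) and are the quantities swept when generating network
#' ensembles.
#'
#' @param r_A,r_P intrinsic per-capita growth rates (1/time).
#' @param h handling time of the type II functional response (time).
#' @param k_A,k_P carrying-capacity scale constants (density).
#' @param x_Amax,y_Pmax trait values of maximal resource access.
#' @param sigma_A,sigma_P resource-accessibility kernel widths (trait units).
#' @param sigma_C competition kernel width (trait units).
#' @param sigma_m mutualism trait-difference tolerance (trait units).
#' @param c maximal mutualistic benefit (1/(density x time)).
#' @param m_A,m_P mutation-rate scalings of the canonical equation.
#' @param extinction_threshold density below which a morph is removed.
#' @param q_threshold interaction strength treated as exactly zero.
#' @param normalized_K if `TRUE` the carrying capacity uses the normalized
#'   Gaussian density (maximum `k/(sigma*sqrt(2*pi))`); the default `FALSE`
#'   uses the unnormalized Gaussian with maximum exactly `k` at the optimum.
#' @return an object of class `mutnet_params` (a validated named list).
#' @export
#' @examples
#' p <- model_params(sigma_C = 0.2)
#' p$sigma_C
model_params <- function(r_A = 1, r_P = 1, h = 0.1, k_A = 400, k_P = 300,
                         x_Amax = 3, y_Pmax = 2,
                         sigma_A = exp(0.75), sigma_P = sigma_A,
                         sigma_C = exp(-3), sigma_m = exp(-2.25),
                         c = 0.1, m_A = 1e-3, m_P = 1e-3,
                         extinction_threshold = 1e-8, q_threshold = 1e-8,
                         normalized_K = FALSE) {
  p <- list(r_A = r_A, r_P = r_P, h = h, k_A = k_A, k_P = k_P,
            x_Amax = x_Amax, y_Pmax = y_Pmax,
            sigma_A = sigma_A, sigma_P = sigma_P, sigma_C = sigma_C,
            sigma_m = sigma_m, c = c, m_A = m_A, m_P = m_P,
            extinction_threshold = extinction_threshold,
            q_threshold = q_threshold, normalized_K = isTRUE(normalized_K))
  validate_params(p)
  class(p) <- "mutnet_params"
  p
}

validate_params <- function(p) {
  num <- setdiff(names(p), "normalized_K")
  for (nm in num) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("parameter '", nm, "' must be a single finite number")
  }
  for (nm in c("sigma_A", "sigma_P", "sigma_C", "sigma_m"))
    if (p[[nm]] <= 0) stop("kernel width '", nm, "' must be positive")
  if (p$h < 0) stop("handling time 'h' must be non-negative")
  if (p$c < 0) stop("mutualistic benefit 'c' must be non-negative")
  if (p$k_A <= 0 || p$k_P <= 0) stop("carrying-capacity constants must be positive")
  invisible(p)
}

#' @export
print.mutnet_params <- function(x, ...) {
  cat("Model parameters (mutnet_params)\n")
  for (nm in names(x)) cat(sprintf("  %-22s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

#' Guild state
#'
#' Traits and matching population densities of one guild (animals or plants).
#'
#' @param traits numeric vector of trait values.
#' @param densities numeric vector of population densities, same length.
#' @param ids optional morph identifiers (kept through pruning/branching).
#' @return a list with elements `traits`, `densities`, `ids`.
#' @export
guild_state <- function(traits, densities, ids = NULL) {
  traits <- as.numeric(traits); densities <- as.numeric(densities)
  if (length(traits) != length(densities))
    stop("traits and densities must have equal length")
  if (length(densities) && any(densities < 0)) stop("densities must be >= 0")
  if (length(traits) && any(!is.finite(traits))) stop("traits must be finite")
  if (is.null(ids)) ids <- seq_along(traits)
  list(traits = traits, densities = densities, ids = as.integer(ids))
}

#' Community of animal and plant morphospecies
#'
#' A community couples the two guild states with the parameter set that
#' governs them. An introduced alien is always an animal morph; it is marked
#' by `alien_index` and carries its own mutualistic tolerance
#' `alien_sigma_m` (natives share `params$sigma_m`).
#'
#' @param animals,plants guild states (see [guild_state()]).
#' @param params a [model_params()] object.
#' @param alien_index index of the alien animal morph, or `NA` for none.
#' @param alien_sigma_m the alien's private mutualistic tolerance.
#' @return an object of class `mutnet_community`.
#' @export
#' @examples
#' comm <- community(guild_state(3, 200), guild_state(2, 150), model_params())
community <- function(animals, plants, params = model_params(),
                      alien_index = NA_integer_, alien_sigma_m = NA_real_) {
  if (is.numeric(animals)) animals <- guild_state(animals, rep(0, length(animals)))
  stopifnot(inherits(params, "mutnet_params"))
  if (length(animals$traits) == 0 && length(plants$traits) == 0)
    stop("at least one guild must be non-empty")
  if (!is.na(alien_index)) {
    if (alien_index < 1 || alien_index > length(animals$traits))
      stop("alien_index out of range (the alien must be an animal morph)")
    if (!is.finite(alien_sigma_m) || alien_sigma_m <= 0)
      stop("an alien requires a positive alien_sigma_m")
  }
  structure(list(animals = animals, plants = plants, params = params,
                 alien_index = as.integer(alien_index),
                 alien_sigma_m = alien_sigma_m),
            class = "mutnet_community")
}

#' @export
print.mutnet_community <- function(x, ...) {
  cat(sprintf("Mutualistic community: %d animal / %d plant morphs\n",
              length(x$animals$traits), length(x$plants$traits)))
  if (!is.na(x$alien_index))
    cat(sprintf("  alien animal at index %d (sigma_m = %.4g)\n",
                x$alien_index, x$alien_sigma_m))
  invisible(x)
}

# per-animal sigma_m vector (alien morphs carry a private tolerance)
sigma_m_animals <- function(comm) {
  n <- length(comm$animals$traits)
  sm <- rep(comm$params$sigma_m, n)
  if (!is.na(comm$alien_index)) sm[comm$alien_index] <- comm$alien_sigma_m
  sm
}

n_animals <- function(comm) length(comm$animals$traits)
n_plants <- function(comm) length(comm$plants$traits)

as_community <- function(x) {
  if (inherits(x, "mutnet_equilibrium")) return(x$community)
  if (inherits(x, "mutnet_community")) return(x)
  stop("expected a mutnet_community or mutnet_equilibrium")
}
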