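# Kinetic and photophysical primitives: dye pairs, FRET species, rate
# matrices, Gillespie trajectories and the two-state occupancy-time law.
# Units: rates are s^-1 and times are seconds everywhere at interfaces;
# nanoseconds appear only for TCSPC micro-times and lifetimes.

#' Define a FRET dye pair
#'
#' A dye pair is characterised by its Foerster radius \eqn{R_0} (the
#' inter-dye distance at which the transfer efficiency is 1/2) and the
#' unquenched donor fluorescence lifetime \eqn{\tau_0}.
#'
#' @param forster_radius Foerster radius \eqn{R_0} in Angstrom. The
#'   Alexa568/647 pair used for long-range chromatin distances has
#'   \eqn{R_0 = 82} A; Alexa488/647 has \eqn{R_0 = 52} A.
#' @param donor_lifetime Unquenched donor lifetime \eqn{\tau_0} in ns.
#' @param label Optional text label.
#' @return An object of class `dye_pair`.
#' @export
dye_pair <- function(forster_radius, donor_lifetime, label = "dye pair") {
  stopifnot(is.numeric(forster_radius), length(forster_radius) == 1L,
            is.numeric(donor_lifetime), length(donor_lifetime) == 1L)
  if (forster_radius <= 0) stop("forster_radius must be > 0")
  if (donor_lifetime <= 0) stop("donor_lifetime must be > 0")
  structure(list(R0 = forster_radius, tau0 = donor_lifetime, label = label),
            class = "dye_pair")
}

#' @export
print.dye_pair <- function(x, ...) {
  cat(sprintf("<dye_pair> %s: R0 = %g A, tau0 = %g ns\n",
              x$label, x$R0, x$tau0))
  invisible(x)
}

#' FRET efficiency from inter-dye distance
#'
#' Evaluates the Foerster relation \eqn{E = 1/(1 + (R_{DA}/R_0)^6)}.
#'
#' @param distance Inter-dye distance \eqn{R_{DA}} in Angstrom (> 0).
#' @param pair A [dye_pair()].
#' @return Transfer efficiency in (0, 1). Vectorised over `distance`.
#' @export
efficiency_from_distance <- function(distance, pair) {
  if (any(!is.finite(distance)) || any(distance <= 0))
    stop("distance must be positive and finite")
  1 / (1 + (distance / pair$R0)^6)
}

#' Inter-dye distance from FRET efficiency
#'
#' Exact inverse of [efficiency_from_distance()].
#'
#' @param efficiency Transfer efficiency, strictly inside (0, 1).
#' @param pair A [dye_pair()].
#' @return Distance in Angstrom. Vectorised over `efficiency`.
#' @export
distance_from_efficiency <- function(efficiency, pair) {
  if (any(!is.finite(efficiency)) || any(efficiency <= 0) ||
      any(efficiency >= 1))
    stop("efficiency must lie strictly inside (0, 1)")
  pair$R0 * (1 / efficiency - 1)^(1 / 6)
}

#' Define a FRET species
#'
#' A species is one limiting conformational state with a fixed inter-dye
#' distance. Its efficiency and quenched donor lifetime follow from the
#' attached dye pair: \eqn{\tau_{D(A)} = \tau_0 (1 - E)}.
#'
#' @param name Species label (e.g. "A".."D").
#' @param pair A [dye_pair()].
#' @param distance Inter-dye distance in Angstrom; give either this or
#'   `efficiency`.
#' @param efficiency Transfer efficiency in (0, 1), alternative to `distance`.
#' @param brightness Relative molecular brightness (positive scalar, 1 =
#'   reference).
#' @return An object of class `fret_species`.
#' @export
fret_species <- function(name, pair, distance = NULL, efficiency = NULL,
                         brightness = 1) {
  if (is.null(distance) == is.null(efficiency))
    stop("give exactly one of distance or efficiency")
  if (is.null(efficiency)) efficiency <- efficiency_from_distance(distance, pair)
  else distance <- distance_from_efficiency(efficiency, pair)
  if (brightness <= 0) stop("brightness must be positive")
  structure(list(name = name, R_DA = distance, E = efficiency,
                 tau_DA = pair$tau0 * (1 - efficiency),
                 brightness = brightness, pair = pair),
            class = "fret_species")
}

#' Build a continuous-time Markov kinetic model over FRET species
#'
#' The rate matrix uses the row-generator convention: `K[i, j]` for `i != j`
#' is the rate (s^-1) of the `i -> j` transition and the diagonal is minus
#' the row sum, so every row sums to zero. Transitions absent from
#' `connectivity` are held at exactly zero. The exchanging subgraph must be
#' irreducible; non-interchanging subpopulations (the "locked" molecules that
#' show no dynamics on the ~10 ms confocal timescale) are carried as a
#' per-molecule static fraction with its own state-probability vector.
#'
#' @param species List of [fret_species()] (or a character vector of names
#'   for abstract models).
#' @param rates Either an S x S numeric matrix of off-diagonal rates (s^-1;
#'   diagonal ignored) or a data.frame with columns `from`, `to`, `rate`
#'   using species names.
#' @param connectivity Optional S x S logical adjacency; defaults to
#'   `rates > 0`. Rates outside the mask must be zero.
#' @param static_fraction Fraction of molecules (between 0 and 1) that
#'   never exchange.
#' @param static_weights State probabilities of the static subpopulation
#'   (defaults to the stationary law of the exchanging pool).
#' @return An object of class `kinetic_model` with elements `species`, `K`,
#'   `connectivity`, `static_fraction`, `static_weights`.
#' @export
kinetic_model <- function(species, rates, connectivity = NULL,
                          static_fraction = 0, static_weights = NULL) {
  if (is.character(species)) {
    nm <- species
    species <- lapply(nm, function(n) list(name = n))
  } else if (inherits(species, "fret_species")) {
    species <- list(species)
  }
  nm <- vapply(species, function(s) s$name, character(1))
  S <- length(species)
  K <- matrix(0, S, S, dimnames = list(nm, nm))
  if (is.data.frame(rates)) {
    for (r in seq_len(nrow(rates))) {
      i <- match(as.character(rates$from[r]), nm)
      j <- match(as.character(rates$to[r]), nm)
      if (is.na(i) || is.na(j)) stop("unknown species in rate table")
      K[i, j] <- rates$rate[r]
    }
  } else {
    rates <- as.matrix(rates)
    stopifnot(nrow(rates) == S, ncol(rates) == S)
    K[] <- rates
    diag(K) <- 0
  }
  if (any(K < 0)) stop("off-diagonal rates must be >= 0")
  if (is.null(connectivity)) connectivity <- K > 0
  storage.mode(connectivity) <- "logical"
  diag(connectivity) <- FALSE
  if (any(K[!connectivity] != 0))
    stop("rates present outside the connectivity mask")
  diag(K) <- -rowSums(K)
  if (static_fraction < 0 || static_fraction > 1)
    stop("static_fraction must lie in [0, 1]")
  model <- structure(list(species = species, K = K,
                          connectivity = connectivity,
                          static_fraction = static_fraction,
                          static_weights = static_weights),
                     class = "kinetic_model")
  if (S > 1 && !is_irreducible(K))
    stop("the exchanging subgraph is reducible; use separate branch models")
  if (is.null(static_weights) && static_fraction > 0)
    model$static_weights <- stationary_distribution(model)
  if (!is.null(model$static_weights)) {
    if (length(model$static_weights) != S ||
        abs(sum(model$static_weights) - 1) > 1e-9)
      stop("static_weights must be a probability vector over species")
  }
  model
}

#' @export
print.kinetic_model <- function(x, ...) {
  cat(sprintf("<kinetic_model> %d species: %s\n", n_states(x),
              paste(species_names(x), collapse = ", ")))
  cat("rate matrix (s^-1):\n")
  print(signif(x$K, 4))
  if (x$static_fraction > 0)
    cat(sprintf("static fraction: %.3f\n", x$static_fraction))
  invisible(x)
}

n_states <- function(model) nrow(model$K)

species_names <- function(model)
  vapply(model$species, function(s) s$name, character(1))

#' Species efficiencies of a kinetic model
#' @param model A [kinetic_model()] with full `fret_species`.
#' @return Numeric vector of per-species efficiencies.
#' @export
species_efficiencies <- function(model)
  vapply(model$species, function(s) s$E, numeric(1))

species_brightness <- function(model)
  vapply(model$species, function(s) if (is.null(s$brightness)) 1 else s$brightness,
         numeric(1))

is_irreducible <- function(K) {
  A <- (K > 0) | diag(nrow(K)) > 0
  # boolean matrix power reachability
  R <- A
  for (i in seq_len(nrow(K))) R <- (R %*% A) > 0 | R
  all(R)
}

#' Relaxation times of a kinetic model
#'
#' Returns \eqn{-1/\lambda} for every nonzero eigenvalue \eqn{\lambda} of the
#' generator, sorted ascending. For a two-state model this is exactly
#' \eqn{1/(k_{12} + k_{21})}.
#'
#' @param model A [kinetic_model()].
#' @return Numeric vector of relaxation times in seconds.
#' @export
relaxation_times <- function(model) {
  K <- model$K
  S <- nrow(K)
  if (S == 1) return(numeric(0))
  if (!is_irreducible(K)) stop("reducible exchanging subgraph")
  if (S == 2) return(1 / (K[1, 2] + K[2, 1]))
  ev <- eigen(K, only.values = TRUE)$values
  ev <- Re(ev)  # generator of a CTMC: eigenvalues have non-positive real part
  scale <- max(abs(K))
  ev <- ev[abs(ev) > 1e-10 * scale]
  sort(-1 / ev)
}

#' Stationary distribution of a kinetic model
#'
#' Left null vector of the generator, normalised to sum 1.
#'
#' @param model A [kinetic_model()].
#' @return Probability vector over species.
#' @export
stationary_distribution <- function(model) {
  K <- model$K
  S <- nrow(K)
  if (S == 1) return(stats::setNames(1, species_names(model)))
  if (!is_irreducible(K)) stop("reducible exchanging subgraph")
  K <- K / max(abs(K))   # scale-invariant; protects near-static models
  A <- rbind(t(K), rep(1, S))
  b <- c(rep(0, S), 1)
  pi <- as.vector(qr.solve(A, b))
  pi[pi < 0] <- 0
  pi <- pi / sum(pi)
  stats::setNames(pi, species_names(model))
}

#' Sample a state trajectory (Gillespie)
#'
#' Draws one exact continuous-time Markov trajectory over `[0, duration]`.
#' The initial state is drawn from the stationary law unless overridden,
#' which supports non-equilibrium injection experiments.
#'
#' @param model A [kinetic_model()].
#' @param duration Trajectory length in seconds (> 0).
#' @param seed Optional integer seed (calls `set.seed`).
#' @param initial_state Optional initial state index (1-based) or species
#'   name.
#' @return A `state_trajectory`: list with `jump_times` (s, starting at 0),
#'   `states` (indices per segment) and `duration`.
#' @export
sample_trajectory <- function(model, duration, seed = NULL,
                              initial_state = NULL) {
  if (duration <= 0) stop("duration must be > 0")
  if (!is.null(seed)) set.seed(seed)
  p0 <- if (n_states(model) == 1) 1 else stationary_distribution(model)
  init <- 0L
  if (!is.null(initial_state)) {
    if (is.character(initial_state))
      initial_state <- match(initial_state, species_names(model))
    init <- as.integer(initial_state)
  }
  tr <- cpp_ctmc_trajectory(model$K, as.numeric(p0), duration, init)
  structure(tr, class = "state_trajectory")
}

#' Time-in-state fractions over a window, by Monte-Carlo
#'
#' Samples `n` equilibrium-start trajectories of length `window` and returns
#' the fraction of time spent in each state. This is the Monte-Carlo
#' occupancy kernel used by dynPDA for models with more than two states, and
#' the independent oracle for the analytic two-state law.
#'
#' @param model A [kinetic_model()].
#' @param window Window duration in seconds.
#' @param n Number of replicates.
#' @param seed Optional integer seed.
#' @return An `n` x S matrix of occupancy fractions (rows sum to 1).
#' @export
occupancy_fraction_sample <- function(model, window, n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  p0 <- if (n_states(model) == 1) 1 else stationary_distribution(model)
  m <- cpp_occupancy_fractions(model$K, as.numeric(p0), window, as.integer(n))
  colnames(m) <- species_names(model)
  m
}

#' Analytic occupancy-fraction law for a two-state model
#'
#' For a two-state exchange process observed over a window of length `T`,
#' the fraction of time `x` spent in state 1 has point masses at 0 and 1
#' (windows without any transition) plus a continuous density expressed
#' through modified Bessel functions. Starting from equilibrium,
#' the mass at 1 is \eqn{\pi_1 e^{-k_{12} T}} and the mass at 0 is
#' \eqn{\pi_2 e^{-k_{21} T}}.
#'
#' @param model A two-state [kinetic_model()].
#' @param window Window duration `T` in seconds.
#' @return A list with `mass0`, `mass1`, and `density(x)` (vectorised over
#'   `x` in (0, 1)); also `pi`, the stationary law.
#' @export
occupancy_fraction_density <- function(model, window) {
  if (n_states(model) != 2)
    stop("analytic occupancy law requires exactly 2 exchanging states; ",
         "use occupancy_fraction_sample() for larger models")
  if (window <= 0) stop("window must be > 0")
  K <- model$K
  k12 <- K[1, 2]; k21 <- K[2, 1]
  pi <- stationary_distribution(model)
  T <- window
  dens <- function(x) {
    stopifnot(all(x > 0 & x < 1))
    u <- k12 * k21 * T^2 * x * (1 - x)
    z <- 2 * sqrt(u)
    i0 <- besselI(z, 0, expon.scaled = TRUE)
    # I1(z)/sqrt(u) -> 1 as u -> 0
    i1r <- ifelse(u > 0, besselI(z, 1, expon.scaled = TRUE) / sqrt(u), exp(-z))
    lead <- exp(-k12 * T * x - k21 * T * (1 - x) + z)
    T * lead * ((pi[1] * k12 + pi[2] * k21) * i0 +
                  k12 * k21 * T * (pi[1] * x + pi[2] * (1 - x)) * i1r)
  }
  list(mass0 = unname(pi[2] * exp(-k21 * T)),
       mass1 = unname(pi[1] * exp(-k12 * T)),
       density = dens, pi = unname(pi))
}

#' Discretised occupancy-fraction distribution
#'
#' Probability weights of the time-in-state-1 fraction on a regular grid,
#' with the no-transition point masses folded into the end grid points.
#' For two-state models the analytic law is used; otherwise a seeded
#' Monte-Carlo sample of trajectories is binned.
#'
#' @param model A [kinetic_model()].
#' @param window Window duration in seconds.
#' @param n_grid Number of interior grid cells (default 101).
#' @param n_mc Monte-Carlo sample size for models with more than two states.
#' @param seed Seed for the Monte-Carlo path.
#' @return A data.frame with columns `x` (fraction in state 1) and `prob`;
#'   probabilities sum to 1.
#' @export
occupancy_fraction_grid <- function(model, window, n_grid = 101,
                                    n_mc = 10000, seed = NULL) {
  if (n_states(model) == 2) {
    law <- occupancy_fraction_density(model, window)
    edges <- seq(0, 1, length.out = n_grid + 1)
    mid <- (edges[-1] + edges[-length(edges)]) / 2
    # fine midpoint rule inside each cell (5 points) for sharp densities
    fine <- 5L
    w <- vapply(seq_len(n_grid), function(i) {
      xs <- seq(edges[i], edges[i + 1], length.out = fine + 2)[2:(fine + 1)]
      mean(law$density(xs)) * (edges[i + 1] - edges[i])
    }, numeric(1))
    cont_mass <- 1 - law$mass0 - law$mass1
    if (sum(w) > 0) w <- w * (cont_mass / sum(w))
    x <- c(0, mid, 1)
    prob <- c(law$mass0, w, law$mass1)
  } else {
    frac <- occupancy_fraction_sample(model, window, n_mc, seed = seed)[, 1]
    edges <- seq(0, 1, length.out = n_grid + 1)
    idx <- pmin(pmax(findInterval(frac, edges, rightmost.closed = TRUE), 1),
                n_grid)
    cnt <- tabulate(idx, nbins = n_grid)
    x <- (edges[-1] + edges[-length(edges)]) / 2
    prob <- cnt / sum(cnt)
  }
  data.frame(x = x, prob = prob)
}

#' Serialise a kinetic model to a config block
#'
#' Writes species (name, distance or efficiency, brightness), rate entries
#' and the static fraction to a YAML file, preserving full double precision
#' so that read/write round-trips are exact.
#'
#' @param model A [kinetic_model()].
#' @param path File path to write.
#' @return `path`, invisibly.
#' @export
write_kinetic_model <- function(model, path) {
  num <- function(x) sprintf("%.17g", x)
  sp <- lapply(model$species, function(s) {
    out <- list(name = s$name)
    if (!is.null(s$E)) out$efficiency <- num(s$E)
    if (!is.null(s$brightness)) out$brightness <- num(s$brightness)
    if (!is.null(s$pair))
      out$pair <- list(R0 = num(s$pair$R0), tau0 = num(s$pair$tau0),
                       label = s$pair$label)
    out
  })
  nm <- species_names(model)
  K <- model$K
  rates <- list()
  for (i in seq_along(nm)) for (j in seq_along(nm))
    if (i != j && K[i, j] > 0)
      rates[[length(rates) + 1]] <- paste(nm[i], nm[j], num(K[i, j]), sep = ",")
  cfg <- list(species = sp, rates = rates,
              static_fraction = num(model$static_fraction))
  if (!is.null(model$static_weights))
    cfg$static_weights <- lapply(as.numeric(model$static_weights), num)
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Read a kinetic model config block
#'
#' Inverse of [write_kinetic_model()].
#'
#' @param path YAML file written by [write_kinetic_model()].
#' @return A [kinetic_model()].
#' @export
read_kinetic_model <- function(path) {
  cfg <- yaml::read_yaml(path)
  sp <- lapply(cfg$species, function(s) {
    if (!is.null(s$pair)) {
      pair <- dye_pair(as.numeric(s$pair$R0), as.numeric(s$pair$tau0),
                       s$pair$label)
      fret_species(s$name, pair, efficiency = as.numeric(s$efficiency),
                   brightness = as.numeric(s$brightness %||% "1"))
    } else {
      out <- list(name = s$name)
      if (!is.null(s$efficiency)) out$E <- as.numeric(s$efficiency)
      if (!is.null(s$brightness)) out$brightness <- as.numeric(s$brightness)
      out
    }
  })
  nm <- vapply(sp, function(s) s$name, character(1))
  parts <- strsplit(unlist(cfg$rates), ",")
  rates <- data.frame(from = vapply(parts, `[`, "", 1),
                      to = vapply(parts, `[`, "", 2),
                      rate = as.numeric(vapply(parts, `[`, "", 3)))
  sw <- if (!is.null(cfg$static_weights))
    as.numeric(unlist(cfg$static_weights)) else NULL
  kinetic_model(sp, rates, static_fraction = as.numeric(cfg$static_fraction),
                static_weights = sw)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
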