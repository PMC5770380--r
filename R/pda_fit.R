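# dynPDA fitting: free parameters are addressed by name
# ("rate.<branch>.<from>.<to>", "E.<species>", "w.<branch>",
# "static_fraction", "donor_only"), transformed to an unconstrained scale
# (log for rates, logit for fractions and efficiencies) and optimised by
# deterministic multi-start Nelder-Mead from a seeded Latin hypercube.
# Species efficiencies are shared across conditions; rates, branch weights
# and the static fraction get per-condition copies ("<name>@<condition>")
# when the data span several conditions.

pda_param_get <- function(model, name) {
  parts <- strsplit(name, ".", fixed = TRUE)[[1]]
  switch(parts[1],
         E = model$species$E[match(parts[2], model$species$name)],
         rate = {
           b <- as.integer(parts[2])
           model$branches[[b]]$rates[parts[3], parts[4]]
         },
         w = model$branch_weights[as.integer(parts[2])],
         static_fraction = model$static_fraction,
         donor_only = model$donor_only_fraction,
         stop("unknown parameter: ", name))
}

pda_param_set <- function(model, name, value) {
  parts <- strsplit(name, ".", fixed = TRUE)[[1]]
  switch(parts[1],
         E = {
           model$species$E[match(parts[2], model$species$name)] <- value
         },
         rate = {
           b <- as.integer(parts[2])
           model$branches[[b]]$rates[parts[3], parts[4]] <- value
         },
         w = {
           if (length(model$branch_weights) != 2)
             stop("free branch weights are supported for two branches")
           b <- as.integer(parts[2])
           model$branch_weights[b] <- value
           model$branch_weights[-b] <- 1 - value
         },
         static_fraction = { model$static_fraction <- value },
         donor_only = { model$donor_only_fraction <- value },
         stop("unknown parameter: ", name))
  model
}

pda_param_kind <- function(name) {
  if (startsWith(name, "rate.")) "log" else "logit"
}

# strip a condition suffix "@cond"
split_cond <- function(name) {
  s <- strsplit(name, "@", fixed = TRUE)[[1]]
  list(base = s[1], cond = if (length(s) > 1) s[2] else NA_character_)
}

model_for_condition <- function(template, par, cond) {
  m <- template
  for (nm in names(par)) {
    sc <- split_cond(nm)
    if (!is.na(sc$cond) && sc$cond != cond) next
    m <- pda_param_set(m, sc$base, par[[nm]])
  }
  if (isTRUE(attr(template, "static_weights_auto")))
    m$static_weights <- default_static_weights(m)
  m
}

# pool adjacent histogram bins until each group holds >= min_count observed
pool_groups <- function(obs, min_count = 5) {
  g <- integer(length(obs)); cur <- 1L; acc <- 0
  for (i in seq_along(obs)) {
    g[i] <- cur
    acc <- acc + obs[i]
    if (acc >= min_count && i < length(obs)) { cur <- cur + 1L; acc <- 0 }
  }
  if (acc < min_count && cur > 1L) g[g == cur] <- cur - 1L
  g
}

lhs_unit <- function(n, d) {
  m <- matrix(0, n, d)
  for (j in seq_len(d)) m[, j] <- (sample.int(n) - stats::runif(n)) / n
  m
}

#' Fit a dynPDA kinetic model to time-window data
#'
#' Minimises the summed Pearson chi-squared between predicted and observed
#' proximity-ratio count histograms across all window durations and
#' conditions simultaneously. Histogram bins are pooled so every group
#' holds at least 5 observed windows (pooling fixed by the data, not the
#' model). Species efficiencies are shared across conditions; rates, branch
#' weights and the static fraction are fitted per condition unless the data
#' has a single condition.
#'
#' @param data Window data.frame (from [slice_time_windows()] or
#'   [simulate_pda_windows()]), or a list of them; must carry `dt_s` and
#'   `condition` columns.
#' @param template A [pda_model()] providing structure and start values.
#' @param free Character vector of free parameter base names, e.g.
#'   `c("rate.1.A.D", "rate.1.D.A", "E.A", "static_fraction")`.
#' @param breaks Proximity-ratio bin edges.
#' @param n_starts Multi-start points (the template itself is always one).
#' @param seed Seed controlling the start spread and the Monte-Carlo
#'   occupancy kernel.
#' @param n_grid,n_mc Occupancy discretisation (two-state analytic grid /
#'   Monte-Carlo trajectories per evaluation).
#' @param maxit Nelder-Mead iteration budget per start.
#' @param rate_range Start range for free rates, s^-1.
#' @param n_classes Total-count classes used per dataset during fitting
#'   (pooling nearby totals speeds the forward model; `Inf` disables).
#' @param compress Equal-mass nodes the occupancy cloud is collapsed to
#'   during fitting (`NULL` disables; predictions reported in the fit
#'   result use the same setting as the objective).
#' @return A `pda_fit`: `par` (named, natural units), `chisq_red`, `value`,
#'   `models` (per condition), `histograms` (per dataset observed/expected),
#'   `n_windows`, `free`, `seed`.
#' @export
fit_kinetic_model <- function(data, template, free,
                              breaks = seq(0, 1, by = 0.02),
                              n_starts = 6, seed = 1L, n_grid = 61,
                              n_mc = 4000, maxit = 400,
                              rate_range = c(10, 1e5), n_classes = 50,
                              compress = 25) {
  if (is.list(data) && !is.data.frame(data)) data <- do.call(rbind, data)
  if (is.null(data$condition)) data$condition <- "all"
  sets <- split(data, list(data$dt_s, data$condition), drop = TRUE)
  conds <- unique(data$condition)
  designs <- lapply(sets, function(d)
    c(pda_design(d$S_G + d$S_R, breaks, n_classes = n_classes), list(
      obs = pda_observed_histogram(d, breaks)$count,
      n = sum(d$S_G + d$S_R > 0), dt = d$dt_s[1], cond = d$condition[1])))
  for (i in seq_along(designs))
    designs[[i]]$groups <- pool_groups(designs[[i]]$obs)

  if (length(free) == 0) stop("no free parameters")
  per_cond <- length(conds) > 1
  expand <- function(nm) {
    if (per_cond && !startsWith(nm, "E.") && nm != "donor_only")
      paste0(nm, "@", conds) else nm
  }
  par_names <- unlist(lapply(free, expand))
  init <- vapply(par_names, function(nm)
    pda_param_get(template, split_cond(nm)$base), numeric(1))
  kinds <- vapply(par_names, function(nm) pda_param_kind(split_cond(nm)$base),
                  character(1))
  to_t <- function(v) ifelse(kinds == "log", log(v),
                             stats::qlogis(pmin(pmax(v, 1e-6), 1 - 1e-6)))
  from_t <- function(z) ifelse(kinds == "log", exp(z), stats::plogis(z))
  mc_seed <- seed * 1000L + 7L

  objective <- function(z) {
    par <- as.list(stats::setNames(from_t(z), par_names))
    total <- 0
    for (d in designs) {
      m <- model_for_condition(template, par, d$cond)
      pr <- tryCatch(
        pda_predict_design(m, d$dt, d, n_grid = n_grid, n_mc = n_mc,
                           mc_seed = mc_seed, compress = compress),
        error = function(e) NULL)
      if (is.null(pr)) return(1e12)
      gE <- tapply(pr * d$n, d$groups, sum)
      gO <- tapply(d$obs, d$groups, sum)
      gE <- pmax(gE, 1e-8 * d$n)
      total <- total + sum((gO - gE)^2 / gE)
    }
    total
  }

  set.seed(seed)
  d <- length(par_names)
  starts <- list(to_t(init))
  if (n_starts > 1) {
    u <- lhs_unit(n_starts - 1, d)
    for (r in seq_len(n_starts - 1)) {
      z <- numeric(d)
      for (j in seq_len(d)) {
        z[j] <- if (kinds[j] == "log")
          log(rate_range[1]) + u[r, j] * log(rate_range[2] / rate_range[1])
        else stats::qlogis(0.05 + 0.9 * u[r, j])
      }
      starts[[r + 1]] <- z
    }
  }
  best <- NULL
  for (z0 in starts) {
    f <- stats::optim(z0, objective, method = "Nelder-Mead",
                      control = list(maxit = maxit, reltol = 1e-8))
    if (is.null(best) || f$value < best$value) best <- f
  }
  # polish the winner
  best <- stats::optim(best$par, objective, method = "Nelder-Mead",
                       control = list(maxit = maxit, reltol = 1e-10))
  par <- stats::setNames(from_t(best$par), par_names)
  parl <- as.list(par)
  models <- lapply(conds, function(cc) model_for_condition(template, parl, cc))
  names(models) <- conds
  hists <- lapply(designs, function(d) {
    m <- models[[d$cond]]
    pr <- pda_predict_design(m, d$dt, d, n_grid = n_grid, n_mc = n_mc,
                             mc_seed = mc_seed, compress = compress)
    data.frame(mid = d$mids, observed = d$obs, expected = pr * d$n,
               dt_s = d$dt, condition = d$cond)
  })
  ngroups <- sum(vapply(designs, function(d) length(unique(d$groups)),
                        numeric(1)))
  dof <- max(ngroups - length(designs) - length(par_names), 1)
  structure(list(par = par, value = best$value,
                 chisq_red = best$value / dof, models = models,
                 histograms = hists, free = free, par_names = par_names,
                 n_windows = sum(vapply(designs, `[[`, numeric(1), "n")),
                 seed = seed, template = template, breaks = breaks,
                 n_grid = n_grid, n_mc = n_mc),
            class = "pda_fit")
}

#' @export
print.pda_fit <- function(x, ...) {
  cat(sprintf("<pda_fit> chisq_red = %.3f over %d windows\n",
              x$chisq_red, x$n_windows))
  print(signif(x$par, 4))
  invisible(x)
}

#' Compare kinetic connectivities on the same data
#'
#' Fits each model template independently (same seed and settings) and
#' ranks them by global reduced chi-squared. Templates whose reduced
#' chi-squared lies within `equivalence_band` (relative) of the best are
#' flagged as statistically equivalent.
#'
#' @param data Window data (see [fit_kinetic_model()]).
#' @param templates Named list of [pda_model()] templates.
#' @param frees List of free-parameter vectors, parallel to `templates`
#'   (recycled if a single vector).
#' @param equivalence_band Relative reduced-chi-squared band (default 0.05).
#' @param ... Passed to [fit_kinetic_model()].
#' @return A list: `ranking` (data.frame model, chisq_red, rank,
#'   equivalent), `fits`.
#' @export
compare_models <- function(data, templates, frees, equivalence_band = 0.05,
                           ...) {
  stopifnot(length(templates) >= 2)
  if (is.character(frees)) frees <- list(frees)
  if (length(frees) == 1) frees <- rep(frees, length(templates))
  stopifnot(length(frees) == length(templates))
  nms <- names(templates) %||% paste0("model", seq_along(templates))
  fits <- Map(function(tm, fr) fit_kinetic_model(data, tm, fr, ...),
              templates, frees)
  cr <- vapply(fits, `[[`, numeric(1), "chisq_red")
  ord <- order(cr)
  ranking <- data.frame(model = nms[ord], chisq_red = cr[ord],
                        rank = seq_along(ord),
                        equivalent = cr[ord] <= cr[ord][1] * (1 + equivalence_band))
  list(ranking = ranking, fits = stats::setNames(fits, nms))
}

#' Subsampling uncertainties for dynPDA parameters
#'
#' Refits random subsets holding `fraction` of the windows (stratified by
#' window duration and condition) and reports the standard deviation of
#' every fitted parameter across replicates — the precision measure used
#' for the reported distances and relaxation times (s.d. between three
#' analyses of 70% subsamples).
#'
#' @param data Window data.
#' @param template,free As in [fit_kinetic_model()].
#' @param fraction Subsample fraction (default 0.7).
#' @param replicates Number of subsamples (default 3).
#' @param seed Seed for subset draws.
#' @param start_from_full Start each refit from the full-data fit (default
#'   TRUE).
#' @param ... Passed to [fit_kinetic_model()].
#' @return A list: `sd` (named), `estimates` (replicates x parameters),
#'   `full_fit`.
#' @export
subsample_uncertainty <- function(data, template, free, fraction = 0.7,
                                  replicates = 3, seed = 1L,
                                  start_from_full = TRUE, ...) {
  if (is.list(data) && !is.data.frame(data)) data <- do.call(rbind, data)
  if (is.null(data$condition)) data$condition <- "all"
  full <- fit_kinetic_model(data, template, free, seed = seed, ...)
  tmpl <- template
  if (start_from_full)
    tmpl <- model_for_condition(template, as.list(full$par),
                                data$condition[1])
  set.seed(seed + 1L)
  est <- matrix(NA_real_, replicates, length(full$par),
                dimnames = list(NULL, names(full$par)))
  fits <- vector("list", replicates)
  refit_args <- list(...)
  if (start_from_full) refit_args$n_starts <- 1
  for (r in seq_len(replicates)) {
    idx <- unlist(lapply(split(seq_len(nrow(data)),
                               list(data$dt_s, data$condition), drop = TRUE),
                         function(ii) sample(ii, round(fraction * length(ii)))))
    sub <- data[sort(idx), ]
    f <- do.call(fit_kinetic_model,
                 c(list(data = sub, template = tmpl, free = free,
                        seed = seed + r), refit_args))
    est[r, ] <- f$par[colnames(est)]
    fits[[r]] <- f
  }
  list(sd = apply(est, 2, stats::sd), estimates = est, full_fit = full,
       fits = fits)
}

#' Combined species populations per condition
#'
#' For every condition the population of species i is the static-pool
#' weight plus the dynamic pool's equilibrium occupancy
#' (branch-weight-averaged stationary laws). Populations are reported over
#' the labelled species (the donor-only contaminant is excluded and the
#' remainder renormalised); static and dynamic contributions are kept as
#' separate columns.
#'
#' @param fit A `pda_fit` (or a single [pda_model()]).
#' @return data.frame `condition`, `species`, `static`, `dynamic`, `total`;
#'   totals sum to 1 within each condition.
#' @export
species_population_summary <- function(fit) {
  models <- if (inherits(fit, "pda_fit")) fit$models
  else list(all = fit)
  out <- list()
  for (cc in names(models)) {
    m <- models[[cc]]
    sp <- m$species$name
    stat <- m$static_fraction * as.numeric(m$static_weights[sp])
    dyn <- stats::setNames(rep(0, length(sp)), sp)
    dyn_f <- 1 - m$static_fraction - m$donor_only_fraction
    for (b in seq_along(m$branches)) {
      km <- branch_kinetic_model(m, b)
      pi <- stationary_distribution(km)
      dyn[names(pi)] <- dyn[names(pi)] + dyn_f * m$branch_weights[b] * pi
    }
    tot <- stat + dyn
    scale <- sum(tot)
    out[[cc]] <- data.frame(condition = cc, species = sp,
                            static = stat / scale, dynamic = dyn / scale,
                            total = tot / scale, row.names = NULL)
  }
  do.call(rbind, out)
}
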