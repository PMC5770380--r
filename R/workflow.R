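# End-to-end orchestration of the synthetic multimodal study: simulate ->
# burst/MFD -> subensemble lifetime -> FCS -> dynPDA -> TIRF -> structure
# screen, with one global seed fanned out deterministically to per-stage
# seeds (stage_seed = 100 * seed + stage index) so any stage can be
# reproduced in isolation. Outputs are written once per stage as TSV.

#' Default workflow configuration
#'
#' A small fully synthetic study: a two-state exchange model in the
#' millisecond regime observed by bursts, correlation, PDA and camera
#' traces, plus a toy two-register structure screen.
#'
#' @param seed Global seed.
#' @param out_dir Output directory (created if missing).
#' @return A nested configuration list.
#' @export
default_workflow_config <- function(seed = 1L, out_dir = tempfile("wf")) {
  pair <- dye_pair(52, 4, "donor/acceptor")
  species <- list(fret_species("H", pair, efficiency = 0.8),
                  fret_species("L", pair, efficiency = 0.15))
  model <- kinetic_model(species, matrix(c(0, 135, 135, 0), 2, 2,
                                         byrow = TRUE))
  list(seed = as.integer(seed), out_dir = out_dir, model = model, pair = pair,
       stages = c("simulate", "bursts", "subensemble", "fcs", "pda", "tirf",
                  "screen"),
       confocal = list(burst_count = 800, mean_burst_duration = 0.004,
                       molecule_brightness = 5e4),
       subensemble = list(n_species = 2, E_min = 0.065),
       fcs = list(duration = 8, brightness = 8e4, max_lag = 0.1),
       pda = list(dts = c(0.001, 0.002, 0.003), n_windows = 4000,
                  mean_total = 50),
       tirf = list(n_traces = 60, n_frames = 900,
                   rates = c(3, 3)),  # slow s^-1 exchange visible at 100 ms
       screen = list(dR = 3))
}

stage_seed <- function(config, k) config$seed * 100L + k

wf_write <- function(report, out_dir, stage, name, df) {
  path <- file.path(out_dir, paste0(stage, "_", name, ".tsv"))
  utils::write.table(format(df, digits = 15), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  report$files <- c(report$files, path)
  report
}

#' Run the full synthetic workflow
#'
#' Executes the enabled stages in dependency order; identical configuration
#' and seed give byte-identical outputs. Stage failures stop with the
#' partial report attached to the error condition.
#'
#' @param config Configuration from [default_workflow_config()] (fields may
#'   be overridden).
#' @return A `run_report`: list with per-stage results, `files` written,
#'   `seed`, and timing.
#' @export
run_workflow <- function(config = default_workflow_config()) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  report <- list(seed = config$seed, stages = list(), files = character(0))
  model <- config$model
  pair <- config$pair
  on_fail <- function(stage, e) {
    stop(structure(class = c("workflow_error", "error", "condition"),
                   list(message = sprintf("stage '%s' failed: %s", stage,
                                          conditionMessage(e)),
                        call = NULL, report = report)))
  }
  sim <- NULL

  if ("simulate" %in% config$stages) {
    sim <- tryCatch({
      cfg <- do.call(confocal_sim_config,
                     c(config$confocal, list(seed = stage_seed(config, 1))))
      simulate_bursts(model, cfg)
    }, error = function(e) on_fail("simulate", e))
    report$stages$simulate <- list(
      n_photons = nrow(sim$stream),
      n_bursts_true = nrow(sim$truth),
      checksum = sum(sim$stream$macro_time))
    report <- wf_write(report, config$out_dir, "simulate", "truth",
                       utils::head(sim$truth, 200))
  }

  bursts <- NULL
  if ("bursts" %in% config$stages && !is.null(sim)) {
    bursts <- tryCatch({
      bs <- burst_search(sim$stream)
      burst_indicators(bs, sim$stream, sim$cfg$calib, pair)
    }, error = function(e) on_fail("bursts", e))
    report$stages$bursts <- list(
      n_bursts = nrow(bursts), mean_E = mean(bursts$E, na.rm = TRUE),
      mean_tau = mean(bursts$tau_f, na.rm = TRUE))
    report <- wf_write(report, config$out_dir, "bursts", "table",
                       bursts[, c("start", "stop", "n_photons", "F_D", "F_A",
                                  "E", "tau_f", "flag")])
  }

  if ("subensemble" %in% config$stages && !is.null(bursts)) {
    se <- tryCatch({
      sub <- select_subensemble(bursts, config$subensemble$E_min)
      dex <- donor_exc_idx(sim$stream) & sim$stream$channel == "donor"
      idx <- unlist(lapply(seq_len(nrow(sub)), function(b)
        sub$start_idx[b]:sub$stop_idx[b]))
      mic <- sim$stream$micro_time[intersect(idx, which(dex))]
      # donor-only reference measured separately (same instrument settings)
      cfg_do <- do.call(confocal_sim_config, c(
        config$confocal,
        list(seed = stage_seed(config, 3),
             calib = calibration_config(donor_only_fraction = 1))))
      ref <- simulate_bursts(model, cfg_do)
      mic_do <- ref$stream$micro_time[ref$stream$channel == "donor"]
      hF <- decay_histogram(mic, range = c(0, 15))
      hD <- decay_histogram(mic_do, range = c(0, 15))
      eps <- fret_induced_decay(hF, hD)
      fit_species_decay(eps, config$subensemble$n_species, pair)
    }, error = function(e) on_fail("subensemble", e))
    report$stages$subensemble <- list(distances = se$distance,
                                      fractions = se$fraction,
                                      chisq_red = attr(se, "chisq_red"))
    report <- wf_write(report, config$out_dir, "subensemble", "species", se)
  }

  if ("fcs" %in% config$stages) {
    fc <- tryCatch({
      stream <- simulate_cw_stream(model, config$fcs$duration,
                                   config$fcs$brightness,
                                   seed = stage_seed(config, 4))
      curves <- list(
        correlate_multitau(stream, "donor", "donor",
                           max_lag = config$fcs$max_lag),
        correlate_multitau(stream, "acceptor", "acceptor",
                           max_lag = config$fcs$max_lag),
        correlate_multitau(stream, "donor", "acceptor",
                           max_lag = config$fcs$max_lag))
      fit <- fcs_global_fit(curves, n_kinetic = 1, diffusion = FALSE)
      list(curves = curves, fit = fit)
    }, error = function(e) on_fail("fcs", e))
    report$stages$fcs <- list(
      t_R = fc$fit$t_R, chisq_red = fc$fit$chisq_red,
      cross_amplitude = fc$fit$models[[3]]$kinetic$amplitude[1])
    report <- wf_write(report, config$out_dir, "fcs", "curve_GG",
                       data.frame(lag_s = fc$curves[[1]]$lag,
                                  G = fc$curves[[1]]$G,
                                  se = fc$curves[[1]]$se))
  }

  if ("pda" %in% config$stages && !is.null(bursts)) {
    pd <- tryCatch({
      wins <- do.call(rbind, lapply(config$pda$dts, function(dt)
        slice_time_windows(bursts, sim$stream, dt)))
      sp <- data.frame(name = c("H", "L"),
                       E = species_efficiencies(model),
                       brightness = 1, sigma = 0)
      tmpl <- pda_model(sp, branches = list(list(
        states = c("H", "L"),
        rates = matrix(c(0, 500, 500, 0), 2, 2, byrow = TRUE,
                       dimnames = list(c("H", "L"), c("H", "L"))))))
      fit <- fit_kinetic_model(wins, tmpl,
                               free = c("rate.1.H.L", "rate.1.L.H"),
                               n_starts = 4, seed = stage_seed(config, 5))
      list(fit = fit,
           relax = 1 / (fit$par[["rate.1.H.L"]] + fit$par[["rate.1.L.H"]]))
    }, error = function(e) on_fail("pda", e))
    report$stages$pda <- list(par = pd$fit$par, relaxation_time = pd$relax,
                              chisq_red = pd$fit$chisq_red,
                              true_relaxation = relaxation_times(model)[1])
    report <- wf_write(report, config$out_dir, "pda", "parameters",
                       data.frame(parameter = names(pd$fit$par),
                                  value = unname(pd$fit$par)))
  }

  if ("tirf" %in% config$stages) {
    tf <- tryCatch({
      # state 1 must be the low-E (open) state for the trace simulator
      slow <- kinetic_model(rev(model$species),
                            matrix(c(0, config$tirf$rates[1],
                                     config$tirf$rates[2], 0), 2, 2,
                                   byrow = TRUE))
      cfg <- tirf_sim_config(n_traces = config$tirf$n_traces,
                             n_frames = config$tirf$n_frames,
                             seed = stage_seed(config, 6))
      ds <- simulate_tirf_traces(slow, cfg)
      sel <- select_traces(ds)
      E <- pooled_efficiencies(ds, sel)
      pops <- fit_population_gaussians(E, 2, seed = stage_seed(config, 6))
      cc <- trace_cross_correlation(ds, sel)
      list(ds = ds, sel = sel, pops = pops, cc = cc)
    }, error = function(e) on_fail("tirf", e))
    report$stages$tirf <- list(
      n_accepted = length(tf$sel$accepted),
      population_means = tf$pops$mean, population_weights = tf$pops$weight,
      cc_t_R = tf$cc$fit$t_R, cc_amplitude = tf$cc$fit$amplitude)
    report <- wf_write(report, config$out_dir, "tirf", "populations", tf$pops)
  }

  if ("screen" %in% config$stages) {
    sc <- tryCatch({
      toy <- toy_register_geometry()
      screen_toy_registers(toy, pair, dR = config$screen$dR)
    }, error = function(e) on_fail("screen", e))
    report$stages$screen <- list(ranking = sc$ranking)
    report <- wf_write(report, config$out_dir, "screen", "ranking",
                       sc$ranking)
  }

  class(report) <- "run_report"
  report
}

#' Toy two-register label geometry
#'
#' Two candidate arrangements of a pair of labelling sites around a simple
#' obstacle wall: register 1 places donor and acceptor on the same unit
#' (short distance), register 2 across units (long distance). Used for the
#' structure-screen self-test.
#'
#' @return A list with `registers`, each holding two [label_site()]s and an
#'   obstacle table.
#' @export
toy_register_geometry <- function() {
  obst <- data.frame(x = rep(seq(-12, 12, by = 3), each = 9),
                     y = rep(rep(seq(-12, 12, by = 3), each = 1), 9),
                     z = 0, radius = 1.6)
  r1 <- list(site_d = label_site(c(-10, 0, 8), linker_length = 10),
             site_a = label_site(c(10, 0, 8), linker_length = 10),
             obstacles = obst)
  r2 <- list(site_d = label_site(c(-10, 0, 8), linker_length = 10),
             site_a = label_site(c(25, 0, -8), linker_length = 10),
             obstacles = obst)
  list(registers = list(register1 = r1, register2 = r2))
}

#' Screen the toy registers against distances generated by one of them
#'
#' @param toy [toy_register_geometry()] output.
#' @param pair A [dye_pair()].
#' @param generator Which register generated the "measured" distances.
#' @param dR Measurement precision in A.
#' @param grid AV grid spacing.
#' @return List with `ranking` (from [screen_structures()]) and the model
#'   distances.
#' @export
screen_toy_registers <- function(toy, pair, generator = "register1", dR = 3,
                                 grid = 1.5) {
  dists <- lapply(toy$registers, function(r) {
    av_d <- compute_accessible_volume(r$obstacles, r$site_d, grid = grid)
    av_a <- compute_accessible_volume(r$obstacles, r$site_a, grid = grid)
    av_mean_distance(av_d, av_a)$mean
  })
  model_distances <- data.frame(
    structure = names(toy$registers), pair_id = "p1",
    R_model = unlist(dists))
  measured <- data.frame(pair_id = "p1", species = "A",
                         R_meas = dists[[generator]], dR = dR)
  list(ranking = screen_structures(model_distances, measured),
       model_distances = model_distances)
}

#' Validate a run report against tolerance-tagged expectations
#'
#' @param report A `run_report`.
#' @param expectations List of checks, each
#'   `list(path = c("stages", ...), value = <num>, tol = <num>)`.
#' @return data.frame `check`, `value`, `expected`, `tol`, `pass`;
#'   attribute `all_pass`.
#' @export
validate_report <- function(report, expectations) {
  if (length(expectations) == 0) {
    out <- data.frame(check = character(0), value = numeric(0),
                      expected = numeric(0), tol = numeric(0),
                      pass = logical(0))
    attr(out, "all_pass") <- TRUE
    return(out)
  }
  rows <- lapply(expectations, function(ex) {
    if (!is.list(ex) || is.null(ex$path) || is.null(ex$value) ||
        is.null(ex$tol))
      stop("malformed expectation: need path, value, tol")
    v <- report
    for (p in ex$path) v <- v[[p]]
    v <- as.numeric(v)[1]
    data.frame(check = paste(ex$path, collapse = "/"), value = v,
               expected = ex$value, tol = ex$tol,
               pass = is.finite(v) && abs(v - ex$value) <= ex$tol)
  })
  out <- do.call(rbind, rows)
  attr(out, "all_pass") <- all(out$pass)
  out
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("<run_report> seed %d; stages: %s\n", x$seed,
              paste(names(x$stages), collapse = ", ")))
  invisible(x)
}
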