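# Camera-trace simulator: surface-immobilised molecules imaged at fixed
# frame time (default 100 ms) with slow two-state switching, single-step
# photobleaching of either dye, optional timed injection (compaction), and
# camera-like noise (Poisson counts, gain, Gaussian read noise).

#' Configuration of the TIRF trace simulator
#'
#' @param frame_time Frame integration time in s (default 0.1).
#' @param n_frames Trace length in frames (default 1200, i.e. 120 s).
#' @param n_traces Number of traces.
#' @param total_counts Total (donor + acceptor) fluorescence per frame before
#'   bleaching, in camera counts.
#' @param bleach_rate_acceptor,bleach_rate_donor Single-step photobleaching
#'   rate constants (s^-1) per dye.
#' @param beta Donor bleed-through into the acceptor camera channel
#'   (acceptor reads `E*total + beta*donor`).
#' @param gamma Detection ratio used when converting to efficiency.
#' @param gain Camera gain applied after Poisson statistics.
#' @param shot_noise Logical: apply Poisson shot noise? Disable together
#'   with `read_noise_sd = 0` for analytically exact traces.
#' @param read_noise_sd Gaussian read noise s.d. in counts (after gain).
#' @param baseline Constant camera offset per channel, counts.
#' @param injection_time Time (s) at which a ligand/cation injection changes
#'   the kinetics, or `NULL` for steady-state runs.
#' @param responder_fraction Fraction of traces that respond to the
#'   injection by compacting.
#' @param injection_tau Mean single-molecule compaction waiting time after
#'   the injection, s (ensemble mean efficiency then approaches the compact
#'   value exponentially with this time constant).
#' @param seed Integer seed.
#' @return An object of class `tirf_sim_config`.
#' @export
tirf_sim_config <- function(frame_time = 0.1, n_frames = 1200, n_traces = 100,
                            total_counts = 1000, bleach_rate_acceptor = 1 / 40,
                            bleach_rate_donor = 1 / 30, beta = 0.1, gamma = 1,
                            gain = 1, shot_noise = TRUE, read_noise_sd = 10,
                            baseline = 0,
                            injection_time = NULL, responder_fraction = 0.65,
                            injection_tau = 1.1, seed = 1L) {
  stopifnot(frame_time > 0, n_frames >= 1, total_counts > 0,
            responder_fraction >= 0, responder_fraction <= 1)
  structure(list(frame_time = frame_time, n_frames = n_frames,
                 n_traces = n_traces, total_counts = total_counts,
                 bleach_rate_acceptor = bleach_rate_acceptor,
                 bleach_rate_donor = bleach_rate_donor, beta = beta,
                 gamma = gamma, gain = gain, shot_noise = shot_noise,
                 read_noise_sd = read_noise_sd,
                 baseline = baseline, injection_time = injection_time,
                 responder_fraction = responder_fraction,
                 injection_tau = injection_tau, seed = seed),
            class = "tirf_sim_config")
}

# per-frame mean occupancy of each state from a trajectory (vectorised):
# integral of the state-1 indicator across frame edges
frame_occupancy <- function(traj, edges) {
  jt <- c(traj$jump_times, traj$duration)
  st <- traj$states
  # cumulative time in state 1 at segment boundaries
  seg <- diff(jt)
  in1 <- as.numeric(st == 1L)
  cum1 <- c(0, cumsum(seg * in1))
  I <- function(t) {
    i <- findInterval(t, jt, rightmost.closed = TRUE)
    i <- pmin(pmax(i, 1L), length(st))
    cum1[i] + (t - jt[i]) * in1[i]
  }
  diff(I(edges)) / diff(edges)
}

#' Simulate smTIRF intensity traces
#'
#' Per frame, donor and acceptor mean counts follow the frame-averaged
#' efficiency of a slow two-state trajectory (state 1 = open/low-E,
#' state 2 = compact/high-E), anti-correlated by construction:
#' donor = (1-E)*total, acceptor = E*total + beta*donor. Single-step bleach
#' times per dye are exponential; after acceptor bleaching the donor mean
#' returns to the pre-bleach total, after donor bleaching both channels drop
#' to baseline. When `injection_time` is set, a `responder_fraction` of
#' traces switches permanently to the compact state at an exponential
#' waiting time after injection.
#'
#' @param model A two-state slow [kinetic_model()] (species 1 low-E, species
#'   2 high-E). For injection runs the pre-injection signal stays in state 1.
#' @param cfg A [tirf_sim_config()].
#' @return A list: `traces` (data.frame trace_id, frame, donor, acceptor),
#'   `truth` (per-trace: bleach frames, responder flag, switch frame,
#'   state-path summary), `frame_time`.
#' @export
simulate_tirf_traces <- function(model, cfg) {
  stopifnot(inherits(cfg, "tirf_sim_config"))
  set.seed(cfg$seed)
  nf <- cfg$n_frames; ft <- cfg$frame_time
  Ttot <- nf * ft
  Es <- species_efficiencies(model)
  if (length(Es) != 2) stop("TIRF simulator expects a two-state model")
  edges <- seq(0, Ttot, by = ft)
  out <- vector("list", cfg$n_traces)
  truth <- data.frame(trace_id = seq_len(cfg$n_traces),
                      acceptor_bleach_frame = NA_integer_,
                      donor_bleach_frame = NA_integer_,
                      responder = FALSE, switch_frame = NA_integer_,
                      acceptor_alive_at_end = TRUE)
  injection <- !is.null(cfg$injection_time)
  for (i in seq_len(cfg$n_traces)) {
    if (injection) {
      responder <- stats::runif(1) < cfg$responder_fraction
      occ1 <- rep(1, nf)  # fraction of frame in state 1 (open)
      sw <- Inf
      if (responder) {
        sw <- cfg$injection_time + stats::rexp(1, 1 / cfg$injection_tau)
        fr <- pmin(pmax((sw - edges[-length(edges)]) / ft, 0), 1)
        occ1 <- fr
      }
      truth$responder[i] <- responder
      truth$switch_frame[i] <- if (is.finite(sw)) min(floor(sw / ft) + 1L, nf)
      else NA_integer_
    } else {
      traj <- sample_trajectory(model, Ttot)
      occ1 <- frame_occupancy(traj, edges)
    }
    Ebar <- occ1 * Es[1] + (1 - occ1) * Es[2]
    tb_a <- stats::rexp(1, cfg$bleach_rate_acceptor)
    tb_d <- stats::rexp(1, cfg$bleach_rate_donor)
    donor_mean <- (1 - Ebar) * cfg$total_counts
    acc_mean <- Ebar * cfg$total_counts + cfg$beta * donor_mean
    fa <- floor(tb_a / ft) + 1L  # first fully bleached frame
    fd <- floor(tb_d / ft) + 1L
    if (fa <= nf && fa < fd) {
      idx <- fa:nf
      donor_mean[idx] <- cfg$total_counts
      acc_mean[idx] <- cfg$beta * cfg$total_counts
      truth$acceptor_bleach_frame[i] <- fa
    }
    if (fd <= nf) {
      idx <- fd:nf
      donor_mean[idx] <- 0
      acc_mean[idx] <- 0
      truth$donor_bleach_frame[i] <- fd
      if (fa > fd && fa <= nf) truth$acceptor_bleach_frame[i] <- NA_integer_
      truth$acceptor_alive_at_end[i] <- fa > nf || fa > fd
    }
    noisy <- function(mu) {
      y <- if (cfg$shot_noise) stats::rpois(nf, pmax(mu, 0)) * cfg$gain
      else mu * cfg$gain
      if (cfg$read_noise_sd > 0) y <- y + stats::rnorm(nf, 0, cfg$read_noise_sd)
      y + cfg$baseline
    }
    don <- noisy(donor_mean)
    acc <- noisy(acc_mean)
    out[[i]] <- data.frame(trace_id = i, frame = seq_len(nf),
                           donor = don, acceptor = acc)
  }
  traces <- do.call(rbind, out)
  structure(list(traces = traces, truth = truth, frame_time = ft,
                 model = model, cfg = cfg),
            class = "tirf_dataset")
}

#' Write TIRF traces and ground truth as TSV
#' @param dataset Result of [simulate_tirf_traces()].
#' @param path Trace table path; ground truth goes to `<path>.truth.tsv`.
#' @return `path`, invisibly.
#' @export
write_tirf_traces <- function(dataset, path) {
  utils::write.table(dataset$traces, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  utils::write.table(dataset$truth, paste0(path, ".truth.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a TIRF trace table (trace_id, frame, donor, acceptor)
#' @param path TSV path.
#' @param frame_time Frame time in seconds.
#' @return A `tirf_dataset` (without ground truth unless the sidecar exists).
#' @export
read_tirf_traces <- function(path, frame_time = 0.1) {
  traces <- utils::read.delim(path)
  truth <- NULL
  sidecar <- paste0(path, ".truth.tsv")
  if (file.exists(sidecar)) truth <- utils::read.delim(sidecar)
  structure(list(traces = traces, truth = truth, frame_time = frame_time),
            class = "tirf_dataset")
}
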