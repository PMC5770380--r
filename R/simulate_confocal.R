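# Confocal burst simulator: freely diffusing molecules switching among FRET
# species emit Poisson photon trains during top-hat transits. Photons are
# routed donor/acceptor according to the instantaneous species efficiency,
# the detection-efficiency ratio gamma and spectral crosstalk alpha; TCSPC
# micro-times follow the species lifetime convolved with a Gaussian IRF.

#' Calibration parameters of a (simulated) instrument
#'
#' @param alpha Spectral crosstalk: fraction of detected donor photons that
#'   are additionally registered in the acceptor channel.
#' @param gamma Detection-efficiency/quantum-yield ratio applied to the
#'   acceptor channel at routing time.
#' @param bg_donor,bg_acceptor Background count rates (counts/s) per channel.
#' @param donor_only_fraction Fraction of molecules carrying no active
#'   acceptor (E = 0 contaminant).
#' @param irf_width Gaussian IRF standard deviation in ns.
#' @param irf_offset IRF position (prompt channel) in ns.
#' @param tau_acceptor Acceptor fluorescence lifetime in ns (red-channel
#'   micro-times only; not used by any FRET indicator).
#' @return An object of class `calibration_config`.
#' @export
calibration_config <- function(alpha = 0, gamma = 1, bg_donor = 0,
                               bg_acceptor = 0, donor_only_fraction = 0,
                               irf_width = 0.25, irf_offset = 2,
                               tau_acceptor = 1.0) {
  stopifnot(alpha >= 0, alpha < 1, gamma > 0, bg_donor >= 0, bg_acceptor >= 0,
            donor_only_fraction >= 0, donor_only_fraction <= 1, irf_width >= 0)
  structure(list(alpha = alpha, gamma = gamma, bg_donor = bg_donor,
                 bg_acceptor = bg_acceptor,
                 donor_only_fraction = donor_only_fraction,
                 irf_width = irf_width, irf_offset = irf_offset,
                 tau_acceptor = tau_acceptor),
            class = "calibration_config")
}

#' Configuration of the confocal burst simulator
#'
#' @param mean_burst_duration Mean top-hat transit duration in s. Transit
#'   durations are exponential; the top-hat envelope keeps the photon
#'   statistics analytically tractable for PDA and FCS tests.
#' @param molecule_brightness Detected photon rate at focus (counts/s) for a
#'   species of relative brightness 1, donor-excitation photons.
#' @param burst_count Number of molecule transits to simulate.
#' @param mean_gap Mean background-only gap between transits, s.
#' @param calib A [calibration_config()].
#' @param pie Logical: simulate pulsed interleaved excitation (acceptor
#'   excitation slots carrying direct acceptor photons)?
#' @param direct_ratio Direct acceptor-excitation photon rate relative to
#'   `molecule_brightness` (dual-labelled molecules only).
#' @param period_ns,slot_offset_ns PIE timing (see [photon_stream()]).
#' @param seed Integer seed.
#' @return An object of class `confocal_sim_config`.
#' @export
confocal_sim_config <- function(mean_burst_duration = 0.003,
                                molecule_brightness = 5e4,
                                burst_count = 2000, mean_gap = 0.01,
                                calib = calibration_config(), pie = FALSE,
                                direct_ratio = 1, period_ns = 31.25,
                                slot_offset_ns = 15.625, seed = 1L) {
  stopifnot(mean_burst_duration > 0, molecule_brightness > 0, burst_count >= 1,
            mean_gap >= 0)
  structure(list(mean_burst_duration = mean_burst_duration,
                 molecule_brightness = molecule_brightness,
                 burst_count = burst_count, mean_gap = mean_gap,
                 calib = calib, pie = pie, direct_ratio = direct_ratio,
                 period_ns = period_ns, slot_offset_ns = slot_offset_ns,
                 seed = seed),
            class = "confocal_sim_config")
}

# Donor-excited photon goes to the acceptor channel with this probability:
# gamma scales acceptor-channel detection at routing time.
route_red_prob <- function(E, gamma) gamma * E / (gamma * E + (1 - E))

#' Simulate diffusing-molecule photon bursts
#'
#' Each molecule transit is a top-hat intensity envelope of exponential
#' duration. Within a transit the molecule follows a Gillespie trajectory of
#' the kinetic model (or a frozen state for the static subpopulation), and
#' photons are emitted as a Poisson process thinned by the instantaneous
#' species brightness. Routing applies `gamma` at detection, then crosstalk
#' registers extra acceptor-channel counts with probability `alpha` per
#' donor-channel photon (mirroring the correction
#' \eqn{F_A = S_R - bg - \alpha F_D} used in burst analysis). A
#' `donor_only_fraction` of molecules emits with E = 0. Under PIE,
#' acceptor-excitation slots carry direct acceptor photons for dual-labelled
#' molecules, enabling stoichiometry. Per-channel Poisson background spans
#' the full acquisition.
#'
#' @param model A [kinetic_model()] whose species carry efficiencies.
#' @param cfg A [confocal_sim_config()].
#' @return A list: `stream` ([photon_stream()] with an `origin` column),
#'   `truth` (per-burst data.frame: start/stop, molecule class, true
#'   time-averaged efficiency, state occupancies) and `model`.
#' @export
simulate_bursts <- function(model, cfg) {
  stopifnot(inherits(model, "kinetic_model"), inherits(cfg, "confocal_sim_config"))
  if (n_states(model) < 1) stop("empty species list")
  set.seed(cfg$seed)
  calib <- cfg$calib
  S <- n_states(model)
  Es <- species_efficiencies(model)
  taus <- vapply(model$species, function(s) s$tau_DA, numeric(1))
  brs <- species_brightness(model)
  bmax <- max(brs)

  n <- cfg$burst_count
  dur <- stats::rexp(n, 1 / cfg$mean_burst_duration)
  gaps <- stats::rexp(n, 1 / max(cfg$mean_gap, 1e-12))
  starts <- cumsum(gaps + c(0, dur[-n]))
  stops <- starts + dur
  total_T <- stops[n] + cfg$mean_gap

  donor_only <- stats::runif(n) < calib$donor_only_fraction
  static <- stats::runif(n) < model$static_fraction
  sw <- model$static_weights %||%
    (if (S == 1) 1 else stationary_distribution(model))

  res_t <- vector("list", n); res_ch <- vector("list", n)
  res_mic <- vector("list", n); res_slot <- vector("list", n)
  res_org <- vector("list", n)
  truth <- data.frame(burst = seq_len(n), start = starts, stop = stops,
                      donor_only = donor_only, static = static,
                      true_E = NA_real_, n_signal = 0L)
  occ <- matrix(0, n, S, dimnames = list(NULL, species_names(model)))

  for (b in seq_len(n)) {
    d <- dur[b]
    # state path during the transit
    if (donor_only[b] || S == 1) {
      jt <- 0; st <- 1L
      frac <- if (donor_only[b]) rep(0, S) else replace(rep(0, S), 1, 1)
    } else if (static[b]) {
      st <- sample.int(S, 1, prob = sw); jt <- 0
      frac <- replace(rep(0, S), st, 1)
    } else {
      tr <- sample_trajectory(model, d)
      jt <- tr$jump_times; st <- tr$states
      seg <- diff(c(jt, d))
      frac <- vapply(seq_len(S), function(s) sum(seg[st == s]), numeric(1)) / d
    }
    occ[b, ] <- frac
    if (donor_only[b]) {
      Eb <- 0
    } else {
      bw <- frac * brs
      Eb <- if (sum(bw) > 0) sum(bw * Es) / sum(bw) else 0
    }
    truth$true_E[b] <- Eb

    # photon emission: homogeneous at bmax * brightness, thinned per state
    N0 <- stats::rpois(1, cfg$molecule_brightness * bmax * d)
    if (N0 > 0) {
      tt <- sort(stats::runif(N0, 0, d))
      if (donor_only[b]) {
        # no acceptor: E = 0, donor decays with the unquenched lifetime
        keep <- rep(TRUE, N0)
        Ep <- rep(0, N0)
        taup <- rep(tau0_of(model), N0)
      } else {
        sp <- if (length(st) == 1L) rep(st, N0)
        else st[findInterval(tt, jt)]
        keep <- stats::runif(N0) < brs[sp] / bmax
        Ep <- Es[sp]; taup <- taus[sp]
      }
      tt <- tt[keep]; Ep <- Ep[keep]; taup <- taup[keep]
      Np <- length(tt)
      if (Np > 0) {
        red <- stats::runif(Np) < route_red_prob(Ep, calib$gamma)
        mic <- numeric(Np)
        mic[!red] <- draw_micro_tau(taup[!red], calib, cfg$period_ns)
        mic[red] <- draw_micro_tau(rep(calib$tau_acceptor, sum(red)), calib,
                                   cfg$period_ns)
        ch <- ifelse(red, "acceptor", "donor")
        org <- rep("signal", Np)
        # crosstalk: donor-channel photons register extra acceptor counts
        if (calib$alpha > 0) {
          gi <- which(!red)
          xc <- gi[stats::runif(length(gi)) < calib$alpha]
          if (length(xc)) {
            tt <- c(tt, tt[xc]); mic <- c(mic, mic[xc])
            ch <- c(ch, rep("acceptor", length(xc)))
            org <- c(org, rep("crosstalk", length(xc)))
          }
        }
        slot <- rep(if (cfg$pie) "donor_exc" else "none", length(tt))
        # PIE: direct acceptor excitation for dual-labelled molecules
        if (cfg$pie && !donor_only[b]) {
          Nd <- stats::rpois(1, cfg$molecule_brightness * cfg$direct_ratio * d)
          if (Nd > 0) {
            td <- stats::runif(Nd, 0, d)
            md <- (draw_micro_tau(rep(calib$tau_acceptor, Nd), calib,
                                  cfg$slot_offset_ns) + cfg$slot_offset_ns)
            tt <- c(tt, td); mic <- c(mic, md)
            ch <- c(ch, rep("acceptor", Nd))
            org <- c(org, rep("direct", Nd))
            slot <- c(slot, rep("acceptor_exc", Nd))
          }
        }
        o <- order(tt)
        res_t[[b]] <- starts[b] + tt[o]
        res_mic[[b]] <- mic[o]
        res_ch[[b]] <- ch[o]
        res_slot[[b]] <- slot[o]
        res_org[[b]] <- org[o]
        truth$n_signal[b] <- Np
      }
    }
  }

  mt <- unlist(res_t); mic <- unlist(res_mic); ch <- unlist(res_ch)
  slot <- unlist(res_slot); org <- unlist(res_org)

  # background photons across the whole acquisition
  for (bgch in c("donor", "acceptor")) {
    rate <- if (bgch == "donor") calib$bg_donor else calib$bg_acceptor
    if (rate > 0) {
      Nb <- stats::rpois(1, rate * total_T)
      if (Nb > 0) {
        tb <- stats::runif(Nb, 0, total_T)
        mb <- stats::runif(Nb, 0, cfg$period_ns)
        sb <- if (cfg$pie)
          ifelse(mb >= cfg$slot_offset_ns, "acceptor_exc", "donor_exc")
        else rep("none", Nb)
        mt <- c(mt, tb); mic <- c(mic, mb); ch <- c(ch, rep(bgch, Nb))
        slot <- c(slot, sb); org <- c(org, rep("background", Nb))
      }
    }
  }

  o <- order(mt)
  stream <- photon_stream(mt[o], pmin(mic[o], cfg$period_ns * (1 - 1e-12)),
                          ch[o], slot[o], period_ns = cfg$period_ns,
                          slot_offset_ns = cfg$slot_offset_ns,
                          origin = org[o])
  truth <- cbind(truth, occ)
  list(stream = stream, truth = truth, model = model, cfg = cfg)
}

# species-lifetime micro-times with per-photon tau
draw_micro_tau <- function(tau, calib, period) {
  n <- length(tau)
  if (n == 0) return(numeric(0))
  m <- stats::rexp(n, 1 / tau) + stats::rnorm(n, calib$irf_offset, calib$irf_width)
  m %% period
}

tau0_of <- function(model) {
  p <- model$species[[1]]$pair
  if (!is.null(p)) p$tau0 else model$species[[1]]$tau_DA / (1 - model$species[[1]]$E)
}

#' Simulate a continuous (immobilised/CW) photon stream
#'
#' A single molecule observed continuously for `duration` seconds: a
#' two-state (or larger) telegraph source whose donor/acceptor routing
#' follows the instantaneous species efficiency. This is the reference
#' source for fluorescence correlation tests, where the kinetic exchange
#' appears as an exponential relaxation term with the model's relaxation
#' time.
#'
#' @param model A [kinetic_model()].
#' @param duration Acquisition length in s.
#' @param brightness Detected photon rate (counts/s) at relative
#'   brightness 1.
#' @param calib A [calibration_config()].
#' @param seed Integer seed.
#' @param period_ns Excitation period for micro-times.
#' @return A [photon_stream()] (slot = "none").
#' @export
simulate_cw_stream <- function(model, duration, brightness,
                               calib = calibration_config(), seed = 1L,
                               period_ns = 31.25) {
  set.seed(seed)
  Es <- species_efficiencies(model)
  taus <- vapply(model$species, function(s) s$tau_DA, numeric(1))
  brs <- species_brightness(model)
  bmax <- max(brs)
  tr <- sample_trajectory(model, duration)
  N0 <- stats::rpois(1, brightness * bmax * duration)
  tt <- sort(stats::runif(N0, 0, duration))
  sp <- if (length(tr$states) == 1L) rep(tr$states, N0)
  else tr$states[findInterval(tt, tr$jump_times)]
  keep <- stats::runif(N0) < brs[sp] / bmax
  tt <- tt[keep]; sp <- sp[keep]
  red <- stats::runif(length(tt)) < route_red_prob(Es[sp], calib$gamma)
  mic <- numeric(length(tt))
  mic[!red] <- draw_micro_tau(taus[sp[!red]], calib, period_ns)
  mic[red] <- draw_micro_tau(rep(calib$tau_acceptor, sum(red)), calib, period_ns)
  ch <- ifelse(red, "acceptor", "donor")
  org <- rep("signal", length(tt))
  if (calib$alpha > 0) {
    gi <- which(!red)
    xc <- gi[stats::runif(length(gi)) < calib$alpha]
    if (length(xc)) {
      tt <- c(tt, tt[xc]); mic <- c(mic, mic[xc])
      ch <- c(ch, rep("acceptor", length(xc)))
      org <- c(org, rep("crosstalk", length(xc)))
    }
  }
  for (bgch in c("donor", "acceptor")) {
    rate <- if (bgch == "donor") calib$bg_donor else calib$bg_acceptor
    if (rate > 0) {
      Nb <- stats::rpois(1, rate * duration)
      tt <- c(tt, stats::runif(Nb, 0, duration))
      mic <- c(mic, stats::runif(Nb, 0, period_ns))
      ch <- c(ch, rep(bgch, Nb)); org <- c(org, rep("background", Nb))
    }
  }
  o <- order(tt)
  photon_stream(tt[o], mic[o], ch[o], rep("none", length(tt)),
                period_ns = period_ns, origin = org[o])
}
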