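# Dynamic photon distribution analysis (dynPDA). Shot-noise-limited
# proximity-ratio histograms are predicted exactly from a kinetic model:
# conditional on the total photons in a fixed time window, the acceptor
# count is binomial at the species detection probability; exchanging
# molecules integrate the binomial over the occupancy-time law of the
# window (analytic for two-state branches, seeded Monte-Carlo otherwise).
# Fitting minimises summed Pearson chi-squared across window durations and
# conditions; kinetic connectivities are compared by reduced chi-squared and
# uncertainties estimated by refitting 70% subsamples.

#' Construct a dynPDA model
#'
#' The kinetic scheme is a weighted mixture of irreducible branches, which
#' represents connectivities like the two-register chromatin scheme (one
#' branch A-C-D, a second branch B-D) where the two dynamic subpopulations
#' do not interchange on the observation timescale. On top of the dynamic
#' pool sit a non-exchanging (static/locked) subpopulation with its own
#' state weights and a donor-only (E = 0) contaminant.
#'
#' @param species data.frame with columns `name`, `E`, optionally
#'   `brightness` (default 1), `R` and `sigma` (apparent distance width, A;
#'   needs `pair` to act).
#' @param branches List of branches; each `list(states = <species names>,
#'   rates = <matrix of off-diagonal rates, s^-1>)`.
#' @param branch_weights Probabilities of a dynamic molecule belonging to
#'   each branch (default uniform).
#' @param static_fraction Fraction of all labelled molecules that never
#'   exchange.
#' @param static_weights State probabilities of the static pool (default:
#'   population-weighted stationary laws of the branches).
#' @param donor_only_fraction Fraction of molecules with E = 0.
#' @param calib A [calibration_config()] (alpha, gamma, backgrounds).
#' @param pair Optional [dye_pair()] used for distance broadening.
#' @return An object of class `pda_model`.
#' @export
pda_model <- function(species, branches, branch_weights = NULL,
                      static_fraction = 0, static_weights = NULL,
                      donor_only_fraction = 0,
                      calib = calibration_config(), pair = NULL) {
  if (!is.data.frame(species)) {
    species <- data.frame(
      name = vapply(species, function(s) s$name, character(1)),
      E = vapply(species, function(s) s$E, numeric(1)),
      brightness = vapply(species, function(s) s$brightness %||% 1, numeric(1)))
  }
  if (is.null(species$brightness)) species$brightness <- 1
  if (is.null(species$sigma)) species$sigma <- 0
  branches <- lapply(branches, function(b) {
    st <- b$states
    stopifnot(all(st %in% species$name))
    r <- as.matrix(b$rates)
    stopifnot(nrow(r) == length(st), ncol(r) == length(st))
    dimnames(r) <- list(st, st)
    diag(r) <- 0
    list(states = st, rates = r)
  })
  B <- length(branches)
  if (is.null(branch_weights)) branch_weights <- rep(1 / B, B)
  branch_weights <- branch_weights / sum(branch_weights)
  m <- structure(list(species = species, branches = branches,
                      branch_weights = branch_weights,
                      static_fraction = static_fraction,
                      static_weights = static_weights,
                      donor_only_fraction = donor_only_fraction,
                      calib = calib, pair = pair),
                 class = "pda_model")
  if (is.null(static_weights)) m$static_weights <- default_static_weights(m)
  m
}

branch_kinetic_model <- function(model, b) {
  br <- model$branches[[b]]
  kinetic_model(br$states, br$rates)
}

default_static_weights <- function(model) {
  sw <- stats::setNames(rep(0, nrow(model$species)), model$species$name)
  for (b in seq_along(model$branches)) {
    km <- branch_kinetic_model(model, b)
    pi <- stationary_distribution(km)
    sw[names(pi)] <- sw[names(pi)] + model$branch_weights[b] * pi
  }
  sw / sum(sw)
}

# Probability that a registered donor-excitation count falls in the acceptor
# channel, for true efficiency E under gamma and crosstalk alpha (crosstalk
# counts are additional registrations, matching the burst corrections).
pr_detection_prob <- function(E, gamma, alpha) {
  q <- gamma * E / (gamma * E + (1 - E))
  (q + (1 - q) * alpha) / (1 + (1 - q) * alpha)
}

# Discrete distribution of the acceptor-count probability p over the
# model's mixture components: data.frame(p, weight), weights sum to 1.
pda_p_mixture <- function(model, dt, n_grid = 101, n_mc = 10000,
                          mc_seed = 101L, compress = NULL) {
  sp <- model$species
  al <- model$calib$alpha; ga <- model$calib$gamma
  p_sp <- pr_detection_prob(sp$E, ga, al)
  ps <- numeric(0); ws <- numeric(0)
  dyn_f <- 1 - model$static_fraction - model$donor_only_fraction
  if (model$donor_only_fraction > 0) {
    ps <- c(ps, pr_detection_prob(0, ga, al))
    ws <- c(ws, model$donor_only_fraction)
  }
  if (model$static_fraction > 0) {
    broad <- broadened_p(model)
    ps <- c(ps, broad$p)
    ws <- c(ws, model$static_fraction * broad$w)
  }
  if (dyn_f > 0) {
    for (b in seq_along(model$branches)) {
      br <- model$branches[[b]]
      idx <- match(br$states, sp$name)
      brs <- sp$brightness[idx]
      pb <- p_sp[idx]
      wb <- dyn_f * model$branch_weights[b]
      if (length(idx) == 2) {
        km <- branch_kinetic_model(model, b)
        g <- occupancy_fraction_grid(km, dt, n_grid = n_grid)
        x <- g$x
        num <- x * brs[1] * pb[1] + (1 - x) * brs[2] * pb[2]
        den <- x * brs[1] + (1 - x) * brs[2]
        pj <- num / den
        wj <- g$prob
        if (!is.null(compress) && length(pj) > compress + 2) {
          # collapse the interior of the occupancy cloud onto equal-mass
          # nodes (weighted-mean p per node); the no-transition endpoint
          # masses stay as distinct nodes. Used by the fitting path, where
          # the residual discretisation error is far below counting noise.
          ii <- 2:(length(pj) - 1)
          wi <- wj[ii]; pi_ <- pj[ii]
          if (sum(wi) > 0) {
            cw <- cumsum(wi) / sum(wi)
            cl <- pmin(floor(cw * compress) + 1L, compress)
            wcl <- as.vector(rowsum(wi, cl))
            pcl <- as.vector(rowsum(wi * pi_, cl)) / wcl
            pj <- c(pj[1], pcl, pj[length(pj)])
            wj <- c(wj[1], wcl, wj[length(wj)])
          }
        }
        ps <- c(ps, pj)
        ws <- c(ws, wb * wj)
      } else {
        km <- branch_kinetic_model(model, b)
        frac <- with_preserved_rng(mc_seed, {
          occupancy_fraction_sample(km, dt, n_mc)
        })
        num <- frac %*% (brs * pb)
        den <- frac %*% brs
        pj <- as.vector(num / den)
        # compact the Monte-Carlo cloud onto a regular p-grid
        edges <- seq(0, 1, length.out = 201)
        ix <- pmin(pmax(findInterval(pj, edges, rightmost.closed = TRUE), 1),
                   200)
        cnt <- tabulate(ix, nbins = 200)
        keep <- cnt > 0
        mids <- (edges[-1] + edges[-201])[keep] / 2
        # use the within-bin mean p for accuracy
        pm <- vapply(which(keep), function(k) mean(pj[ix == k]), numeric(1))
        ps <- c(ps, pm)
        ws <- c(ws, wb * cnt[keep] / sum(cnt))
      }
    }
  }
  data.frame(p = ps, weight = ws / sum(ws) * sum(c(model$donor_only_fraction,
                                                   model$static_fraction,
                                                   dyn_f)))
}

# static-species p values with optional Gaussian distance broadening
broadened_p <- function(model) {
  sp <- model$species
  al <- model$calib$alpha; ga <- model$calib$gamma
  sw <- model$static_weights[sp$name]
  ps <- numeric(0); ws <- numeric(0)
  for (i in seq_len(nrow(sp))) {
    if (sw[i] <= 0) next
    if (!is.null(model$pair) && sp$sigma[i] > 0 && !is.na(sp$R[i])) {
      gh <- gauss_hermite7()
      R <- sp$R[i] + sqrt(2) * sp$sigma[i] * gh$x
      R <- pmax(R, 1)
      E <- efficiency_from_distance(R, model$pair)
      ps <- c(ps, pr_detection_prob(E, ga, al))
      ws <- c(ws, sw[i] * gh$w / sqrt(pi))
    } else {
      ps <- c(ps, pr_detection_prob(sp$E[i], ga, al))
      ws <- c(ws, sw[i])
    }
  }
  list(p = ps, w = ws / sum(ws))
}

gauss_hermite7 <- function() {
  list(x = c(-2.651961356835233, -1.673551628767471, -0.8162878828589647, 0,
             0.8162878828589647, 1.673551628767471, 2.651961356835233),
       w = c(0.0009717812450995192, 0.05451558281912703, 0.4256072526101278,
             0.8102646175568073, 0.4256072526101278, 0.05451558281912703,
             0.0009717812450995192))
}

with_preserved_rng <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  set.seed(seed)
  out <- force(expr)
  if (had) assign(".Random.seed", old, envir = globalenv())
  out
}

#' Slice bursts into fixed photon-count time windows
#'
#' Each burst is cut into consecutive non-overlapping windows of exactly
#' `dt` seconds starting at the burst start; the trailing remainder is
#' discarded. Donor-excitation photons are counted per window and channel.
#'
#' @param bursts Burst table ([burst_search()] output, possibly populated).
#' @param stream The [photon_stream()].
#' @param dt Window duration in s.
#' @param condition Optional condition label attached to all windows.
#' @return data.frame `burst_id`, `window_idx`, `S_G`, `S_R`, `dt_s`,
#'   `condition`.
#' @export
slice_time_windows <- function(bursts, stream, dt, condition = "all") {
  stopifnot(dt > 0)
  res <- vector("list", nrow(bursts))
  dex <- donor_exc_idx(stream)
  is_d <- stream$channel == "donor"
  t <- stream$macro_time
  for (b in seq_len(nrow(bursts))) {
    idx <- bursts$start_idx[b]:bursts$stop_idx[b]
    idx <- idx[dex[idx]]
    nw <- floor((bursts$stop[b] - bursts$start[b]) / dt)
    if (nw < 1) next
    w <- floor((t[idx] - bursts$start[b]) / dt) + 1L
    keep <- w >= 1 & w <= nw
    w <- w[keep]; di <- is_d[idx][keep]
    sg <- tabulate(w[di], nbins = nw)
    sr <- tabulate(w[!di], nbins = nw)
    res[[b]] <- data.frame(burst_id = bursts$start_idx[b], window_idx = 1:nw,
                           S_G = sg, S_R = sr)
  }
  out <- do.call(rbind, res[!vapply(res, is.null, logical(1))])
  if (is.null(out))
    out <- data.frame(burst_id = integer(0), window_idx = integer(0),
                      S_G = integer(0), S_R = integer(0))
  out$dt_s <- dt
  out$condition <- condition
  out
}

#' Predict the proximity-ratio histogram of a dynPDA model
#'
#' Conditional on each observed total count `n`, the acceptor count is a
#' mixture of binomials over the model's component detection probabilities:
#' static species split photons binomially, exchanging branches integrate
#' over the occupancy-time law (analytic two-state density or seeded
#' Monte-Carlo), the donor-only component sits at E = 0, and per-channel
#' Poisson background counts are convolved in when background rates are
#' nonzero. The output is a probability histogram over the uncorrected
#' proximity ratio S_R/(S_G+S_R).
#'
#' @param model A [pda_model()].
#' @param dt Window duration, s.
#' @param total_counts Integer vector: empirical total photons per window
#'   (donor-excitation counts, background included).
#' @param breaks Proximity-ratio bin edges (default 51 bins of width 0.02).
#' @param n_grid Occupancy grid size for two-state branches.
#' @param n_mc Monte-Carlo trajectories for larger branches.
#' @param mc_seed Seed of the Monte-Carlo occupancy kernel.
#' @return data.frame `mid`, `prob` (sums to 1), with `breaks` attribute.
#' @export
pda_predict_histogram <- function(model, dt, total_counts,
                                  breaks = seq(0, 1, by = 0.02),
                                  n_grid = 101, n_mc = 10000,
                                  mc_seed = 101L) {
  design <- pda_design(total_counts, breaks)
  prob <- pda_predict_design(model, dt, design, n_grid = n_grid, n_mc = n_mc,
                             mc_seed = mc_seed)
  out <- data.frame(mid = design$mids, prob = prob)
  attr(out, "breaks") <- breaks
  out
}

# Precompute the reusable parts of a prediction: unique totals (optionally
# pooled into count classes), weights, and per-total cumulative bin-edge
# counts so that per-bin probabilities come from pbinom differences.
pda_design <- function(total_counts, breaks, n_classes = Inf) {
  total_counts <- total_counts[total_counts > 0]
  tab <- table(total_counts)
  ns <- as.integer(names(tab))
  wN <- as.numeric(tab) / sum(tab)
  if (is.finite(n_classes) && length(ns) > n_classes) {
    grp <- cut(cumsum(wN), breaks = seq(0, 1, length.out = n_classes + 1),
               include.lowest = TRUE, labels = FALSE)
    ns2 <- as.integer(round(tapply(ns * wN, grp, sum) /
                              tapply(wN, grp, sum)))
    wN2 <- as.numeric(tapply(wN, grp, sum))
    ns <- ns2; wN <- wN2
  }
  kmax <- lapply(ns, function(n) {
    # bin j covers PR in [b_j, b_{j+1}) (last bin right-closed): count
    # edges must reproduce findInterval's floating-point comparisons so
    # predictions and observed histograms share one binning
    pr <- (0:n) / n
    ke <- vapply(breaks, function(b) sum(pr < b), integer(1)) - 1L
    ke[length(ke)] <- n
    ke
  })
  list(ns = ns, wN = wN, kmax = kmax, breaks = breaks,
       mids = (breaks[-1] + breaks[-length(breaks)]) / 2,
       nbin = length(breaks) - 1L)
}

pda_predict_design <- function(model, dt, design, n_grid = 101, n_mc = 10000,
                               mc_seed = 101L, compress = NULL) {
  mix <- pda_p_mixture(model, dt, n_grid = n_grid, n_mc = n_mc,
                       mc_seed = mc_seed, compress = compress)
  lam_g <- model$calib$bg_donor * dt
  lam_r <- model$calib$bg_acceptor * dt
  J <- nrow(mix)
  nb <- design$nbin
  nk <- nb + 1L
  # Background handling: acceptor-background counts shift the acceptor
  # count directly, so they are convolved exactly (Poisson sum over br,
  # truncated below 1e-7 and renormalised). Donor-background counts only
  # dilute the green channel; they are folded in by deflating each
  # component's detection probability so that the conditional mean of S_R
  # stays exact, with a variance error of order lambda_g p^2 (far below
  # counting noise). All (class, br) rows are stacked into one pbinom
  # call; the whole prediction is two vectorised kernels.
  rmax <- if (lam_r > 0) stats::qpois(1 - 1e-7, lam_r) else 0L
  wbr <- stats::dpois(0:rmax, lam_r)
  keep_br <- which(wbr >= 1e-7) - 1L
  wbr <- wbr[keep_br + 1L]
  R <- length(design$ns) * length(keep_br)
  KE <- integer(R * nk); NS <- integer(R)
  WR <- numeric(R); UU <- integer(R)
  r <- 0L
  for (u in seq_along(design$ns)) {
    n <- design$ns[u]
    ke <- design$kmax[[u]]
    for (bi in seq_along(keep_br)) {
      br <- keep_br[bi]
      if (br > n) next
      r <- r + 1L
      nsig <- n - br
      KE[((r - 1L) * nk + 1L):(r * nk)] <- pmin(pmax(ke - br, -1L), nsig)
      NS[r] <- nsig
      WR[r] <- design$wN[u] * wbr[bi]
      UU[r] <- u
    }
  }
  KE <- KE[seq_len(r * nk)]; NS <- NS[seq_len(r)]
  WR <- WR[seq_len(r)]; UU <- UU[seq_len(r)]
  NSl <- rep(NS, each = nk)
  defl <- if (lam_g > 0) (NSl - lam_g) / pmax(NSl, 1) else 1
  # one stacked evaluation over rows x mixture components
  CUM <- numeric(r * nk)
  for (j in seq_len(J)) {
    CUM <- CUM + mix$weight[j] *
      stats::pbinom(KE, NSl, pmax(mix$p[j] * defl, 0))
  }
  M <- matrix(CUM, nk, r)
  masses <- M[-1L, , drop = FALSE] - M[-nk, , drop = FALSE]
  hist <- as.vector(masses %*% WR)
  # renormalise per class over the truncated br sum
  hist / sum(hist)
}

#' Simulate photon-count windows directly from a dynPDA model
#'
#' Window-level Monte-Carlo: each window draws its component (donor-only,
#' static species, or an exchanging branch with a Gillespie occupancy),
#' its total count from a Poisson law, and splits photons binomially at the
#' component's detection probability; per-channel Poisson background counts
#' are added. This is the brute-force oracle for
#' [pda_predict_histogram()] and the generator for parameter-recovery
#' studies.
#'
#' @param model A [pda_model()].
#' @param dt Window duration, s.
#' @param n_windows Number of windows.
#' @param mean_total Mean fluorescence photons per window (species of
#'   brightness 1).
#' @param seed Integer seed.
#' @param condition Condition label.
#' @return Window data.frame as in [slice_time_windows()].
#' @export
simulate_pda_windows <- function(model, dt, n_windows, mean_total = 50,
                                 seed = 1L, condition = "all") {
  set.seed(seed)
  sp <- model$species
  al <- model$calib$alpha; ga <- model$calib$gamma
  p_sp <- pr_detection_prob(sp$E, ga, al)
  dyn_f <- 1 - model$static_fraction - model$donor_only_fraction
  u <- stats::runif(n_windows)
  comp <- ifelse(u < model$donor_only_fraction, 0L,
                 ifelse(u < model$donor_only_fraction + model$static_fraction,
                        -1L, 1L))
  p <- numeric(n_windows)
  bright <- rep(1, n_windows)
  # donor-only
  p[comp == 0L] <- pr_detection_prob(0, ga, al)
  # static species
  ns <- sum(comp == -1L)
  if (ns > 0) {
    si <- sample.int(nrow(sp), ns, replace = TRUE,
                     prob = model$static_weights[sp$name])
    p[comp == -1L] <- p_sp[si]
    bright[comp == -1L] <- sp$brightness[si]
  }
  # exchanging branches
  nd <- sum(comp == 1L)
  if (nd > 0) {
    bsel <- sample.int(length(model$branches), nd, replace = TRUE,
                       prob = model$branch_weights)
    pj <- numeric(nd); bj <- numeric(nd)
    for (b in seq_along(model$branches)) {
      ii <- which(bsel == b)
      if (!length(ii)) next
      km <- branch_kinetic_model(model, b)
      idx <- match(model$branches[[b]]$states, sp$name)
      frac <- occupancy_fraction_sample(km, dt, length(ii))
      num <- frac %*% (sp$brightness[idx] * p_sp[idx])
      den <- frac %*% sp$brightness[idx]
      pj[ii] <- num / den
      bj[ii] <- den
    }
    p[comp == 1L] <- pj
    bright[comp == 1L] <- bj
  }
  ntot <- stats::rpois(n_windows, mean_total * bright)
  sr <- stats::rbinom(n_windows, ntot, p)
  sg <- ntot - sr
  if (model$calib$bg_donor > 0)
    sg <- sg + stats::rpois(n_windows, model$calib$bg_donor * dt)
  if (model$calib$bg_acceptor > 0)
    sr <- sr + stats::rpois(n_windows, model$calib$bg_acceptor * dt)
  data.frame(burst_id = seq_len(n_windows), window_idx = 1L,
             S_G = sg, S_R = sr, dt_s = dt, condition = condition)
}

#' Observed proximity-ratio histogram of window data
#' @param windows Window data.frame (`S_G`, `S_R`).
#' @param breaks Bin edges.
#' @return data.frame `mid`, `count`.
#' @export
pda_observed_histogram <- function(windows, breaks = seq(0, 1, by = 0.02)) {
  n <- windows$S_G + windows$S_R
  keep <- n > 0
  pr <- windows$S_R[keep] / n[keep]
  i <- findInterval(pr, breaks, rightmost.closed = TRUE)
  i <- pmin(pmax(i, 1L), length(breaks) - 1L)
  data.frame(mid = (breaks[-1] + breaks[-length(breaks)]) / 2,
             count = tabulate(i, nbins = length(breaks) - 1L))
}
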