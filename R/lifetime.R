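# Subensemble fluorescence lifetime analysis: the FRET-induced donor decay
# epsilon_D(t) is the donor decay of the FRET subensemble divided by a
# donor-only reference decay. For a discrete set of FRET species with
# molecule fractions x_i it is a multi-exponential
#   epsilon_D(t) = sum_i x_i exp(-k_i t),  k_i = (R0/R_i)^6 / tau0,
# because each species' donor decay rate is 1/tau0 + k_i and the common
# radiative amplitude cancels in the ratio. The instrument response largely
# cancels in the ratio as well, which keeps the fit model IRF-free.

#' Histogram TCSPC micro-times into a decay
#'
#' @param micro_times Micro-times in ns.
#' @param bin_width Bin width in ns (default 0.05).
#' @param range Micro-time range covered, ns.
#' @return An object of class `decay_histogram`: `edges`, `centers`,
#'   `counts`, `total`.
#' @export
decay_histogram <- function(micro_times, bin_width = 0.05, range = c(0, 25)) {
  edges <- seq(range[1], range[2], by = bin_width)
  idx <- findInterval(micro_times, edges, rightmost.closed = TRUE)
  keep <- idx >= 1 & idx <= length(edges) - 1
  counts <- tabulate(idx[keep], nbins = length(edges) - 1)
  structure(list(edges = edges, centers = (edges[-1] + edges[-length(edges)]) / 2,
                 counts = counts, total = sum(counts)),
            class = "decay_histogram")
}

#' FRET-induced donor decay
#'
#' Divides the donor decay of the FRET subensemble by a donor-only
#' reference decay sharing the same binning, normalises so that the value
#' extrapolated to time zero is 1, and masks bins where the reference has
#' fewer than `count_floor` counts. The time axis is shifted by
#' `irf_offset` so that t = 0 is the excitation prompt; bins earlier than
#' `t_min` after the prompt (where the IRF does not cancel) are excluded.
#'
#' @param fret_decay [decay_histogram()] of the FRET sample donor channel.
#' @param donor_only_decay [decay_histogram()] of the donor-only reference.
#' @param irf_offset Prompt position in ns.
#' @param irf_width Gaussian IRF standard deviation in ns. The IRF largely
#'   cancels in the ratio; the remaining per-component amplitude factor
#'   \eqn{e^{\sigma^2(a_i^2 - a_0^2)/2}} and the prompt-edge error-function
#'   are modelled exactly when `irf_width > 0`.
#' @param tau0 Unquenched donor lifetime (ns), needed when `irf_width > 0`.
#' @param t_min Start of the analysis range after the prompt, ns.
#' @param count_floor Minimum reference counts per bin.
#' @return An `epsilon_decay`: data.frame `t` (ns after the prompt),
#'   `epsilon`, `se`, plus the normalisation constant as attribute `norm`.
#' @export
fret_induced_decay <- function(fret_decay, donor_only_decay, irf_offset = 2,
                               irf_width = 0, tau0 = 4, t_min = 0.5,
                               count_floor = 10) {
  if (length(fret_decay$edges) != length(donor_only_decay$edges) ||
      any(abs(fret_decay$edges - donor_only_decay$edges) > 1e-9))
    stop("decay histograms must share their binning")
  t <- fret_decay$centers - irf_offset
  cF <- fret_decay$counts; cD <- donor_only_decay$counts
  keep <- t >= t_min & cD >= count_floor & cF > 0
  t <- t[keep]
  ratio <- (cF[keep] / fret_decay$total) / (cD[keep] / donor_only_decay$total)
  se <- ratio * sqrt(1 / cF[keep] + 1 / cD[keep])
  # Normalisation to epsilon(0) = 1 by a model-free multi-exponential
  # extrapolation: non-negative least squares on a log-spaced grid of FRET
  # rate constants (plus k = 0); the t = 0 value of that expansion is the
  # sum of its coefficients. Pinning the scale here is what makes the
  # species fractions of the subsequent discrete fit sum to 1 meaningfully.
  # Rates faster than ~3/t_min are not constrained by the analysis range
  # and are excluded to keep the extrapolation stable.
  kgrid <- c(0, exp(seq(log(1e-3), log(3 / t_min), length.out = 60)))
  basis <- vapply(kgrid, function(k)
    epsilon_component(t, k, tau0, irf_width), numeric(length(t)))
  cf <- pracma::lsqnonneg(basis / se, ratio / se)$x
  norm <- sum(cf)
  out <- data.frame(t = t, epsilon = ratio / norm, se = se / norm)
  attr(out, "norm") <- norm
  # the unnormalised count ratio and range bounds let the species fit use
  # the exact self-normalisation (total counts scale with sum_i x_i tau_i)
  attr(out, "raw") <- data.frame(t = t, ratio = ratio, se = se)
  attr(out, "t_hi") <- max(fret_decay$edges) - irf_offset
  attr(out, "tau0") <- tau0
  attr(out, "rate_spectrum") <- data.frame(k = kgrid, coef = cf)
  class(out) <- c("epsilon_decay", "data.frame")
  out
}

# One epsilon component: the ratio of the Gaussian-IRF-convolved donor
# decay with total rate a = 1/tau0 + k to the convolved donor-only decay
# (rate a0 = 1/tau0). For sigma = 0 this is exp(-k t).
epsilon_component <- function(t, k, tau0, sigma) {
  if (sigma <= 0) return(exp(-k * t))
  a <- 1 / tau0 + k
  a0 <- 1 / tau0
  lognum <- sigma^2 * a^2 / 2 - a * t +
    stats::pnorm((t - sigma^2 * a) / sigma, log.p = TRUE)
  logden <- sigma^2 * a0^2 / 2 - a0 * t +
    stats::pnorm((t - sigma^2 * a0) / sigma, log.p = TRUE)
  exp(lognum - logden)
}

#' Fit FRET species distances and fractions to an epsilon decay
#'
#' Weighted least squares of
#' \eqn{\epsilon_D(t) = \sum_i x_i e^{-k_i t}} with
#' \eqn{k_i = (R_0/R_i)^6/\tau_0}, fractions non-negative and summing to 1.
#' The amplitude scale is not free: the fit works on the unnormalised
#' count-histogram ratio, whose overall scale is fixed by the model itself
#' through the total-count identity (the donor photon yield of species i is
#' proportional to \eqn{\tau_i = \tau_0(1-E_i)}), so
#' \eqn{N_F/N_D = \sum_i x_i \tau_i/\tau_0} up to range truncation, which
#' is accounted for. This self-normalisation is what makes a
#' three-component fit identifiable at realistic photon counts. Distances
#' are bounded in `[0.3, 3] * R0`; the upper bound acts as the no-FRET
#' limit. Deterministic multi-start local optimisation.
#'
#' @param eps An `epsilon_decay` from [fret_induced_decay()].
#' @param n_species Number of FRET species, 1..4.
#' @param pair The [dye_pair()] (R0, tau0).
#' @param no_fret Include an extra fixed k = 0 component with a free
#'   fraction (e.g. an uncut donor-only contaminant)?
#' @param irf_width Gaussian IRF s.d. in ns (must match the value given to
#'   [fret_induced_decay()]); components are convolved accordingly.
#' @param n_starts Number of multi-start points.
#' @param seed Seed for the start-point spread.
#' @return A data.frame `distance` (A, ascending), `fraction`, with
#'   attributes `chisq_red`, `scale`, `no_fret_fraction` (if requested).
#' @export
fit_species_decay <- function(eps, n_species, pair, no_fret = FALSE,
                              irf_width = 0, n_starts = 24, seed = 1L) {
  stopifnot(n_species >= 1, n_species <= 4)
  raw <- attr(eps, "raw")
  self_norm <- !is.null(raw)
  if (self_norm) {
    t <- raw$t; y <- raw$ratio
    w <- 1 / pmax(raw$se, 1e-12)^2
    t_hi <- attr(eps, "t_hi")
  } else {
    t <- eps$t; y <- eps$epsilon
    w <- 1 / pmax(eps$se, 1e-12)^2
  }
  R0 <- pair$R0; tau0 <- pair$tau0
  nsp <- n_species + as.integer(no_fret)
  softmax <- function(z) { e <- exp(z - max(z)); e / sum(e) }
  model_of <- function(par) {
    lr <- par[seq_len(n_species)]
    x <- if (nsp > 1) softmax(c(par[n_species + seq_len(nsp - 1)], 0))
    else 1
    k <- (R0 / exp(lr))^6 / tau0
    if (no_fret) k <- c(k, 0)
    comps <- vapply(k, function(kk)
      epsilon_component(t, kk, tau0, irf_width), numeric(length(t)))
    shape <- as.vector(comps %*% x)
    if (self_norm) {
      taui <- 1 / (1 / tau0 + k)
      Ii <- taui * (1 - exp(-t_hi / taui))      # per-component yield in range
      I0 <- tau0 * (1 - exp(-t_hi / tau0))
      sc <- I0 / sum(x * Ii)
    } else sc <- 1
    list(x = x, R = exp(lr), scale = sc, fit = sc * shape)
  }
  obj <- function(par) {
    m <- model_of(par)
    sum(w * (y - m$fit)^2)
  }
  lower <- c(rep(log(0.3 * R0), n_species), rep(-10, nsp - 1))
  upper <- c(rep(log(3 * R0), n_species), rep(10, nsp - 1))
  set.seed(seed)
  starts <- lapply(seq_len(n_starts), function(i) {
    c(sort(stats::runif(n_species, log(0.5 * R0), log(2 * R0))),
      stats::rnorm(nsp - 1, 0, 0.5))
  })
  # seed one start from the peaks of the model-free rate spectrum
  spec <- attr(eps, "rate_spectrum")
  if (!is.null(spec)) {
    pk <- spec[spec$coef > 0 & spec$k > 0, ]
    if (nrow(pk) >= 1) {
      pk <- pk[order(-pk$coef), ]
      ks <- utils::head(pk$k, n_species)
      ks <- c(ks, rep(ks[length(ks)] / 4, n_species - length(ks)))
      Rs <- pmin(pmax((tau0 * ks)^(-1 / 6) * R0, 0.35 * R0), 2.8 * R0)
      starts <- c(list(c(sort(log(Rs)), rep(0, nsp - 1))), starts)
    }
  }
  best <- NULL
  for (p0 in starts) {
    f <- tryCatch(stats::optim(p0, obj, method = "L-BFGS-B", lower = lower,
                               upper = upper, control = list(maxit = 400)),
                  error = function(e) NULL)
    if (!is.null(f) && (is.null(best) || f$value < best$value)) best <- f
  }
  if (is.null(best)) stop("species-decay fit failed to converge; inspect residuals")
  # polish with a simplex pass (multi-parameter fits only)
  if (length(best$par) >= 2) {
    nm <- stats::optim(best$par, function(z)
      obj(pmin(pmax(z, lower), upper)), method = "Nelder-Mead",
      control = list(maxit = 600, reltol = 1e-12))
    if (nm$value < best$value) {
      nm$par <- pmin(pmax(nm$par, lower), upper)
      best <- nm
    }
  }
  m <- model_of(best$par)
  ord <- order(m$R)
  out <- data.frame(distance = m$R[ord],
                    fraction = m$x[seq_len(n_species)][ord])
  npar <- length(best$par)
  attr(out, "chisq_red") <- best$value / max(length(t) - npar, 1)
  attr(out, "scale") <- m$scale
  if (no_fret) attr(out, "no_fret_fraction") <- m$x[nsp]
  out
}
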