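# Multi-tau photon correlation and global fitting. Correlation curves are
# computed on a quasi-logarithmic lag grid by binning the photon arrivals at
# the lag-matched resolution (coarsening by octave, the multi-tau scheme)
# with symmetric normalisation; uncertainties come from contiguous-segment
# statistics. The fit model is a 3D-Gaussian diffusion factor times a
# multi-exponential kinetic bracket; kinetic exchange between FRET states
# adds positive relaxation terms to the autocorrelations and a negative term
# to the donor-acceptor cross-correlation.

#' Multi-tau correlation of two photon channels
#'
#' @param stream A [photon_stream()].
#' @param channel_a,channel_b Channel names ("donor"/"acceptor"); equal for
#'   autocorrelation.
#' @param base_lag Finest lag resolution in s (default 1 us).
#' @param points_per_octave Lag points per octave (default 8).
#' @param max_lag Longest lag in s (default 1).
#' @param n_segments Contiguous segments for the error estimate (default 10).
#' @param donor_exc_only Use only donor-excitation photons (default TRUE;
#'   PIE acceptor-excitation photons carry no FRET information).
#' @return A `correlation_curve` data.frame: `lag` (s), `G`, `se`, with the
#'   channel pair label as attribute `pair_label`.
#' @export
correlate_multitau <- function(stream, channel_a, channel_b,
                               base_lag = 1e-6, points_per_octave = 8,
                               max_lag = 1, n_segments = 10,
                               donor_exc_only = TRUE) {
  sel <- if (donor_exc_only) donor_exc_idx(stream) else rep(TRUE, nrow(stream))
  ta <- stream$macro_time[sel & stream$channel == channel_a]
  tb <- stream$macro_time[sel & stream$channel == channel_b]
  if (length(ta) == 0 || length(tb) == 0) stop("empty channel")
  t0 <- min(ta[1], tb[1])
  ta <- ta - t0; tb <- tb - t0
  Ttot <- max(ta[length(ta)], tb[length(tb)])
  # lag grid: first two octaves at base resolution, then doubling
  lags <- list(); deltas <- numeric(0)
  o <- 0L
  repeat {
    d <- base_lag * 2^o
    ks <- if (o == 0L) seq_len(2L * points_per_octave)
    else (points_per_octave + 1L):(2L * points_per_octave)
    lg <- ks * d
    lg <- lg[lg <= max_lag]
    if (!length(lg)) break
    lags[[o + 1L]] <- list(delta = d, k = ks[seq_along(lg)])
    o <- o + 1L
    if (d * 2 * points_per_octave > max_lag) break
  }
  seg_edges <- seq(0, Ttot, length.out = n_segments + 1)
  all_lags <- unlist(lapply(lags, function(l) l$k * l$delta))
  Gseg <- matrix(NA_real_, n_segments, length(all_lags))
  Pairs <- matrix(0, n_segments, length(all_lags))
  for (s in seq_len(n_segments)) {
    a <- ta[ta >= seg_edges[s] & ta < seg_edges[s + 1]] - seg_edges[s]
    b <- tb[tb >= seg_edges[s] & tb < seg_edges[s + 1]] - seg_edges[s]
    seg_T <- seg_edges[s + 1] - seg_edges[s]
    col <- 1L
    for (l in lags) {
      L <- ceiling(seg_T / l$delta)
      na <- tabulate(pmin(floor(a / l$delta) + 1L, L), nbins = L)
      nb <- if (channel_a == channel_b) na
      else tabulate(pmin(floor(b / l$delta) + 1L, L), nbins = L)
      for (k in l$k) {
        if (k < L - 1) {
          x <- na[1:(L - k)]; y <- nb[(k + 1):L]
          mx <- mean(x); my <- mean(y)
          Gseg[s, col] <- if (mx > 0 && my > 0)
            mean(x * y) / (mx * my) else NA_real_
          Pairs[s, col] <- sum(x * y)
        }
        col <- col + 1L
      }
    }
  }
  G <- colMeans(Gseg, na.rm = TRUE)
  se <- apply(Gseg, 2, function(g) {
    g <- g[is.finite(g)]
    if (length(g) > 1) stats::sd(g) / sqrt(length(g)) else NA_real_
  })
  # the segment scatter underestimates the error when pair counts are low;
  # keep it above the Poisson pair-count (shot-noise) floor
  shot <- abs(G) / sqrt(pmax(colSums(Pairs), 1))
  se <- pmax(se, shot)
  out <- data.frame(lag = all_lags, G = G, se = se)
  out <- out[is.finite(out$G), ]
  rownames(out) <- NULL
  attr(out, "pair_label") <- paste(channel_a, channel_b, sep = "x")
  class(out) <- c("correlation_curve", "data.frame")
  out
}

# 3D-Gaussian diffusion factor
fcs_diffusion_factor <- function(t, t_diff, axial_ratio = 5) {
  1 / ((1 + t / t_diff) * sqrt(1 + t / (axial_ratio^2 * t_diff)))
}

#' Evaluate an FCS model curve
#'
#' \deqn{G(t) = B + \frac{1}{N} D(t; t_{diff}, r)
#'   \left(1 + \sum_i A_i e^{-t/t_{R,i}}\right)}
#' with D the 3D-Gaussian diffusion factor (1 when `diffusion = FALSE`).
#' Anti-correlated FRET kinetics enter through negative amplitudes.
#'
#' @param model List with `N`, `t_diff`, `axial_ratio` (default 5),
#'   `kinetic` (data.frame `amplitude`, `t_R`), `baseline` (default 1),
#'   `diffusion` (default TRUE). With `N = NULL` the number-fluctuation
#'   factor is dropped and amplitudes are absolute:
#'   `G = B + sum_i A_i exp(-t/t_R_i)`.
#' @param lags Lag times in s.
#' @return Numeric vector of G values.
#' @export
fcs_model_eval <- function(model, lags) {
  B <- model$baseline %||% 1
  kin <- model$kinetic
  bracket <- rep(1, length(lags))
  if (!is.null(kin) && nrow(kin))
    for (i in seq_len(nrow(kin)))
      bracket <- bracket + kin$amplitude[i] * exp(-lags / kin$t_R[i])
  if (is.null(model$N)) {
    # pure kinetic source (e.g. immobilised telegraph): absolute amplitudes
    return(B + (bracket - 1))
  }
  D <- if (isFALSE(model$diffusion)) 1
  else fcs_diffusion_factor(lags, model$t_diff, model$axial_ratio %||% 5)
  B + (1 / model$N) * D * bracket
}

#' Global fit of correlation curves
#'
#' Shared relaxation times (and diffusion time, if enabled) across all
#' curves; per-curve amplitudes and effective N. The linear parameters are
#' profiled out by weighted least squares at each candidate set of
#' relaxation times, so the nonlinear search runs only over `n_kinetic`
#' (+1 for diffusion) log-times, from a deterministic multi-start grid.
#'
#' @param curves List of `correlation_curve` objects.
#' @param n_kinetic Number of shared kinetic relaxation terms.
#' @param diffusion Include the 3D-Gaussian diffusion factor with a shared
#'   diffusion time?
#' @param axial_ratio Focal axial ratio (fixed, default 5).
#' @param t_range Search range (s) for relaxation times; defaults to the
#'   span of the lag grid.
#' @param n_starts Multi-start points per nonlinear dimension.
#' @return A list: `t_R` (ascending), `t_diff` (or NA), per-curve `models`
#'   (each with `N`, `amplitudes`, `shares`, `baseline`), `chisq_red`,
#'   `fitted` (list of fitted G), `par`.
#' @export
fcs_global_fit <- function(curves, n_kinetic = 1, diffusion = TRUE,
                           axial_ratio = 5, t_range = NULL, n_starts = 5) {
  stopifnot(length(curves) >= 1)
  lags <- lapply(curves, `[[`, "lag")
  ys <- lapply(curves, `[[`, "G")
  ws <- lapply(curves, function(cu) {
    se <- cu$se
    se[!is.finite(se) | se <= 0] <- stats::median(se[is.finite(se) & se > 0])
    1 / se^2
  })
  if (is.null(t_range))
    t_range <- range(unlist(lags))
  nlin <- n_kinetic + as.integer(diffusion)
  sse_of <- function(logt) {
    tR <- sort(exp(logt[seq_len(n_kinetic)]))
    td <- if (diffusion) exp(logt[n_kinetic + 1]) else NA_real_
    total <- 0
    for (i in seq_along(curves)) {
      t <- lags[[i]]
      base <- if (diffusion) fcs_diffusion_factor(t, td, axial_ratio)
      else rep(1, length(t))
      X <- cbind(base, base * vapply(tR, function(tr) exp(-t / tr),
                                     numeric(length(t))))
      fit <- stats::lm.wfit(X, ys[[i]] - 1, ws[[i]])
      total <- total + sum(ws[[i]] * fit$residuals^2)
    }
    total
  }
  # deterministic log-spaced start grid
  grid1 <- exp(seq(log(t_range[1] * 2), log(t_range[2] / 2),
                   length.out = n_starts))
  starts <- as.matrix(expand.grid(rep(list(log(grid1)), nlin)))
  if (n_kinetic > 1)   # keep ordered starts only, halves the grid
    starts <- starts[apply(starts[, seq_len(n_kinetic), drop = FALSE], 1,
                           function(r) !is.unsorted(r)), , drop = FALSE]
  best <- NULL
  if (nlin == 1) {
    o <- stats::optimize(function(z) sse_of(z),
                         c(log(t_range[1]), log(t_range[2])), tol = 1e-10)
    best <- list(par = o$minimum, value = o$objective)
  } else {
    for (r in seq_len(nrow(starts))) {
      f <- stats::optim(starts[r, ], sse_of, method = "Nelder-Mead",
                        control = list(maxit = 500, reltol = 1e-10))
      if (is.null(best) || f$value < best$value) best <- f
    }
  }
  tR <- sort(exp(best$par[seq_len(n_kinetic)]))
  td <- if (diffusion) exp(best$par[n_kinetic + 1]) else NA_real_
  models <- vector("list", length(curves))
  fitted <- vector("list", length(curves))
  npts <- 0
  for (i in seq_along(curves)) {
    t <- lags[[i]]
    base <- if (diffusion) fcs_diffusion_factor(t, td, axial_ratio)
    else rep(1, length(t))
    X <- cbind(base, base * vapply(tR, function(tr) exp(-t / tr),
                                   numeric(length(t))))
    fit <- stats::lm.wfit(X, ys[[i]] - 1, ws[[i]])
    cf <- fit$coefficients
    sig2 <- sum(ws[[i]] * fit$residuals^2) / max(length(t) - ncol(X), 1)
    cf_cov <- tryCatch(sig2 * solve(crossprod(X * sqrt(ws[[i]]))),
                       error = function(e) matrix(NA, ncol(X), ncol(X)))
    cf_se <- sqrt(pmax(diag(cf_cov), 0))
    if (diffusion) {
      # G - 1 = (1/N) D (1 + sum A_i e): coefficients are 1/N and A_i/N
      N <- 1 / cf[1]
      A <- cf[-1] / cf[1]
      baseline <- 1
    } else {
      # immobilised/pure-kinetic source: absolute amplitudes plus an offset
      N <- NA_real_
      A <- cf[-1]
      baseline <- 1 + cf[1]
    }
    A_se <- if (diffusion) abs(A) * sqrt((cf_se[-1] / abs(cf[-1]))^2 +
                                           (cf_se[1] / abs(cf[1]))^2)
    else cf_se[-1]
    models[[i]] <- list(N = unname(N), t_diff = td, axial_ratio = axial_ratio,
                        kinetic = data.frame(amplitude = unname(A),
                                             amplitude_se = unname(A_se),
                                             t_R = tR),
                        baseline = baseline, diffusion = diffusion,
                        shares = unname(A / sum(abs(A))),
                        pair_label = attr(curves[[i]], "pair_label"))
    fitted[[i]] <- 1 + as.vector(X %*% cf)
    npts <- npts + length(t)
  }
  dof <- npts - nlin - length(curves) * (1 + n_kinetic)
  list(t_R = tR, t_diff = td, models = models,
       chisq_red = best$value / max(dof, 1), fitted = fitted, par = best$par)
}

#' Write a correlation curve as TSV (lag_s, G, se)
#' @param curve A `correlation_curve`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_correlation_curve <- function(curve, path) {
  utils::write.table(data.frame(lag_s = curve$lag, G = curve$G, se = curve$se),
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
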