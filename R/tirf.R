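# Millisecond-to-seconds analysis of two-channel camera traces: selection
# criteria, per-frame FRET efficiency, Gaussian population fits,
# donor-acceptor cross-correlation and injection (compaction) kinetics.

#' Trace selection criteria
#'
#' The four acceptance criteria applied, in order, to every trace:
#' (1) initial total fluorescence (donor + beta-corrected acceptor) above
#' `min_initial_total` counts; (2) at least `min_prebleach_span` seconds
#' before the first bleaching event (use 10 s for injection runs);
#' (3) single-step bleaching — if the acceptor bleaches first the donor
#' must rise to the pre-bleach total, if the donor bleaches first the
#' acceptor must still be intact when probed directly at the end;
#' (4) donor bleaching within `require_donor_bleach_within` seconds so the
#' background level is unambiguous.
#'
#' @param min_initial_total Counts over baseline (default 600).
#' @param min_prebleach_span Seconds (default 5).
#' @param require_single_step Enforce criterion 3?
#' @param require_donor_bleach_within Seconds (default 120).
#' @param anticorrelation_check Require donor recovery after acceptor
#'   bleach (part of criterion 3a)?
#' @param beta Donor bleed-through used for the beta-corrected acceptor.
#' @param initial_frames Frames averaged for the initial total.
#' @param total_recovery_tol Relative tolerance on the donor recovery to
#'   the pre-bleach total (criterion 3a).
#' @param min_step_sd Bleach-step detector threshold in frame-noise s.d.
#' @return An object of class `selection_criteria`.
#' @export
selection_criteria <- function(min_initial_total = 600,
                               min_prebleach_span = 5,
                               require_single_step = TRUE,
                               require_donor_bleach_within = 120,
                               anticorrelation_check = TRUE,
                               beta = 0.1, initial_frames = 5,
                               total_recovery_tol = 0.25, min_step_sd = 5) {
  structure(list(min_initial_total = min_initial_total,
                 min_prebleach_span = min_prebleach_span,
                 require_single_step = require_single_step,
                 require_donor_bleach_within = require_donor_bleach_within,
                 anticorrelation_check = anticorrelation_check,
                 beta = beta, initial_frames = initial_frames,
                 total_recovery_tol = total_recovery_tol,
                 min_step_sd = min_step_sd),
            class = "selection_criteria")
}

# two-sided cumulative-mean step finder: returns the first frame of the
# post-step segment and the step size, or NA when no step clears the
# threshold (min_size in absolute counts)
detect_step <- function(x, min_size) {
  n <- length(x)
  if (n < 4) return(list(frame = NA_integer_, size = NA_real_))
  cs <- cumsum(x)
  t <- 1:(n - 1)
  m1 <- cs[t] / t
  m2 <- (cs[n] - cs[t]) / (n - t)
  crit <- t * (n - t) * (m2 - m1)^2
  t_star <- which.max(crit)
  size <- m2[t_star] - m1[t_star]
  if (abs(size) < min_size) return(list(frame = NA_integer_, size = NA_real_))
  list(frame = t_star + 1L, size = size)
}

frame_noise_sd <- function(x) stats::mad(diff(x)) / sqrt(2)

# Detect bleach frames from the channels themselves: a donor bleach drops
# the total to the background; an acceptor bleach steps the acceptor down
# while the total persists.
detect_bleach <- function(donor, acceptor, min_step_sd = 5) {
  total <- donor + acceptor
  sd_t <- max(frame_noise_sd(total), 1e-9)
  donor_frame <- NA_integer_; acceptor_frame <- NA_integer_
  st <- detect_step(total, min_step_sd * sd_t)
  if (!is.na(st$frame) && st$size < 0 &&
      mean(total[st$frame:length(total)]) < 0.35 * mean(total[1:(st$frame - 1)]))
    donor_frame <- st$frame
  upto <- if (is.na(donor_frame)) length(acceptor) else donor_frame - 1L
  if (upto > 4) {
    sd_a <- max(frame_noise_sd(acceptor[1:upto]), 1e-9)
    sa <- detect_step(acceptor[1:upto], min_step_sd * sd_a)
    if (!is.na(sa$frame) && sa$size < 0) acceptor_frame <- sa$frame
  }
  list(donor_frame = donor_frame, acceptor_frame = acceptor_frame)
}

# count additional accepted steps inside a segment (single-step check)
extra_steps <- function(x, min_step_sd = 5) {
  if (length(x) < 8) return(0L)
  s <- detect_step(x, min_step_sd * max(frame_noise_sd(x), 1e-9))
  if (is.na(s$frame)) 0L else 1L
}

split_traces <- function(dataset) {
  split(dataset$traces, dataset$traces$trace_id)
}

#' Apply the trace selection criteria
#'
#' Criteria are applied in order and each rejected trace carries the first
#' failing criterion as its reason code ("initial_total",
#' "prebleach_span", "single_step", "donor_bleach_window"). Bleach events
#' come from ground-truth annotations when the dataset carries them
#' (`use_annotations = TRUE`), otherwise from the cumulative-mean step
#' finder. Selection is deterministic and order-independent.
#'
#' @param dataset A `tirf_dataset` (traces + frame_time, optional truth).
#' @param criteria A [selection_criteria()].
#' @param use_annotations Use ground-truth bleach annotations when present?
#' @return A list: `accepted` (trace ids), `report` (data.frame trace_id,
#'   accepted, reason), `annotations` (per-trace bleach frames used).
#' @export
select_traces <- function(dataset, criteria = selection_criteria(),
                          use_annotations = TRUE) {
  ft <- dataset$frame_time
  tr_list <- split_traces(dataset)
  ids <- as.integer(names(tr_list))
  truth <- if (use_annotations) dataset$truth else NULL
  report <- data.frame(trace_id = ids, accepted = FALSE,
                       reason = NA_character_)
  ann <- data.frame(trace_id = ids, donor_bleach_frame = NA_integer_,
                    acceptor_bleach_frame = NA_integer_)
  for (i in seq_along(ids)) {
    tr <- tr_list[[i]]
    d <- tr$donor; a <- tr$acceptor
    nf <- length(d)
    if (!is.null(truth)) {
      row <- truth[truth$trace_id == ids[i], ]
      bf_d <- row$donor_bleach_frame[1]
      bf_a <- row$acceptor_bleach_frame[1]
      acc_alive <- isTRUE(row$acceptor_alive_at_end[1])
    } else {
      bl <- detect_bleach(d, a, criteria$min_step_sd)
      bf_d <- bl$donor_frame; bf_a <- bl$acceptor_frame
      acc_alive <- TRUE  # cannot probe without a direct-excitation frame
    }
    ann$donor_bleach_frame[i] <- bf_d
    ann$acceptor_bleach_frame[i] <- bf_a
    first_bleach <- suppressWarnings(min(c(bf_d, bf_a), na.rm = TRUE))
    k <- min(criteria$initial_frames, nf)
    init_total <- mean(d[1:k]) +
      mean(a[1:k] - criteria$beta * d[1:k])
    if (init_total <= criteria$min_initial_total) {
      report$reason[i] <- "initial_total"; next
    }
    if (is.finite(first_bleach) &&
        (first_bleach - 1) * ft < criteria$min_prebleach_span) {
      # criterion 2; without any bleach it is vacuous and criterion 4 decides
      report$reason[i] <- "prebleach_span"; next
    }
    if (criteria$require_single_step) {
      ok <- TRUE
      if (is.finite(first_bleach)) {
        pre <- 1:(first_bleach - 1)
        # FRET exchange moves counts between the channels but leaves the
        # total invariant, so multi-step bleaching is probed on the total
        if (extra_steps((d + a)[pre], criteria$min_step_sd) > 0) ok <- FALSE
        if (ok && !is.na(bf_a) && (is.na(bf_d) || bf_a < bf_d)) {
          # 3a: donor must recover to the pre-bleach total
          if (criteria$anticorrelation_check) {
            upto <- if (is.na(bf_d)) nf else bf_d - 1L
            if (upto > bf_a) {
              tot_pre <- mean(d[pre] + a[pre])
              don_post <- mean(d[bf_a:upto])
              if (abs(don_post - tot_pre) >
                  criteria$total_recovery_tol * tot_pre) ok <- FALSE
            }
          }
        }
        if (ok && !is.na(bf_d) && (is.na(bf_a) || bf_d < bf_a)) {
          # 3b: acceptor probed at the end must still be fluorescent
          if (!acc_alive) ok <- FALSE
        }
      }
      if (!ok) { report$reason[i] <- "single_step"; next }
    }
    if (is.na(bf_d) ||
        (bf_d - 1) * ft > criteria$require_donor_bleach_within) {
      report$reason[i] <- "donor_bleach_window"; next
    }
    report$accepted[i] <- TRUE
  }
  list(accepted = ids[report$accepted], report = report, annotations = ann)
}

#' Per-frame FRET efficiency of a trace
#'
#' `E_t = A'_t / (A'_t + gamma D_t)` with the beta-corrected acceptor
#' `A'_t = A_t - beta D_t - bg`. Frames from the first bleaching event on
#' are masked invalid.
#'
#' @param trace data.frame with `donor`, `acceptor` columns (one trace).
#' @param beta Donor bleed-through into the acceptor channel.
#' @param gamma Detection ratio.
#' @param bg Constant acceptor background, counts.
#' @param bleach_frame First bleached frame (NA = none).
#' @return data.frame `frame`, `E`, `valid`.
#' @export
efficiency_trace <- function(trace, beta = 0.1, gamma = 1, bg = 0,
                             bleach_frame = NA) {
  d <- trace$donor; a <- trace$acceptor
  ap <- a - beta * d - bg
  E <- ap / (ap + gamma * d)
  valid <- rep(TRUE, length(E))
  if (!is.na(bleach_frame) && bleach_frame <= length(E))
    valid[bleach_frame:length(E)] <- FALSE
  valid <- valid & is.finite(E)
  if (!any(valid)) stop("all frames masked in efficiency trace")
  data.frame(frame = seq_along(E), E = E, valid = valid)
}

first_bleach_frame <- function(ann_row) {
  suppressWarnings(min(c(ann_row$donor_bleach_frame,
                         ann_row$acceptor_bleach_frame), na.rm = TRUE))
}

#' Pool valid efficiency samples over selected traces
#'
#' @param dataset A `tirf_dataset`.
#' @param selection Result of [select_traces()] (default: select with
#'   default criteria).
#' @param beta,gamma,bg Passed to [efficiency_trace()].
#' @return Numeric vector of per-frame efficiencies from valid pre-bleach
#'   frames of accepted traces.
#' @export
pooled_efficiencies <- function(dataset, selection = NULL, beta = 0.1,
                                gamma = 1, bg = 0) {
  if (is.null(selection)) selection <- select_traces(dataset)
  tr_list <- split_traces(dataset)
  out <- lapply(as.character(selection$accepted), function(id) {
    ann <- selection$annotations[selection$annotations$trace_id ==
                                   as.integer(id), ]
    et <- efficiency_trace(tr_list[[id]], beta, gamma, bg,
                           bleach_frame = first_bleach_frame(ann))
    et$E[et$valid]
  })
  unlist(out)
}

#' Fit Gaussian populations to pooled efficiencies
#'
#' Least-squares fit of `n_components` Gaussians to the binned efficiency
#' histogram (density scale), deterministic given the seed for start
#' points. The chromatin populations are typically a low-E (< 0.1) open
#' population plus intermediate/high-E stacked populations.
#'
#' @param E Pooled efficiency samples (>= 500 recommended).
#' @param n_components Number of Gaussians.
#' @param binwidth Histogram bin width in E (default 0.02).
#' @param n_starts Multi-start points.
#' @param seed Start-spread seed.
#' @return data.frame `mean`, `sd`, `weight` (ascending means, weights sum
#'   to 1) with attributes `chisq`, `fitted` and `hist`.
#' @export
fit_population_gaussians <- function(E, n_components, binwidth = 0.02,
                                     n_starts = 10, seed = 1L) {
  E <- E[is.finite(E)]
  lo <- floor(min(E, -0.1) / binwidth) * binwidth
  hi <- ceiling(max(E, 1.1) / binwidth) * binwidth
  breaks <- seq(lo, hi, by = binwidth)
  h <- graphics::hist(E, breaks = breaks, plot = FALSE)
  y <- h$density; x <- h$mids
  softmax <- function(z) { e <- exp(z - max(z)); e / sum(e) }
  nc <- n_components
  model_of <- function(par) {
    mu <- par[1:nc]
    sdv <- exp(par[nc + 1:nc])
    w <- if (nc > 1) softmax(c(par[2 * nc + seq_len(nc - 1)], 0)) else 1
    f <- rowSums(vapply(seq_len(nc), function(i)
      w[i] * stats::dnorm(x, mu[i], sdv[i]), numeric(length(x))))
    list(mu = mu, sd = sdv, w = w, f = f)
  }
  obj <- function(par) sum((y - model_of(par)$f)^2)
  set.seed(seed)
  qs <- stats::quantile(E, probs = (seq_len(nc) - 0.5) / nc)
  starts <- lapply(seq_len(n_starts), function(r) {
    c(qs + stats::rnorm(nc, 0, 0.05), rep(log(0.05), nc) +
        stats::rnorm(nc, 0, 0.3), rep(0, nc - 1))
  })
  best <- NULL
  for (p0 in starts) {
    f <- stats::optim(p0, obj, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-12))
    if (is.null(best) || f$value < best$value) best <- f
  }
  m <- model_of(best$par)
  ord <- order(m$mu)
  out <- data.frame(mean = m$mu[ord], sd = m$sd[ord], weight = m$w[ord])
  attr(out, "chisq") <- best$value
  attr(out, "fitted") <- data.frame(mid = x, density = y, fit = m$f)
  out
}

#' Donor-acceptor cross-correlation of camera traces
#'
#' Per trace, the normalised cross-covariance of mean-subtracted donor and
#' acceptor signals over valid (pre-bleach) frames; the pooled curve is the
#' trace average with its s.e.m. Exponential components are fitted over
#' lags >= 1 frame (the zero-lag shot-noise spike is excluded); the
#' single- vs two-exponential choice uses an F-test at alpha = 0.05 when
#' `n_exp = "auto"`. Anti-correlated FRET fluctuations give a negative
#' amplitude.
#'
#' @param dataset A `tirf_dataset`.
#' @param selection Result of [select_traces()]; default selects with
#'   default criteria.
#' @param max_lag Longest lag in s.
#' @param n_exp 1, 2 or "auto".
#' @return A list of class `trace_correlation`: `lag` (s), `cc` (pooled),
#'   `sem`, `per_trace` (matrix), `fit` (t_R, amplitude, shares, n_exp),
#'   `n_traces`.
#' @export
trace_cross_correlation <- function(dataset, selection = NULL, max_lag = 5,
                                    n_exp = "auto") {
  if (is.null(selection)) selection <- select_traces(dataset)
  ft <- dataset$frame_time
  K <- max(2L, floor(max_lag / ft))
  tr_list <- split_traces(dataset)
  ids <- as.character(selection$accepted)
  if (length(ids) < 1) stop("no accepted traces")
  per <- matrix(NA_real_, length(ids), K + 1)
  for (j in seq_along(ids)) {
    ann <- selection$annotations[selection$annotations$trace_id ==
                                   as.integer(ids[j]), ]
    fb <- first_bleach_frame(ann)
    tr <- tr_list[[ids[j]]]
    upto <- if (is.finite(fb)) fb - 1L else nrow(tr)
    d <- tr$donor[1:upto]; a <- tr$acceptor[1:upto]
    n <- length(d)
    if (n < 10) next
    d <- d - mean(d); a <- a - mean(a)
    denom <- stats::sd(d) * stats::sd(a)
    Kj <- min(K, n - 2L)
    for (k in 0:Kj)
      per[j, k + 1] <- mean(d[1:(n - k)] * a[(k + 1):n]) / denom
  }
  keep <- rowSums(is.finite(per)) > 2
  per <- per[keep, , drop = FALSE]
  cc <- colMeans(per, na.rm = TRUE)
  sem <- apply(per, 2, function(v) {
    v <- v[is.finite(v)]
    if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else NA_real_
  })
  lag <- (0:K) * ft
  fit <- fit_cc_exponentials(lag[-1], cc[-1], sem[-1], n_exp)
  structure(list(lag = lag, cc = cc, sem = sem, per_trace = per, fit = fit,
                 n_traces = nrow(per), frame_time = ft),
            class = "trace_correlation")
}

# profile the linear amplitudes over a log-spaced relaxation-time grid;
# a free constant absorbs the negative offset that per-trace mean
# subtraction induces on finite traces
fit_cc_exponentials <- function(lag, cc, sem, n_exp = "auto") {
  ok <- is.finite(cc) & is.finite(sem) & sem > 0
  lag <- lag[ok]; cc <- cc[ok]; w <- 1 / sem[ok]^2
  sse_for <- function(tRs) {
    X <- cbind(1, vapply(tRs, function(tr) exp(-lag / tr),
                         numeric(length(lag))))
    f <- stats::lm.wfit(X, cc, w)
    list(sse = sum(w * f$residuals^2), amp = f$coefficients[-1],
         offset = f$coefficients[1])
  }
  grid <- exp(seq(log(lag[1]), log(max(lag)), length.out = 25))
  one <- NULL
  for (tr in grid) {
    s <- sse_for(tr)
    if (is.null(one) || s$sse < one$sse) one <- c(s, t_R = tr)
  }
  o1 <- stats::optim(log(one$t_R), function(z) sse_for(exp(z))$sse,
                     method = "Brent", lower = log(lag[1] / 10),
                     upper = log(max(lag) * 10))
  best1 <- sse_for(exp(o1$par))
  fit1 <- list(t_R = exp(o1$par), amplitude = unname(best1$amp),
               shares = 1, n_exp = 1, sse = best1$sse)
  if (identical(n_exp, 1)) return(fit1)
  two <- NULL
  gpairs <- expand.grid(a = grid[seq(1, 25, by = 3)],
                        b = grid[seq(1, 25, by = 3)])
  gpairs <- gpairs[gpairs$a < gpairs$b, ]
  for (r in seq_len(nrow(gpairs))) {
    s <- sse_for(c(gpairs$a[r], gpairs$b[r]))
    if (is.null(two) || s$sse < two$sse)
      two <- c(s, list(t_R = c(gpairs$a[r], gpairs$b[r])))
  }
  o2 <- stats::optim(log(two$t_R), function(z) sse_for(exp(z))$sse,
                     method = "Nelder-Mead", control = list(maxit = 300))
  best2 <- sse_for(exp(o2$par))
  amp2 <- unname(best2$amp)
  fit2 <- list(t_R = exp(o2$par), amplitude = amp2,
               shares = abs(amp2) / sum(abs(amp2)), n_exp = 2,
               sse = best2$sse)
  ord <- order(fit2$t_R)
  fit2$t_R <- fit2$t_R[ord]; fit2$amplitude <- fit2$amplitude[ord]
  fit2$shares <- fit2$shares[ord]
  # two nearly equal times (or wildly cancelling amplitudes) mean the
  # second component is not supported by the data
  degenerate <- fit2$t_R[2] / fit2$t_R[1] < 1.5 ||
    max(abs(fit2$amplitude)) > 20 * max(abs(cc))
  if (identical(n_exp, 2)) return(if (degenerate) fit1 else fit2)
  if (degenerate) return(fit1)
  # F-test: does the two-component fit reduce the residual significantly?
  n <- length(lag)
  fstat <- ((fit1$sse - fit2$sse) / 2) / (fit2$sse / max(n - 4, 1))
  pval <- stats::pf(fstat, 2, max(n - 4, 1), lower.tail = FALSE)
  if (is.finite(pval) && pval < 0.05) { fit2$f_p <- pval; fit2 }
  else { fit1$f_p <- pval; fit1 }
}

#' Fraction of dynamic traces
#'
#' A trace counts as dynamic when the magnitude of its cross-correlation
#' amplitude (projected on the pooled relaxation time) exceeds
#' `threshold` times its standard error.
#'
#' @param corr A `trace_correlation`.
#' @param threshold Significance multiple (default 3).
#' @return Fraction between 0 and 1.
#' @export
dynamic_trace_fraction <- function(corr, threshold = 3) {
  if (!is.finite(threshold)) return(0)
  tR <- corr$fit$t_R[which.max(abs(corr$fit$amplitude))]
  lag <- corr$lag[-1]
  b <- exp(-lag / tR)
  dyn <- apply(corr$per_trace[, -1, drop = FALSE], 1, function(v) {
    ok <- is.finite(v)
    if (sum(ok) < 5) return(FALSE)
    X <- cbind(1, b[ok])
    cf <- qr.solve(X, v[ok])
    resid <- v[ok] - as.vector(X %*% cf)
    s2 <- sum(resid^2) / max(sum(ok) - 2, 1)
    seA <- sqrt(s2 * solve(crossprod(X))[2, 2])
    abs(cf[2]) > threshold * seA
  })
  mean(dyn)
}

#' Injection (compaction) kinetics
#'
#' Classifies traces as responders by a pre/post mean-efficiency shift
#' test, then fits a single-exponential approach to the post-injection
#' plateau of the responder-averaged efficiency:
#' `E(t) = E_inf - (E_inf - E_0) exp(-(t - t_inject)/tau)`.
#'
#' @param dataset A `tirf_dataset`.
#' @param t_inject Injection time in s.
#' @param selection Result of [select_traces()] (injection criteria);
#'   default selects with a 10 s pre-bleach span.
#' @param shift_threshold Minimum post-pre mean-E shift for a responder.
#' @param beta,gamma Efficiency-trace corrections.
#' @param pre_window,post_window Averaging windows (s) before/after the
#'   injection for the shift test.
#' @return A list: `tau` (s), `tau_ci` (95%), `responder_fraction`,
#'   `n_responders`, `mean_trace` (data.frame t, E), `fit` parameters.
#' @export
fit_injection_kinetics <- function(dataset, t_inject, selection = NULL,
                                   shift_threshold = 0.15, beta = 0.1,
                                   gamma = 1, pre_window = 3,
                                   post_window = 10) {
  ft <- dataset$frame_time
  if (is.null(selection))
    selection <- select_traces(dataset,
                               selection_criteria(min_prebleach_span = 10))
  tr_list <- split_traces(dataset)
  ids <- as.character(selection$accepted)
  if (!length(ids)) stop("no accepted traces")
  fi <- floor(t_inject / ft) + 1L
  Emat <- NULL; resp <- logical(length(ids))
  for (j in seq_along(ids)) {
    ann <- selection$annotations[selection$annotations$trace_id ==
                                   as.integer(ids[j]), ]
    et <- efficiency_trace(tr_list[[ids[j]]], beta, gamma,
                           bleach_frame = first_bleach_frame(ann))
    E <- ifelse(et$valid, et$E, NA_real_)
    pre <- E[max(1, fi - round(pre_window / ft)):(fi - 1)]
    post <- E[(fi + 1):min(length(E), fi + round(post_window / ft))]
    if (sum(is.finite(pre)) >= 3 && sum(is.finite(post)) >= 3)
      resp[j] <- mean(post, na.rm = TRUE) - mean(pre, na.rm = TRUE) >
        shift_threshold
    if (is.null(Emat)) Emat <- matrix(NA_real_, length(ids), length(E))
    Emat[j, seq_along(E)] <- E
  }
  frac <- mean(resp)
  if (!any(resp))
    return(list(tau = NA_real_, tau_ci = c(NA, NA), responder_fraction = 0,
                n_responders = 0, mean_trace = NULL, fit = NULL))
  Eresp <- colMeans(Emat[resp, , drop = FALSE], na.rm = TRUE)
  tt <- (seq_along(Eresp) - 1) * ft
  post <- which(tt >= t_inject & is.finite(Eresp))
  t_rel <- tt[post] - t_inject
  y <- Eresp[post]
  # profile the linear parameters over tau
  sse_for <- function(tau) {
    X <- cbind(1, exp(-t_rel / tau))
    f <- stats::lm.fit(X, y)
    list(sse = sum(f$residuals^2), cf = f$coefficients)
  }
  o <- stats::optim(log(1), function(z) sse_for(exp(z))$sse,
                    method = "Brent", lower = log(ft / 2), upper = log(100))
  tau <- exp(o$par)
  bf <- sse_for(tau)
  # 95% CI from the profile-likelihood curvature in log tau
  h <- 0.05
  f0 <- o$value
  fp <- sse_for(exp(o$par + h))$sse; fm <- sse_for(exp(o$par - h))$sse
  curv <- (fp + fm - 2 * f0) / h^2
  sig2 <- f0 / max(length(y) - 3, 1)
  se_log <- if (curv > 0) sqrt(2 * sig2 / curv) else NA_real_
  ci <- tau * exp(c(-1.96, 1.96) * se_log)
  list(tau = tau, tau_ci = ci, responder_fraction = frac,
       n_responders = sum(resp),
       mean_trace = data.frame(t = tt, E = Eresp),
       fit = list(E_inf = unname(bf$cf[1] + 0),
                  amplitude = unname(bf$cf[2]), sse = bf$sse))
}
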