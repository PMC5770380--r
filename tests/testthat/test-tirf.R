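# Camera-trace analysis: selection criteria, efficiency traces, population
# fits, cross-correlation kinetics, injection kinetics.

# deterministic trace builder: piecewise-constant donor/acceptor with
# optional bleach steps; frame time 0.1 s, 1200 frames unless stated
make_trace <- function(id, total = 1000, E = 0.4, beta = 0.1,
                       acceptor_bleach = NA, donor_bleach = NA,
                       n_frames = 1200, extra_step_frame = NA,
                       acceptor_alive = TRUE, noise_sd = 4, seed = id) {
  set.seed(seed)
  d <- rep((1 - E) * total, n_frames)
  a <- rep(E * total + beta * (1 - E) * total, n_frames)
  if (!is.na(acceptor_bleach) &&
      (is.na(donor_bleach) || acceptor_bleach < donor_bleach)) {
    idx <- acceptor_bleach:n_frames
    d[idx] <- total; a[idx] <- beta * total
  }
  if (!is.na(donor_bleach) && donor_bleach <= n_frames) {
    idx <- donor_bleach:n_frames
    d[idx] <- 0; a[idx] <- 0
  }
  if (!is.na(extra_step_frame)) {
    idx <- extra_step_frame:n_frames
    d[idx] <- d[idx] * 0.5; a[idx] <- a[idx] * 0.5
  }
  list(trace = data.frame(trace_id = id, frame = seq_len(n_frames),
                          donor = d + rnorm(n_frames, 0, noise_sd),
                          acceptor = a + rnorm(n_frames, 0, noise_sd)),
       truth = data.frame(trace_id = id,
                          acceptor_bleach_frame =
                            ifelse(!is.na(acceptor_bleach) &&
                                     (is.na(donor_bleach) ||
                                        acceptor_bleach < donor_bleach),
                                   acceptor_bleach, NA),
                          donor_bleach_frame = donor_bleach,
                          acceptor_alive_at_end = acceptor_alive))
}

panel_dataset <- function(specs) {
  parts <- lapply(seq_along(specs), function(i)
    do.call(make_trace, c(list(id = i), specs[[i]])))
  structure(list(traces = do.call(rbind, lapply(parts, `[[`, "trace")),
                 truth = do.call(rbind, lapply(parts, `[[`, "truth")),
                 frame_time = 0.1),
            class = "tirf_dataset")
}

test_that("the four selection criteria reproduce a hand-enumerated panel", {
  specs <- list(
    list(acceptor_bleach = 300, donor_bleach = 700),          # 1 ok
    list(donor_bleach = 600),                                 # 2 ok
    list(total = 550, acceptor_bleach = 300, donor_bleach = 700),  # 3 initial_total
    list(acceptor_bleach = 30, donor_bleach = 700),           # 4 prebleach_span
    list(donor_bleach = 20),                                  # 5 prebleach_span
    list(acceptor_bleach = 300, donor_bleach = 700,
         extra_step_frame = 150),                             # 6 single_step
    list(donor_bleach = 600, acceptor_alive = FALSE),         # 7 single_step (3b)
    list(),                                                   # 8 no donor bleach
    list(acceptor_bleach = 400),                              # 9 donor never bleaches
    list(acceptor_bleach = 200, donor_bleach = 900),          # 10 ok
    list(total = 400, donor_bleach = 500),                    # 11 initial_total
    list(donor_bleach = 45),                                  # 12 prebleach_span
    list(acceptor_bleach = 100, donor_bleach = 1100),         # 13 ok
    list(donor_bleach = 1150),                                # 14 ok
    list(acceptor_bleach = 52, donor_bleach = 300),           # 15 ok (5.1 s)
    list(acceptor_bleach = 49, donor_bleach = 300),           # 16 prebleach (4.8 s)
    list(total = 620, donor_bleach = 700),                    # 17 ok (just above)
    list(acceptor_bleach = 300, donor_bleach = 700,
         extra_step_frame = 100),                             # 18 single_step
    list(donor_bleach = 80),                                  # 19 ok (7.9 s span)
    list(total = 300)                                         # 20 initial_total
  )
  expected <- c("ok", "ok", "initial_total", "prebleach_span",
                "prebleach_span", "single_step", "single_step",
                "donor_bleach_window", "donor_bleach_window", "ok",
                "initial_total", "prebleach_span", "ok", "ok", "ok",
                "prebleach_span", "ok", "single_step", "ok",
                "initial_total")
  ds <- panel_dataset(specs)
  sel <- select_traces(ds)
  got <- ifelse(sel$report$accepted, "ok", sel$report$reason)
  expect_identical(unname(got), expected)
  # order independence: shuffling the trace table gives the same set
  shuf <- ds
  shuf$traces <- ds$traces[sample(nrow(ds$traces)), ]
  shuf$traces <- shuf$traces[order(shuf$traces$trace_id, shuf$traces$frame), ]
  sel2 <- select_traces(shuf)
  expect_setequal(sel2$accepted, sel$accepted)
})

test_that("bleach detection finds steps without annotations", {
  specs <- list(list(acceptor_bleach = 300, donor_bleach = 700),
                list(donor_bleach = 500))
  ds <- panel_dataset(specs)
  sel <- select_traces(ds, use_annotations = FALSE)
  expect_equal(sel$annotations$acceptor_bleach_frame[1], 300, tolerance = 2)
  expect_equal(sel$annotations$donor_bleach_frame[1], 700, tolerance = 2)
  expect_equal(sel$annotations$donor_bleach_frame[2], 500, tolerance = 2)
})

test_that("efficiency traces apply the beta correction and bleach mask", {
  tr <- data.frame(donor = rep(500, 100),
                   acceptor = rep(500 + 0.1 * 500, 100))
  et <- efficiency_trace(tr, beta = 0.1, gamma = 1)
  expect_equal(et$E, rep(0.5, 100))
  et2 <- efficiency_trace(tr, beta = 0.1, bleach_frame = 60)
  expect_true(all(!et2$valid[60:100]))
  expect_true(all(et2$valid[1:59]))
  expect_error(efficiency_trace(tr, bleach_frame = 1), "masked")
})

test_that("Gaussian population fits recover means, widths and weights", {
  set.seed(5)
  E <- c(rnorm(7000, 0.4, 0.05))
  f1 <- fit_population_gaussians(E, 1, seed = 1)
  expect_lt(abs(f1$mean - 0.4), 0.01)
  expect_lt(abs(f1$sd - 0.05) / 0.05, 0.10)
  E2 <- c(rnorm(6000, 0.15, 0.04), rnorm(4000, 0.55, 0.06))
  f2 <- fit_population_gaussians(E2, 2, seed = 1)
  expect_lt(max(abs(f2$mean - c(0.15, 0.55))), 0.02)
  expect_lt(max(abs(f2$weight - c(0.6, 0.4))), 0.05)
  expect_equal(sum(f2$weight), 1, tolerance = 1e-6)
  # bin-width invariance of the recovered means
  f2b <- fit_population_gaussians(E2, 2, binwidth = 0.01, seed = 1)
  expect_lt(max(abs(f2b$mean - f2$mean)), 0.005)
})

test_that("cross-correlation recovers slow switching times within 25%", {
  p <- pair52()
  for (tR in c(0.2, 0.5)) {
    k <- 1 / tR / 2
    m <- two_state_model(k, k, E = c(0.15, 0.5), pair = p)
    ds <- simulate_tirf_traces(m, tirf_sim_config(n_traces = 100,
                                                  n_frames = 1200,
                                                  seed = round(100 * tR)))
    sel <- select_traces(ds)
    cc <- trace_cross_correlation(ds, sel, max_lag = max(3, 5 * tR),
                                  n_exp = 1)
    expect_lt(abs(cc$fit$t_R - tR) / tR, 0.25)
    expect_lt(cc$fit$amplitude, 0)   # anti-correlated by construction
  }
})

test_that("static panels give null amplitudes and zero dynamic fraction", {
  p <- pair52()
  m <- two_state_model(1e-6, 1e-6, E = c(0.3, 0.3), pair = p)
  ds <- simulate_tirf_traces(m, tirf_sim_config(n_traces = 60,
                                                n_frames = 1200, seed = 11))
  sel <- select_traces(ds)
  cc <- trace_cross_correlation(ds, sel, n_exp = 1)
  # amplitude consistent with zero at the pooled-curve noise level
  expect_lt(abs(cc$fit$amplitude), 4 * stats::median(cc$sem, na.rm = TRUE) *
              sqrt(length(cc$lag)))
  expect_lt(dynamic_trace_fraction(cc), 0.1)
  expect_equal(dynamic_trace_fraction(cc, Inf), 0)
})

test_that("half-dynamic panels are classified near 50% dynamic", {
  p <- pair52()
  dyn <- simulate_tirf_traces(two_state_model(2.5, 2.5, E = c(0.15, 0.5),
                                              pair = p),
                              tirf_sim_config(n_traces = 40, n_frames = 1200,
                                              seed = 21))
  sta <- simulate_tirf_traces(two_state_model(1e-6, 1e-6, E = c(0.3, 0.3),
                                              pair = p),
                              tirf_sim_config(n_traces = 40, n_frames = 1200,
                                              seed = 22))
  sta$traces$trace_id <- sta$traces$trace_id + 40
  sta$truth$trace_id <- sta$truth$trace_id + 40
  ds <- structure(list(traces = rbind(dyn$traces, sta$traces),
                       truth = rbind(dyn$truth, sta$truth),
                       frame_time = 0.1), class = "tirf_dataset")
  sel <- select_traces(ds)
  cc <- trace_cross_correlation(ds, sel, n_exp = 1)
  frac <- dynamic_trace_fraction(cc)
  n_dyn_sel <- sum(sel$accepted <= 40)
  expect_lt(abs(frac - n_dyn_sel / length(sel$accepted)), 0.12)
})

test_that("injection kinetics recovers the compaction time constant", {
  p <- pair52()
  m <- two_state_model(1e-6, 1e-6, E = c(0.1, 0.6), pair = p)
  cfg <- tirf_sim_config(n_traces = 120, n_frames = 400, injection_time = 5,
                         responder_fraction = 0.65, injection_tau = 1.0,
                         bleach_rate_acceptor = 1 / 60,
                         bleach_rate_donor = 1 / 50, seed = 9)
  ds <- simulate_tirf_traces(m, cfg)
  sel <- select_traces(ds, selection_criteria(min_prebleach_span = 10,
                                              require_donor_bleach_within = 40))
  fit <- fit_injection_kinetics(ds, 5, sel)
  expect_lt(abs(fit$tau - 1.0), 0.2)
  expect_lt(abs(fit$responder_fraction - 0.65), 0.12)
  # flat traces: no responders, no fit attempted
  flat <- simulate_tirf_traces(two_state_model(1e-6, 1e-6, E = c(0.3, 0.3),
                                               pair = p),
                               tirf_sim_config(n_traces = 30, n_frames = 400,
                                               bleach_rate_acceptor = 1 / 60,
                                               bleach_rate_donor = 1 / 50,
                                               seed = 10))
  .sel <- select_traces(flat, selection_criteria(min_prebleach_span = 10,
                                                 require_donor_bleach_within = 40))
  f0 <- fit_injection_kinetics(flat, 5, .sel)
  expect_equal(f0$responder_fraction, 0)
  expect_true(is.na(f0$tau))
})
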