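# Confocal and camera-trace simulators: routing statistics, photon
# bookkeeping, micro-time decays and determinism.

test_that("E = 0 molecules put all donor-excitation photons in the donor channel", {
  p <- pair52()
  m <- kinetic_model(list(fret_species("S", p, efficiency = 1e-12)),
                     matrix(0, 1, 1))
  sim <- simulate_bursts(m, confocal_sim_config(burst_count = 50, seed = 1))
  st <- sim$stream
  expect_true(all(st$channel[st$slot != "acceptor_exc"] == "donor"))
})

test_that("routing recovers the configured efficiency and conserves photons", {
  p <- pair52()
  m <- kinetic_model(list(fret_species("S", p, efficiency = 0.5)),
                     matrix(0, 1, 1))
  sim <- simulate_bursts(m, confocal_sim_config(burst_count = 2000, seed = 3))
  sig <- sim$stream[sim$stream$origin == "signal", ]
  fa <- sum(sig$channel == "acceptor"); n <- nrow(sig)
  se <- sqrt(0.25 / n)
  expect_lt(abs(fa / n - 0.5), 3 * se)
  # conservation: signal photons equal the recorded emitted count
  expect_identical(n, sum(sim$truth$n_signal))
})

test_that("crosstalk registers extra acceptor counts at the configured rate", {
  p <- pair52()
  m <- kinetic_model(list(fret_species("S", p, efficiency = 1e-12)),
                     matrix(0, 1, 1))
  cfg <- confocal_sim_config(burst_count = 500,
                             calib = calibration_config(alpha = 0.1),
                             seed = 4)
  sim <- simulate_bursts(m, cfg)
  st <- sim$stream
  nd <- sum(st$channel == "donor"); na <- sum(st$channel == "acceptor")
  se <- sqrt(0.1 * nd) / nd
  expect_lt(abs(na / nd - 0.1), 3 * se)
  expect_true(all(st$origin[st$channel == "acceptor"] == "crosstalk"))
})

test_that("micro-time decay follows tau0 (1 - E) within 2% at 1e6 photons", {
  p <- pair52()   # tau0 = 4 ns
  m <- kinetic_model(list(fret_species("S", p, efficiency = 0.5)),
                     matrix(0, 1, 1))
  stream <- simulate_cw_stream(m, duration = 20, brightness = 1e5, seed = 5)
  don <- stream$micro_time[stream$channel == "donor"]
  expect_gt(length(don), 5e5)
  tau_hat <- mean(don) - 2     # IRF offset 2 ns
  expect_lt(abs(tau_hat - 2) / 2, 0.02)
})

test_that("slow-exchange bursts give a bimodal E histogram at the stationary law", {
  p <- pair52()
  m <- two_state_model(5, 15, E = c(0.8, 0.1))  # relaxation 50 ms >> transit
  sim <- simulate_bursts(m, confocal_sim_config(burst_count = 1500, seed = 6))
  bi <- burst_indicators(burst_search(sim$stream), sim$stream,
                         calibration_config(), p)
  hi <- mean(bi$E > 0.45, na.rm = TRUE)
  piv <- stationary_distribution(m)
  se <- sqrt(piv[1] * piv[2] / nrow(bi))
  expect_lt(abs(hi - piv[1]), 3 * se + 0.02)
})

test_that("same seed gives bit-identical streams", {
  m <- two_state_model(1000, 1000)
  cfg <- confocal_sim_config(burst_count = 100, seed = 9, pie = TRUE,
                             calib = calibration_config(alpha = 0.05,
                                                        bg_donor = 300,
                                                        bg_acceptor = 300,
                                                        donor_only_fraction = 0.2))
  s1 <- simulate_bursts(m, cfg)
  s2 <- simulate_bursts(m, cfg)
  expect_identical(s1$stream, s2$stream)
  expect_identical(s1$truth, s2$truth)
})

test_that("photon stream TSV round trip is bit exact", {
  m <- two_state_model(1000, 1000)
  sim <- simulate_bursts(m, confocal_sim_config(burst_count = 30, seed = 2,
                                                pie = TRUE))
  path <- tempfile(fileext = ".tsv")
  write_photon_stream(sim$stream, path)
  st2 <- read_photon_stream(path)
  expect_identical(st2$macro_time, sim$stream$macro_time)
  expect_identical(st2$micro_time, sim$stream$micro_time)
  expect_identical(st2$channel, sim$stream$channel)
  expect_identical(st2$slot, sim$stream$slot)
  expect_identical(attr(st2, "period_ns"), attr(sim$stream, "period_ns"))
})

test_that("noise-free static TIRF traces are exactly (1-E, E) times total", {
  m <- two_state_model(1e-9, 1e-9, E = c(0.3, 0.3))
  cfg <- tirf_sim_config(n_traces = 3, n_frames = 50, total_counts = 1000,
                         bleach_rate_acceptor = 1e-12,
                         bleach_rate_donor = 1e-12, beta = 0,
                         shot_noise = FALSE, read_noise_sd = 0, seed = 1)
  ds <- simulate_tirf_traces(m, cfg)
  expect_true(all(ds$traces$donor == 700))
  expect_true(all(ds$traces$acceptor == 300))
})

test_that("acceptor bleach drops the acceptor and restores the donor", {
  m <- two_state_model(1e-9, 1e-9, E = c(0.4, 0.4))
  cfg <- tirf_sim_config(n_traces = 20, n_frames = 400, total_counts = 1000,
                         bleach_rate_acceptor = 1 / 15,
                         bleach_rate_donor = 1e-12, beta = 0.1,
                         shot_noise = FALSE, read_noise_sd = 0, seed = 2)
  ds <- simulate_tirf_traces(m, cfg)
  tr <- split(ds$traces, ds$traces$trace_id)
  for (i in seq_along(tr)) {
    fb <- ds$truth$acceptor_bleach_frame[i]
    if (is.na(fb) || fb > 390) next
    expect_true(all(tr[[i]]$donor[fb:400] == 1000))
    expect_true(all(tr[[i]]$acceptor[fb:400] == 100))  # beta * total
    expect_true(all(tr[[i]]$donor[1:(fb - 1)] == 600))
  }
})

test_that("injection runs flip the configured responder fraction", {
  m <- two_state_model(1, 1, E = c(0.1, 0.6))  # state 1 low-E open
  cfg <- tirf_sim_config(n_traces = 200, n_frames = 300,
                         injection_time = 5, responder_fraction = 0.5,
                         injection_tau = 1, bleach_rate_acceptor = 1e-9,
                         bleach_rate_donor = 1e-9, seed = 3)
  ds <- simulate_tirf_traces(m, cfg)
  n_resp <- sum(ds$truth$responder)
  expect_lt(abs(n_resp - 100), 15 * 3)  # binomial 3 s.e. ~ 21
  expect_gt(n_resp, 70)
  # responders change their mean efficiency after injection
  tr <- split(ds$traces, ds$traces$trace_id)
  resp_ids <- which(ds$truth$responder)
  shifts <- vapply(resp_ids[1:20], function(i) {
    et <- efficiency_trace(tr[[i]], beta = 0.1)
    mean(et$E[200:300]) - mean(et$E[1:40])
  }, numeric(1))
  expect_gt(mean(shifts > 0.2), 0.8)
})
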