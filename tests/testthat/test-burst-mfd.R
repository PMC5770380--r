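# Burst search, corrected MFD indicators, subensemble selection and 2D
# histograms.

test_that("burst search: background-only streams yield no bursts", {
  set.seed(1)
  t <- sort(runif(2000, 0, 2))   # 1 kHz
  st <- photon_stream(t, rep(1, 2000), rep("donor", 2000), rep("none", 2000))
  expect_equal(nrow(burst_search(st, window = 500e-6, m = 20,
                                 min_total = 20)), 0L)
  # empty stream
  empty <- photon_stream(numeric(0), numeric(0), character(0), character(0))
  expect_equal(nrow(burst_search(empty)), 0L)
})

test_that("burst search finds inserted clusters against a brute-force oracle", {
  set.seed(2)
  bg <- sort(runif(400, 0, 2))                 # 200 Hz background
  cl1 <- sort(runif(200, 0.50, 0.502))         # 200 photons over 2 ms
  cl2 <- sort(runif(150, 1.30, 1.302))
  t <- sort(c(bg, cl1, cl2))
  st <- photon_stream(t, rep(1, length(t)), rep("donor", length(t)),
                      rep("none", length(t)))
  bs <- burst_search(st, window = 500e-6, m = 15, min_total = 60)
  expect_equal(nrow(bs), 2L)
  # each burst contains >= 95% of its cluster photons
  in1 <- sum(cl1 >= bs$start[1] & cl1 <= bs$stop[1])
  in2 <- sum(cl2 >= bs$start[2] & cl2 <= bs$stop[2])
  expect_gte(in1 / 200, 0.95)
  expect_gte(in2 / 150, 0.95)
  # brute-force oracle: recompute the neighbour counts by explicit scan
  ok_oracle <- vapply(seq_along(t), function(i)
    sum(abs(t - t[i]) <= 250e-6) >= 15, logical(1))
  for (b in seq_len(nrow(bs)))
    expect_true(all(ok_oracle[bs$start_idx[b]:bs$stop_idx[b]]))
})

test_that("indicator corrections follow the stated arithmetic", {
  # synthetic single burst: S_G = 100, S_R = 55, alpha = 0.05 -> E = 1/3
  t <- seq(0, 1e-3, length.out = 155)
  ch <- c(rep("donor", 100), rep("acceptor", 55))
  st <- photon_stream(t, rep(3, 155), ch, rep("none", 155))
  bursts <- data.frame(start_idx = 1L, stop_idx = 155L, start = 0,
                       stop = 1e-3, n_photons = 155L)
  bi <- burst_indicators(bursts, st, calibration_config(alpha = 0.05),
                         min_lifetime_photons = 20)
  expect_equal(bi$F_D, 100)
  expect_equal(bi$F_A, 50)
  expect_equal(bi$E, 1 / 3)
})

test_that("equal corrected counts give E = 1/2 and zero signal is flagged", {
  t <- seq(0, 1e-3, length.out = 200)
  ch <- rep(c("donor", "acceptor"), 100)
  st <- photon_stream(t, rep(3, 200), ch, rep("none", 200))
  bursts <- data.frame(start_idx = 1L, stop_idx = 200L, start = 0,
                       stop = 1e-3, n_photons = 200L)
  bi <- burst_indicators(bursts, st, calibration_config())
  expect_equal(bi$E, 0.5)
  # background subtraction removing everything flags the burst
  big_bg <- calibration_config(bg_donor = 2e5, bg_acceptor = 2e5)
  bi2 <- burst_indicators(bursts, st, big_bg)
  expect_equal(bi2$flag, "empty")
  expect_true(is.na(bi2$E))
})

test_that("PIE stoichiometry separates donor-only from dual-labelled", {
  p <- pair52()
  m <- kinetic_model(list(fret_species("S", p, efficiency = 0.5)),
                     matrix(0, 1, 1))
  cfg <- confocal_sim_config(
    burst_count = 400, pie = TRUE, seed = 21,
    calib = calibration_config(donor_only_fraction = 0.3))
  sim <- simulate_bursts(m, cfg)
  bi <- burst_indicators(burst_search(sim$stream), sim$stream, cfg$calib, p)
  mid <- (bi$start + bi$stop) / 2
  truth_idx <- vapply(mid, function(tt)
    which(sim$truth$start <= tt & sim$truth$stop >= tt)[1], numeric(1))
  do <- sim$truth$donor_only[truth_idx]
  called_do <- bi$S > 0.8
  expect_gt(mean(called_do == do, na.rm = TRUE), 0.99)
  # donor-only bursts sit at S ~ 1 (rare transit overlaps aside)
  expect_gt(median(bi$S[do], na.rm = TRUE), 0.95)
  expect_lt(median(bi$S[!do], na.rm = TRUE), 0.7)
})

test_that("mean fluorescence lifetime is the mixture moment estimator", {
  expect_equal(mean_fluorescence_lifetime(rep(1.5, 100), irf_offset = 1.5), 0)
  set.seed(3)
  x <- rexp(1e5, 1 / 2)
  expect_lt(abs(mean_fluorescence_lifetime(x) - 2), 3 * 2 / sqrt(1e5))
  # equal-amplitude 1 ns / 3 ns mixture -> fluorescence-weighted 2.5 ns
  y <- c(rexp(5e4, 1), rexp(15e4, 1 / 3))  # photon counts proportional to tau
  expect_lt(abs(mean_fluorescence_lifetime(y) - 2.5), 0.03)
  expect_true(is.na(mean_fluorescence_lifetime(rexp(5, 1), min_photons = 20)))
})

test_that("static simulations recover E and tau and sit on the static line", {
  p <- pair52()
  for (E in c(0.2, 0.5, 0.8)) {
    m <- kinetic_model(list(fret_species("S", p, efficiency = E)),
                       matrix(0, 1, 1))
    sim <- simulate_bursts(m, confocal_sim_config(burst_count = 2000,
                                                  seed = 30 + round(10 * E)))
    bi <- burst_indicators(burst_search(sim$stream), sim$stream,
                           calibration_config(), p)
    expect_gt(nrow(bi), 1200)
    expect_lt(abs(mean(bi$E, na.rm = TRUE) - E), 0.01)
    tau_true <- p$tau0 * (1 - E)
    expect_lt(abs(mean(bi$tau_f, na.rm = TRUE) - tau_true) / tau_true, 0.03)
    sl <- static_fret_line(p)
    expect_lt(abs(mean(bi$E, na.rm = TRUE) -
                    sl$evaluate(mean(bi$tau_f, na.rm = TRUE))), 0.02)
  }
})

test_that("correction round trip recovers E across alpha and backgrounds", {
  p <- pair52()
  m <- kinetic_model(list(fret_species("S", p, efficiency = 0.5)),
                     matrix(0, 1, 1))
  for (al in c(0, 0.05, 0.1)) {
    calib <- calibration_config(alpha = al, gamma = 1.3, bg_donor = 500,
                                bg_acceptor = 500)
    cfg <- confocal_sim_config(burst_count = 2000, calib = calib,
                               seed = 40 + round(100 * al))
    sim <- simulate_bursts(m, cfg)
    bi <- burst_indicators(burst_search(sim$stream), sim$stream, calib, p)
    se <- sd(bi$E, na.rm = TRUE) / sqrt(sum(!is.na(bi$E)))
    expect_lt(abs(mean(bi$E, na.rm = TRUE) - 0.5), 3 * se + 0.003)
  }
})

test_that("FRET lines have the stated endpoints and closed forms", {
  p <- pair52()
  sl <- static_fret_line(p)
  expect_equal(sl$evaluate(p$tau0), 0)
  expect_equal(sl$evaluate(0), 1)
  expect_equal(sl$evaluate(p$tau0 / 2), 0.5)
  s1 <- fret_species("A", dye_pair(52, 4), efficiency = 1 - 3.2 / 4)
  s2 <- fret_species("D", dye_pair(52, 4), efficiency = 1 - 0.8 / 4)
  dl <- dynamic_fret_line(s1, s2, dye_pair(52, 4))
  expect_equal(dl$evaluate(3.2), 1 - 3.2 / 4)   # meets static line
  expect_equal(dl$evaluate(0.8), 1 - 0.8 / 4)
  expect_equal(dl$evaluate(2.0), 1 - 2.56 / 8.0)
  expect_error(dl$evaluate(3.5), "outside")
})

test_that("fast-exchange centroid lies on the dynamic line within 0.03", {
  p <- pair52()
  s1 <- fret_species("A", p, efficiency = 0.8)
  s2 <- fret_species("D", p, efficiency = 0.1)
  m <- kinetic_model(list(s1, s2), matrix(c(0, 2e4, 2e4, 0), 2, 2,
                                          byrow = TRUE))
  sim <- simulate_bursts(m, confocal_sim_config(burst_count = 2000, seed = 12))
  bi <- burst_indicators(burst_search(sim$stream), sim$stream,
                         calibration_config(), p)
  dl <- dynamic_fret_line(s1, s2, p)
  cE <- mean(bi$E, na.rm = TRUE); ctau <- mean(bi$tau_f, na.rm = TRUE)
  expect_lt(abs(cE - dl$evaluate(ctau)), 0.03)
})

test_that("subensemble selection and the 2D histogram conserve bursts", {
  df <- data.frame(start_idx = 1:6, stop_idx = 1:6, start = 1:6, stop = 2:7,
                   E = c(0.01, 0.05, 0.066, 0.3, 0.9, NA),
                   tau_f = c(1, 2, 3, 2, 0.5, 1))
  sel <- select_subensemble(df, 0.065)
  expect_equal(sel$E, c(0.066, 0.3, 0.9))
  expect_equal(nrow(select_subensemble(df[df$E < 0.05 & !is.na(df$E), ],
                                       0.065)), 0L)
  sel0 <- select_subensemble(df, 0)
  expect_equal(nrow(sel0), 5L)   # identity on in-range bursts
  # brute-force filter oracle
  expect_equal(nrow(sel), sum(df$E > 0.065, na.rm = TRUE))
  h <- mfd_histogram2d(df)
  expect_equal(sum(h$counts) + h$overflow, nrow(df))
  h0 <- mfd_histogram2d(df[0, ])
  expect_true(all(h0$counts == 0))
})
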