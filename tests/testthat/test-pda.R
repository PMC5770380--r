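# Dynamic photon distribution analysis: window slicing, exact forward
# model, kinetic fitting, model comparison and subsampling uncertainties.

test_that("time-window slicing preserves counts and matches index arithmetic", {
  set.seed(1)
  n <- 3000
  t <- sort(runif(n, 0, 3.5e-3))
  ch <- sample(c("donor", "acceptor"), n, replace = TRUE)
  st <- photon_stream(t, rep(1, n), ch, rep("none", n))
  bursts <- data.frame(start_idx = 1L, stop_idx = n, start = 0,
                       stop = 3.5e-3, n_photons = n)
  w <- slice_time_windows(bursts, st, 1e-3)
  expect_equal(nrow(w), 3L)   # floor(3.5)
  # conservation over retained spans + brute-force index oracle
  for (k in 1:3) {
    in_win <- t >= (k - 1) * 1e-3 & t < k * 1e-3
    expect_equal(w$S_G[k], sum(in_win & ch == "donor"))
    expect_equal(w$S_R[k], sum(in_win & ch == "acceptor"))
  }
})

test_that("static single-species prediction is the exact binomial law", {
  sp <- data.frame(name = "S", E = 0.6, brightness = 1, sigma = 0)
  m <- pda_model(sp, branches = list(), static_fraction = 1,
                 static_weights = c(S = 1))
  breaks <- seq(0, 1, by = 0.02)
  pred <- pda_predict_histogram(m, 1e-3, rep(40L, 100), breaks = breaks)
  p <- fiberFRET:::pr_detection_prob(0.6, 1, 0)
  k <- 0:40
  i <- pmin(pmax(findInterval(k / 40, breaks, rightmost.closed = TRUE), 1), 50)
  exact <- as.vector(tapply(dbinom(k, 40, p), factor(i, levels = 1:50), sum))
  exact[is.na(exact)] <- 0
  expect_lt(max(abs(pred$prob - exact)), 1e-12)
  expect_equal(sum(pred$prob), 1, tolerance = 1e-9)
})

test_that("slow- and fast-exchange limits reduce to static mixtures", {
  breaks <- seq(0, 1, by = 0.02)
  Ns <- rep(60L, 1000)
  # dt << relaxation time: population-weighted static sum
  slow <- two_state_pda(5, 5)
  pred <- pda_predict_histogram(slow, 1e-3, Ns, breaks = breaks)
  stat <- pda_model(data.frame(name = c("H", "L"), E = c(0.8, 0.1),
                               brightness = 1, sigma = 0),
                    branches = list(), static_fraction = 1,
                    static_weights = c(H = 0.5, L = 0.5))
  pstat <- pda_predict_histogram(stat, 1e-3, Ns, breaks = breaks)
  expect_lt(sum(abs(pred$prob - pstat$prob)) / 2, 0.01)
  # dt >> relaxation time: single static species at the mean p
  fast <- two_state_pda(2e6, 2e6)
  predf <- pda_predict_histogram(fast, 1e-3, Ns, breaks = breaks)
  pbar <- mean(fiberFRET:::pr_detection_prob(c(0.8, 0.1), 1, 0))
  Ebar <- pbar
  statf <- pda_model(data.frame(name = "M", E = Ebar, brightness = 1,
                                sigma = 0),
                     branches = list(), static_fraction = 1,
                     static_weights = c(M = 1))
  pstatf <- pda_predict_histogram(statf, 1e-3, Ns, breaks = breaks)
  expect_lt(sum(abs(predf$prob - pstatf$prob)) / 2, 0.01)
})

test_that("prediction matches the window-level Monte-Carlo across regimes", {
  breaks <- seq(0, 1, by = 0.04)
  for (k12 in c(27, 270, 2700, 27000)) {
    mod <- two_state_pda(k12, k12)
    win <- simulate_pda_windows(mod, 1e-3, 2e4, mean_total = 50,
                                seed = 100 + round(log10(k12) * 10))
    obs <- pda_observed_histogram(win, breaks)
    pred <- pda_predict_histogram(mod, 1e-3, win$S_G + win$S_R,
                                  breaks = breaks)
    expect_lt(tvd_pred_obs(pred, obs$count), 0.025)
  }
})

test_that("donor-only, static and background components enter the forward model", {
  calib <- calibration_config(alpha = 0.03, gamma = 1.2, bg_donor = 2000,
                              bg_acceptor = 1500)
  mod <- two_state_pda(500, 700, static_fraction = 0.3, donor_only = 0.2,
                       calib = calib)
  win <- simulate_pda_windows(mod, 1e-3, 2e4, mean_total = 60, seed = 7)
  breaks <- seq(0, 1, by = 0.04)
  obs <- pda_observed_histogram(win, breaks)
  pred <- pda_predict_histogram(mod, 1e-3, win$S_G + win$S_R, breaks = breaks)
  expect_lt(tvd_pred_obs(pred, obs$count), 0.03)
  expect_equal(sum(pred$prob), 1, tolerance = 1e-9)
})

test_that("two-state rates are recovered from multi-window data", {
  truth <- two_state_pda(135, 135, E = c(0.8, 0.05))
  wins <- do.call(rbind, lapply(c(1e-3, 2e-3), function(dt)
    simulate_pda_windows(truth, dt, 6000, mean_total = 5e4 * dt,
                         seed = round(dt * 1e6))))
  tmpl <- two_state_pda(500, 500, E = c(0.7, 0.1))
  fit <- fit_kinetic_model(wins, tmpl,
                           free = c("rate.1.H.L", "rate.1.L.H", "E.H", "E.L"),
                           n_starts = 3, seed = 1, maxit = 300)
  relax <- 1 / (fit$par[["rate.1.H.L"]] + fit$par[["rate.1.L.H"]])
  expect_lt(abs(relax - 1 / 270) * 270, 0.2)
  expect_lt(abs(fit$par[["E.H"]] - 0.8), 0.05)
  # self-consistency: refitting from the fitted parameters stays put
  expect_lt(fit$chisq_red, 2)
})

test_that("static-only data fitted with an exchanging model pins the rates", {
  stat <- two_state_pda(1, 1, E = c(0.8, 0.05))  # essentially frozen mixture
  win <- simulate_pda_windows(stat, 1e-3, 8000, mean_total = 50, seed = 3)
  tmpl <- two_state_pda(500, 500, E = c(0.8, 0.05))
  fit <- fit_kinetic_model(win, tmpl, free = c("rate.1.H.L", "rate.1.L.H"),
                           n_starts = 3, seed = 2, maxit = 300)
  relax_fit <- 1 / (fit$par[["rate.1.H.L"]] + fit$par[["rate.1.L.H"]])
  # fitted exchange is much slower than the window (no dynamics visible)
  expect_gt(relax_fit, 5e-3)
  expect_lt(fit$chisq_red, 1.5)
})

test_that("model comparison is deterministic and flags identical templates", {
  truth <- two_state_pda(270, 270, E = c(0.8, 0.1))
  win <- simulate_pda_windows(truth, 1e-3, 5000, mean_total = 50, seed = 4)
  tmpl <- two_state_pda(500, 500, E = c(0.8, 0.1))
  cmp1 <- compare_models(win, list(a = tmpl, b = tmpl),
                         frees = list(c("rate.1.H.L", "rate.1.L.H")),
                         n_starts = 2, maxit = 200, seed = 5)
  cmp2 <- compare_models(win, list(a = tmpl, b = tmpl),
                         frees = list(c("rate.1.H.L", "rate.1.L.H")),
                         n_starts = 2, maxit = 200, seed = 5)
  expect_identical(cmp1$ranking$chisq_red, cmp2$ranking$chisq_red)
  # identical templates give identical chi-squared, flagged equivalent
  expect_equal(cmp1$ranking$chisq_red[1], cmp1$ranking$chisq_red[2],
               tolerance = 1e-10)
  expect_true(all(cmp1$ranking$equivalent))
})

test_that("subsampling uncertainties are small and shrink with window count", {
  truth <- two_state_pda(270, 270, E = c(0.8, 0.1))
  win1 <- simulate_pda_windows(truth, 1e-3, 4000, mean_total = 50, seed = 6)
  win2 <- simulate_pda_windows(truth, 1e-3, 16000, mean_total = 50, seed = 7)
  tmpl <- two_state_pda(400, 400, E = c(0.8, 0.1))
  su1 <- subsample_uncertainty(win1, tmpl,
                               free = c("rate.1.H.L", "rate.1.L.H"),
                               replicates = 3, seed = 1, n_starts = 2,
                               maxit = 250)
  su2 <- subsample_uncertainty(win2, tmpl,
                               free = c("rate.1.H.L", "rate.1.L.H"),
                               replicates = 3, seed = 1, n_starts = 2,
                               maxit = 250)
  expect_true(all(is.finite(su1$sd)))
  # relative sd at 4x windows is smaller (sqrt-n scaling, loose factor)
  rel1 <- mean(su1$sd / su1$full_fit$par[names(su1$sd)])
  rel2 <- mean(su2$sd / su2$full_fit$par[names(su2$sd)])
  expect_lt(rel2, rel1)
  expect_lt(rel1, 0.5)
})

test_that("population summaries combine static and dynamic pools correctly", {
  # all-static model: populations equal the static weights exactly
  spd <- data.frame(name = c("H", "L"), E = c(0.8, 0.1), brightness = 1,
                    sigma = 0)
  m1 <- pda_model(spd, branches = list(list(
    states = c("H", "L"),
    rates = matrix(c(0, 100, 300, 0), 2, 2, byrow = TRUE))),
    static_fraction = 1, static_weights = c(H = 0.3, L = 0.7))
  s1 <- species_population_summary(m1)
  expect_equal(s1$total, c(0.3, 0.7))
  # pure two-state exchanging model: stationary law
  m2 <- pda_model(spd, branches = list(list(
    states = c("H", "L"),
    rates = matrix(c(0, 100, 300, 0), 2, 2, byrow = TRUE))))
  s2 <- species_population_summary(m2)
  expect_equal(s2$total, c(0.75, 0.25))
  expect_equal(sum(s2$total), 1, tolerance = 1e-9)
  # monotone rates across synthetic conditions -> monotone populations
  pops <- vapply(c(100, 200, 400, 800), function(k21) {
    mm <- pda_model(spd, branches = list(list(
      states = c("H", "L"),
      rates = matrix(c(0, 100, k21, 0), 2, 2, byrow = TRUE))))
    species_population_summary(mm)$total[1]
  }, numeric(1))
  expect_true(all(diff(pops) > 0))
})
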