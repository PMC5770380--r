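# Kinetic primitives: the Foerster distance map, rate-matrix spectral
# quantities, Gillespie sampling and the two-state occupancy-time law.

test_that("efficiency/distance maps follow the Foerster relation and invert", {
  p <- pair82()
  expect_equal(efficiency_from_distance(82, p), 0.5)
  expect_equal(efficiency_from_distance(164, p), 1 / 65)
  expect_equal(efficiency_from_distance(41, p), 64 / 65)
  expect_equal(distance_from_efficiency(0.5, p), 82)
  expect_equal(distance_from_efficiency(1 / 65, p), 164)
  R <- seq(30, 150, by = 5)
  expect_equal(distance_from_efficiency(efficiency_from_distance(R, p), p),
               R, tolerance = 1e-9)
  # strict monotonicity
  expect_true(all(diff(efficiency_from_distance(R, p)) < 0))
  expect_error(efficiency_from_distance(-1, p))
  expect_error(distance_from_efficiency(0, p))
  expect_error(distance_from_efficiency(1, p))
})

test_that("fret_species ties efficiency, distance and lifetime together", {
  p <- pair52()
  s <- fret_species("A", p, distance = 52)
  expect_equal(s$E, 0.5)
  expect_equal(s$tau_DA, p$tau0 * 0.5)
  s2 <- fret_species("B", p, efficiency = 0.8)
  expect_equal(s2$R_DA, distance_from_efficiency(0.8, p))
})

test_that("kinetic model validates its generator and connectivity", {
  m <- two_state_model(100, 300)
  expect_equal(rowSums(m$K), c(H = 0, L = 0), tolerance = 1e-12)
  # forbidden transitions stay at zero
  expect_error(kinetic_model(c("a", "b", "c"),
                             matrix(c(0, 1, 1, 1, 0, 1, 1, 1, 0), 3, 3),
                             connectivity = matrix(c(F, T, F, T, F, F,
                                                     F, F, F), 3, 3)),
               "outside the connectivity")
  # reducible models are rejected
  expect_error(kinetic_model(c("a", "b", "c"),
                             matrix(c(0, 10, 0, 10, 0, 0, 0, 0, 0), 3, 3,
                                    byrow = TRUE)),
               "reducible")
})

test_that("relaxation times match the two-state closed form and eigen oracle", {
  expect_equal(relaxation_times(two_state_model(135, 135)),
               1 / 270, tolerance = 1e-12)  # 3.7037 ms
  expect_equal(relaxation_times(two_state_model(8333.3, 8333.3)),
               60.0e-6, tolerance = 1e-4)
  for (seed in 1:5) for (S in 3:5) {
    K <- random_generator(S, seed * 10 + S)
    m <- kinetic_model(letters[1:S], K)
    ev <- eigen(m$K, only.values = TRUE)$values
    oracle <- sort(-1 / Re(ev[abs(Re(ev)) > 1e-8]))
    expect_equal(relaxation_times(m), oracle, tolerance = 1e-10)
  }
})

test_that("stationary distribution is the left null vector", {
  expect_equal(unname(stationary_distribution(two_state_model(1000, 1000))),
               c(0.5, 0.5))
  expect_equal(unname(stationary_distribution(two_state_model(100, 300))),
               c(0.75, 0.25))
  for (seed in 1:5) {
    m <- kinetic_model(letters[1:4], random_generator(4, seed))
    pi <- stationary_distribution(m)
    expect_equal(sum(pi), 1, tolerance = 1e-12)
    expect_lt(max(abs(pi %*% m$K)), 1e-10)
    expect_true(all(pi > 0))
  }
})

test_that("Gillespie trajectories have exact occupancy and jump statistics", {
  m1 <- single_state_model()
  tr <- sample_trajectory(m1, 1, seed = 1)
  expect_equal(length(tr$states), 1L)

  m <- two_state_model(1000, 1000)
  set.seed(42)
  occ <- jumps <- numeric(200)
  for (r in 1:200) {
    tr <- sample_trajectory(m, 10)
    seg <- diff(c(tr$jump_times, tr$duration))
    occ[r] <- sum(seg[tr$states == 1]) / 10
    jumps[r] <- length(tr$states) - 1
  }
  # stationary occupancy 0.5 within 3 s.e.
  expect_lt(abs(mean(occ) - 0.5), 3 * sd(occ) / sqrt(200))
  # mean jump count = sum_i pi_i * exit_i * T = 1000 * 10
  expect_lt(abs(mean(jumps) - 1e4), 3 * sd(jumps) / sqrt(200))
})

test_that("two-state occupancy law is a proper distribution with the stated masses", {
  for (k in list(c(1000, 1000), c(100, 300), c(5000, 500))) {
    for (Tw in c(2e-4, 1e-3, 5e-3)) {
      m <- two_state_model(k[1], k[2])
      law <- occupancy_fraction_density(m, Tw)
      pi <- stationary_distribution(m)
      expect_equal(law$mass1, unname(pi[1] * exp(-k[1] * Tw)), tolerance = 1e-12)
      expect_equal(law$mass0, unname(pi[2] * exp(-k[2] * Tw)), tolerance = 1e-12)
      total <- law$mass0 + law$mass1 +
        integrate(law$density, 0, 1, rel.tol = 1e-10)$value
      expect_equal(total, 1, tolerance = 1e-8)
    }
  }
})

test_that("occupancy law limits: no-jump masses at short T, ergodic at long T", {
  m <- two_state_model(100, 300)
  pi <- stationary_distribution(m)
  law <- occupancy_fraction_density(m, 1e-7)
  expect_equal(law$mass1, unname(pi[1]), tolerance = 1e-4)
  expect_equal(law$mass0, unname(pi[2]), tolerance = 1e-4)
  # T >> relaxation time: concentrates at pi1
  g <- occupancy_fraction_grid(m, 2, n_grid = 2001)
  mn <- sum(g$x * g$prob)
  v <- sum((g$x - mn)^2 * g$prob)
  expect_lt(abs(mn - pi[1]), 1e-3)
  expect_lt(v, 1e-3)
})

test_that("occupancy law matches the Gillespie oracle across T/t_R 0.1-10", {
  m <- two_state_model(1000, 1000)   # relaxation 0.5 ms
  tR <- relaxation_times(m)
  for (ratio in c(0.1, 1, 10)) {
    Tw <- ratio * tR
    g <- occupancy_fraction_grid(m, Tw, n_grid = 1001)
    cdf_a <- cumsum(g$prob)
    fr <- occupancy_fraction_sample(m, Tw, 1e5, seed = round(1000 * ratio))[, 1]
    cdf_mc <- ecdf(fr)(g$x)
    expect_lt(max(abs(cdf_a - cdf_mc)), 0.02)
  }
})

test_that("kinetic model config round-trips exactly", {
  m <- two_state_model(123.456789012345, 987.654321098765,
                       static_fraction = 0.3)
  path <- tempfile(fileext = ".yaml")
  write_kinetic_model(m, path)
  m2 <- read_kinetic_model(path)
  expect_identical(m2$K, m$K)
  expect_identical(m2$static_fraction, m$static_fraction)
  expect_identical(as.numeric(m2$static_weights), as.numeric(m$static_weights))
  expect_identical(species_efficiencies(m2), species_efficiencies(m))
})
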