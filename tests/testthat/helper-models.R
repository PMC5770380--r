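# Shared fixtures: dye pairs and kinetic models used across the suite.

pair82 <- function() dye_pair(82, 3.8, "Alexa568/647")
pair52 <- function() dye_pair(52, 4.0, "Alexa488/647")

two_state_model <- function(k12 = 1000, k21 = 1000, E = c(0.8, 0.1),
                            pair = pair52(), static_fraction = 0,
                            names = c("H", "L")) {
  sp <- list(fret_species(names[1], pair, efficiency = E[1]),
             fret_species(names[2], pair, efficiency = E[2]))
  kinetic_model(sp, matrix(c(0, k12, k21, 0), 2, 2, byrow = TRUE),
                static_fraction = static_fraction)
}

single_state_model <- function(E = 0.5, pair = pair52(), name = "S") {
  kinetic_model(list(fret_species(name, pair, efficiency = E)),
                matrix(0, 1, 1))
}

random_generator <- function(S, seed) {
  set.seed(seed)
  K <- matrix(stats::runif(S * S, 0.2, 2) * 1000, S, S)
  diag(K) <- 0
  K
}

# simple two-state PDA template over species H (high E) and L (low E)
two_state_pda <- function(k12 = 270, k21 = 270, E = c(0.8, 0.1),
                          static_fraction = 0, donor_only = 0,
                          calib = calibration_config()) {
  sp <- data.frame(name = c("H", "L"), E = E, brightness = 1, sigma = 0)
  pda_model(sp,
            branches = list(list(states = c("H", "L"),
                                 rates = matrix(c(0, k12, k21, 0), 2, 2,
                                                byrow = TRUE))),
            static_fraction = static_fraction,
            donor_only_fraction = donor_only, calib = calib)
}

# total-variation distance between a predicted histogram and observed counts
tvd_pred_obs <- function(pred, counts) {
  p <- pred$prob / sum(pred$prob)
  q <- counts / sum(counts)
  sum(abs(p - q)) / 2
}
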