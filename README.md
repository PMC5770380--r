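# fiberFRET

Multimodal single-molecule FRET analysis of chromatin fiber structural
dynamics, built as a reusable R package plus a numbered analysis workflow
(`analysis/01…08`).

## The problem

Chromatin fibers are not static: nucleosomes stack transiently into
tetranucleosome units, and the *register* of stacking (which neighbour a
nucleosome pairs with) interconverts through open intermediates. These
motions span microseconds to seconds, far beyond the reach of any single
measurement. Two complementary single-molecule FRET modalities cover the
range:

* **Confocal multiparameter fluorescence detection (MFD)** of freely
  diffusing fibers — photon bursts give per-molecule intensities,
  FRET efficiency `E`, the fluorescence-weighted donor lifetime
  `⟨τ_D(A)⟩_F`, and (with pulsed interleaved excitation, PIE)
  stoichiometry; µs–ms dynamics appear in photon statistics and
  correlation functions.
* **smTIRF microscopy** of immobilised fibers at 100 ms frames —
  slow (0.1 s – minutes) switching, photobleaching-verified traces and
  injection (compaction) kinetics.

The package implements the full analysis chain for both: kinetic models,
burst search and corrected MFD indicators with static/dynamic FRET lines,
subensemble lifetime analysis of the FRET-induced donor decay
`ε_D(t) = Σᵢ xᵢ e^(−kᵢt)` with `kᵢ = (R₀/Rᵢ)⁶/τ₀`, multi-tau FCS with
global kinetic fitting, dynamic photon distribution analysis (dynPDA),
TIRF trace selection/population/correlation analysis, and accessible
contact volume (ACV) screening of candidate structures against measured
distance sets. A synthetic-data module generates photon streams and camera
traces with known ground truth, so every stage is verified by parameter
recovery.

## The core method: dynPDA

For a window of duration `Δt` holding `N` detected photons, the acceptor
count is binomial at the species' detection probability. A molecule
exchanging between states spends a random fraction `x` of the window in
each; for a two-state branch the law of `x` has point masses
`π₁e^(−k₁₂Δt)`, `π₂e^(−k₂₁Δt)` and a continuous Bessel-function density,
which the package evaluates analytically (larger branches use a seeded
Gillespie kernel). Mixing the binomial over that law — plus static
(locked) molecules, a donor-only contaminant, crosstalk `α`, detection
ratio `γ` and Poisson background — predicts the proximity-ratio histogram
exactly; rates and populations are fitted by Pearson χ² across several
`Δt` and conditions simultaneously, connectivities are ranked by reduced
χ², and uncertainties come from refitting 70% subsamples. Two-branch
schemes (register 1 `A–C–D`, register 2 `B–D`, no interchange on the
observation timescale) are expressed as weighted mixtures of irreducible
branches.

## Worked example

```r
library(fiberFRET)
pair  <- dye_pair(52, 4, "Alexa488/647")          # R0 = 52 A, tau0 = 4 ns
model <- kinetic_model(
  list(fret_species("stacked", pair, efficiency = 0.8),
       fret_species("open",    pair, efficiency = 0.15)),
  matrix(c(0, 135, 135, 0), 2, 2, byrow = TRUE))  # 135 s^-1 each way
relaxation_times(model)                            # 0.0037 s

sim    <- simulate_bursts(model, confocal_sim_config(burst_count = 800,
                                                     seed = 42))
bursts <- burst_indicators(burst_search(sim$stream), sim$stream,
                           calibration_config(), pair)
wins <- do.call(rbind, lapply(c(1e-3, 2e-3, 3e-3), function(dt)
  slice_time_windows(bursts, sim$stream, dt)))
tmpl <- pda_model(data.frame(name = c("stacked", "open"), E = c(0.7, 0.2),
                             brightness = 1, sigma = 0),
                  branches = list(list(states = c("stacked", "open"),
                                       rates = matrix(c(0, 500, 500, 0),
                                                      2, 2, byrow = TRUE))))
fit <- fit_kinetic_model(wins, tmpl,
                         free = c("rate.1.stacked.open",
                                  "rate.1.open.stacked",
                                  "E.stacked", "E.open"),
                         n_starts = 3, seed = 1)
```

This prints, on the session it was run:

```
relaxation time: 3.70 ms
620 bursts, mean E = 0.50, mean tau = 2.40 ns
dynPDA: relaxation 3.34 ms, E = 0.80 / 0.15 (chi2_red 1.02)
```

The burst centroid at `E ≈ 0.5` between the two species is the signature
of exchange faster than the transit; dynPDA resolves the underlying
states (`E = 0.80/0.15`, recovered from start values `0.7/0.2`) and the
millisecond relaxation time from the window-size dependence of the
histograms.

The numbered scripts under `analysis/` run the complete study on
synthetic data (simulation → burst/MFD → subensemble lifetime → FCS →
dynPDA → TIRF → structure screen) and write their tables under
`results/`:

```sh
for f in analysis/0*.R; do Rscript "$f"; done   # from the repository root
```

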