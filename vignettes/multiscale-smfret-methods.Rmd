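---
title: "Models and methods for multiscale chromatin smFRET analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for multiscale chromatin smFRET analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fiberFRET)
```

This vignette is the package's account of its science: the models behind
each analysis stage, the assumptions they make, the tunable parameters
and their defaults, the numerical choices, and the known limits. All
quantitative statements about recovery accuracy are the ones the test
suite itself computes.

## 1. Kinetic model

Conformational exchange is modelled as a continuous-time Markov chain over
a small set of FRET species. Each species carries an inter-dye distance
$R_{DA}$, the Förster efficiency $E = 1/(1 + (R_{DA}/R_0)^6)$, the
quenched donor lifetime $\tau_{D(A)} = \tau_0(1-E)$ and a relative
brightness. The generator $K$ uses the row convention ($K_{ij}$, $i\neq j$,
is the $i\to j$ rate in s$^{-1}$; rows sum to zero); rates are always per
second and times seconds at interfaces, with nanoseconds reserved for
TCSPC micro-times. The exchanging graph of one model must be irreducible;
relaxation times are $-1/\lambda$ over the nonzero eigenvalues of $K$
(exactly $1/(k_{12}+k_{21})$ for two states) and equilibrium populations
are the left null vector of $K$.

Two features of chromatin data sit on top of this chain:

* a **static (locked) subpopulation**: a per-molecule Bernoulli flag with
  its own state-probability vector (default: the stationary law). Nothing
  in the data constrains the composition rule of locked molecules, so it
  is a free vector rather than a derived one.
* **non-interchanging branches**: the two stacking registers exchange
  internally but not with each other on the ~10 ms observation scale.
  A reducible chain would break every spectral routine, so branch schemes
  are expressed in the dynPDA layer as *weighted mixtures of irreducible
  models* (e.g. register 1 = A–C–D, register 2 = B–D), which is exactly
  the physical statement "two coexisting subpopulations".

Trajectories are sampled by an exact Gillespie kernel (compiled, driven by
R's RNG so `set.seed()` controls everything). Initial states default to
the stationary law but can be overridden for injection-style
non-equilibrium starts.

### Occupancy-time law

dynPDA needs the distribution of the fraction $x$ of a window $T$ spent
in state 1 of a two-state chain. Splitting trajectories by their number
of transitions and integrating the sojourn volumes gives point masses
$P(x{=}1) = \pi_1 e^{-k_{12}T}$, $P(x{=}0) = \pi_2 e^{-k_{21}T}$ and the
continuous density

$$p(x) = T\,e^{-k_{12}Tx - k_{21}T(1-x)}\Big[(\pi_1 k_{12} + \pi_2 k_{21})
I_0(2\sqrt{u}) + k_{12}k_{21}T\,(\pi_1 x + \pi_2(1-x))\,
\tfrac{I_1(2\sqrt{u})}{\sqrt{u}}\Big],\quad u = k_{12}k_{21}T^2x(1-x),$$

evaluated with exponentially scaled Bessel functions to stay finite at
$k T \gg 1$. The law integrates to one to $10^{-8}$ and matches Gillespie
sampling with a Kolmogorov–Smirnov distance below 0.02 at $10^5$ samples
across $T$ from a tenth to ten times the relaxation time (asserted in the
tests). Branches with more than two states use the seeded Monte-Carlo
kernel (default $10^4$ trajectories per evaluation, fixed seed per fit so
objectives are deterministic).

## 2. What the simulators emulate — and what they do not

The **confocal simulator** draws exponential top-hat transits (default
mean 3 ms, brightness $5\times10^4$ counts/s at focus), runs a Gillespie
path per molecule, emits photons as a thinned Poisson process, routes them
donor/acceptor with probability $\gamma E/(\gamma E + 1 - E)$, adds
crosstalk and per-channel Poisson background, draws micro-times from the
species lifetime convolved with a Gaussian IRF (default width 0.25 ns,
offset 2 ns) folded into the 31.25 ns excitation period, and — under PIE —
adds direct acceptor-excitation photons in the slot shifted by 15.625 ns
(two interleaved 32 MHz trains). A configurable fraction of molecules is
donor-only ($E = 0$) and another fraction is locked.

Deliberate simplifications: the diffusion envelope is a top-hat, not a 3D
Gaussian path, so burst-duration and brightness distributions are cleaner
than in real data (this is what makes PDA and FCS recoveries exactly
checkable); there is no triplet blinking, no acceptor photophysics beyond
a fixed lifetime, and no detector afterpulsing. Passing tests therefore
demonstrate correctness of the estimators under the stated photon
statistics, not robustness to every instrumental artifact.

**Crosstalk convention.** Corrections in burst analysis follow
$F_D = S_G - b_G$, $F_A = S_R - b_R - \alpha F_D$,
$E = F_A/(F_A + \gamma F_D)$. For that correction to be exact, crosstalk
photons must be *additional* acceptor-channel registrations (a donor
photon also seen by the red detector), and the simulator implements them
that way; at $E=0$ the acceptor/donor count ratio is then $\alpha$. The
simulator and the corrections are deliberately mirror images — the
round-trip test (recovering $E$ to within sampling error for
$\alpha \in \{0, 0.05, 0.1\}$) depends on it.

The **TIRF simulator** produces frame-integrated two-channel traces
(default 100 ms frames, 120 s, 1000 counts/frame): the frame-averaged
efficiency of a slow two-state path sets anti-correlated donor/acceptor
means with bleed-through $\beta$ (default 0.1), single-step exponential
bleaching per dye (acceptor bleach returns the donor to the pre-bleach
total; donor bleach drops both channels), and camera noise as Poisson
counts, gain, and Gaussian read noise. EMCCD excess noise is out of scope.
Injection runs switch a responder fraction permanently to the compact
state at an exponential waiting time after the injection, so the
responder-averaged efficiency approaches its plateau with exactly that
time constant.

## 3. Burst analysis and FRET lines

The all-photon sliding-window search accepts photons with at least $m$
neighbours (self included) within a centred window (defaults 500 µs,
$m = 15$, 60 photons per burst). Runs are additionally split where
consecutive photons are farther apart than the window — photons that far
apart cannot share a window, and without this rule background-free
simulated transits would merge into one index-contiguous run.

The lifetime estimator is the micro-time moment (mean micro-time minus the
IRF offset), which estimates the fluorescence-weighted lifetime
$\sum a_i\tau_i^2/\sum a_i\tau_i$ — robust at per-burst photon counts
where maximum-likelihood deconvolution is not. The static FRET line is
$E = 1 - \tau/\tau_0$ (a linker-correction polynomial is accepted as a
calibration hook and defaults to zero); the dynamic line between species
1 and 2 is $E = 1 - \tau_1\tau_2/(\tau_0(\tau_1+\tau_2-\tau))$, which is
an exact identity for two-component mixtures: the intensity-averaged $E$
and the fluorescence-weighted lifetime of any mixing fraction lie on it.

Donor-only molecules are removed by PIE stoichiometry when acceptor
excitation slots exist, and otherwise kept and modelled in PDA as an
$E \approx 0$ component — mirroring the one-colour-excitation
measurements where PIE was unavailable and the subensemble is instead
selected by $E > 0.065$.

## 4. Subensemble lifetime analysis

The FRET-induced donor decay divides the subensemble donor decay by a
donor-only reference with the same binning (default 0.05 ns bins). For
discrete species with molecule fractions $x_i$,
$\varepsilon_D(t) = \sum_i x_i e^{-k_i t}$ with
$k_i = (R_0/R_i)^6/\tau_0$ — the radiative amplitude cancels because the
photon yield of species $i$ scales as $\tau_i$. Two numerical points
matter:

* **Self-normalisation.** The same yield identity fixes the ratio's
  overall scale: $N_F/N_D = \sum_i x_i \tau_i/\tau_0$ up to range
  truncation, which the fit model computes from its own parameters. This
  removes the free amplitude that otherwise makes multi-exponential
  fitting hopelessly sloppy, and it is why the fractions-sum-to-one
  constraint has teeth.
* **IRF treatment.** The Gaussian IRF largely cancels in the ratio, but
  the per-component amplitude factor $e^{\sigma^2(a_i^2-a_0^2)/2}$ and the
  prompt-edge error function do not; both are modelled exactly
  (`epsilon_component()`), which removes a percent-level coherent
  residual that would otherwise bias distances.

The reported $\varepsilon$ is normalised to 1 at $t = 0$ by a
non-negative least-squares expansion on a log-spaced rate grid capped at
$3/t_{\min}$ (faster components are unconstrained by the analysis range
and would destabilise the extrapolation); the peaks of that spectrum also
seed the discrete fit, which then runs bounded multi-start L-BFGS-B with
a simplex polish. Distances are bounded in $[0.3, 3]R_0$, the upper bound
acting as the no-FRET limit.

**Identifiability limit.** Multi-exponential decomposition is an
ill-posed inverse problem. The package's tests demonstrate accurate
recovery for species within roughly $0.6$–$1.3R_0$; distances near
$2R_0$ (efficiencies of a few percent) are not determined at
$10^6$-photon statistics by any estimator — the Fisher information of the
decay model bounds their relative error far above the few-percent level.
Such species' *fractions* remain approximately recoverable through the
normalisation identity, but their distances should be treated as lower
bounds. This is the package's stated reason for measuring long distances
with a larger-$R_0$ dye pair instead.

## 5. Fluorescence correlation

`correlate_multitau()` computes $G(\tau)$ on a quasi-logarithmic grid
(defaults: 1 µs base lag, 8 points per octave, up to 1 s) by binning
photon arrivals at the lag-matched resolution with symmetric
normalisation. Uncertainties are the scatter over 10 contiguous segments,
floored by the Poisson pair-count shot noise (the segment estimate is
unreliable exactly where pairs are scarce). The global fit shares the
relaxation times (and optionally a 3D-Gaussian diffusion time, axial
ratio 5) across curves and profiles all linear parameters (amplitudes,
$1/N$, baseline) out by weighted least squares, leaving a 1–3 dimensional
deterministic search. For immobilised/telegraph sources the
number-fluctuation factor is dropped and amplitudes are absolute with a
free baseline. The FRET sign convention — positive kinetic amplitudes in
the autocorrelations, negative in the donor–acceptor cross-correlation —
is asserted on simulations.

## 6. dynPDA

The fit axis is the uncorrected proximity ratio $S_R/(S_G+S_R)$ (default
0.02-wide bins); all corrections live in the forward map, keeping the
count likelihood exact. Conditional on each observed window total, the
acceptor count is a mixture of binomials over the model's component
detection probabilities $p = (\gamma E + \alpha(1-E)(1+\ldots))$, with
the exchanging pool integrated over the occupancy law (analytic
two-state density on a 61–101 point grid, Monte-Carlo otherwise),
brightness-weighted time averages for unequal species brightness, and
optional per-species Gaussian distance broadening (7-point
Gauss–Hermite). Poisson background enters asymmetrically: acceptor
background counts shift the acceptor count directly and are convolved
exactly (truncated at $10^{-7}$ tail mass), while donor background only
dilutes the green channel and is folded in by deflating each component's
detection probability — the conditional mean stays exact and the variance
error is of order $\lambda_g p^2$, far below counting noise. Binomial bin
masses are evaluated as `pbinom` differences at count edges that
replicate the observed histogram's floating-point binning exactly, in a
single stacked call.

Fitting minimises the summed Pearson $\chi^2$ over all window durations
and conditions, with adjacent bins pooled until each group holds at least
five *observed* windows (pooling fixed by data, so the objective surface
is continuous). Free parameters are addressed by name
(`rate.<branch>.<from>.<to>`, `E.<species>`, `w.<branch>`,
`static_fraction`, `donor_only`), log/logit-transformed, and optimised by
Nelder–Mead from a seeded Latin-hypercube of starts (the template is
always one start) with a polish pass. Default window durations for burst
slicing are 1/2/3 ms fitted jointly; sub-millisecond windows resolve the
fast branch. During fitting, nearby totals are pooled into 50 count
classes and the occupancy cloud is collapsed onto 25 equal-mass nodes
(no-transition endpoint masses kept distinct) — forward-model speed-ups
whose error is far below counting noise; reported predictions use the
full resolution. Model comparison refits each connectivity with identical settings
and ranks by global reduced $\chi^2$ (5% equivalence band); register
exchange within the open species is excluded by construction because the
two registers live in separate branches. Uncertainties follow the
subsampling protocol: three refits on random 70% window subsets,
reported as per-parameter standard deviations.

## 7. TIRF traces

Selection applies the four criteria in order — initial
donor + $\beta$-corrected acceptor total above 600 counts over baseline,
at least 5 s before the first bleach (10 s for injections), single-step
bleaching (including donor recovery to the pre-bleach total after an
acceptor bleach, and an intact directly-probed acceptor after a donor
bleach), and donor bleaching within the 120 s acquisition — and each
rejection carries the first failing criterion. When annotations are
absent, bleach steps come from a two-segment cumulative-mean step finder
with a minimum step of five frame-noise standard deviations; the
single-step check runs on the *total* intensity, which is invariant under
FRET exchange but steps on bleaching.

Population analysis is a least-squares Gaussian fit to the binned
efficiency histogram (default 0.02 bins; means are bin-width invariant in
the tests), with k-quantile start points under a fixed seed. The
donor–acceptor cross-correlation is computed per trace on mean-subtracted
valid frames, pooled with s.e.m., and fitted beyond lag zero (shot-noise
spike) by one or two exponentials *plus a free constant* — per-trace mean
subtraction biases finite-trace correlations by a constant offset which
otherwise drags the fitted time down by tens of percent. The single- vs
two-component choice is an F-test at $\alpha = 0.05$ with a degeneracy
guard (component times closer than 1.5-fold, or wildly cancelling
amplitudes, fall back to one component). A trace counts as dynamic when
its projected amplitude exceeds three standard errors. Injection fits
classify responders by a pre/post mean-efficiency shift (default
threshold 0.15) and fit the responder-averaged efficiency with a
profiled single exponential; the 95% CI comes from the profile
curvature.

## 8. Accessible volumes and screening

Dye positions are modelled on a regular grid (default 1 Å): a position is
allowed when it clears every obstacle atom by the dye radius, and its
geodesic distance from the attachment — 26-neighbour lattice relaxation
through allowed space — stays within the linker length. Because the
lattice metric overestimates Euclidean lengths by a few percent,
contested points (within straight-line reach but rejected by the lattice
pass) are admitted after a sampled line-of-sight check; free and convex
regions are thereby exact, which the ball-volume test verifies to 2%.
ACV mode doubles the weight of positions within a 3 Å contact shell of
the obstacle surface. The reported distance is the weighted mean over
position *pairs* $\langle R_{DA}\rangle$ (matching FRET averaging), exact
below $4\times10^6$ pairs and seeded-sampled above, with the two volumes
ordered canonically so the estimate is symmetric. Screening computes
$\chi^2 = \sum ((\langle R_{model}\rangle - R_{meas})/\Delta R)^2$ per
candidate and species, flags $\chi^2/n \le 1$, and excludes pairs a
candidate cannot provide. Obstacles are read from PDB files via `bio3d`
with element-based van-der-Waals radii, hydrogens ignored; the AV1
single-radius dye model is the default, with linker length/width and dye
radius as free configuration.

## 9. Problem sizes and determinism

The bundled studies are sized for a desk machine: $10^5$ windows for
oracle-equivalence checks, $2\times10^4$ windows per duration for rate
recovery, $5\times10^4$ windows for connectivity comparison, $10^6$
photons for lifetime fits, ~$10^6$ photons for correlation, 100 traces
of 1200 frames for TIRF. Every random stage is seeded, including the
Monte-Carlo kernels inside fit objectives (seed fan-out:
`100*seed + stage`), so a workflow rerun under the same configuration is
byte-identical — asserted by the end-to-end test.

## 10. Known limitations

* Multi-exponential lifetime decomposition beyond ~$1.3R_0$ is
  information-limited (section 4); use the matched dye pair.
* Filtered (species-weighted) FCS and lifetime-gated correlations are not
  implemented; plain channel correlations carry the kinetic terms used
  here.
* Photobleaching/blinking artefact analysis of confocal data is reduced
  to a simulator flag plus the burst-selection filters; the camera-trace
  pipeline starts at extracted traces (no image processing).
* dynPDA assumes Markovian exchange and discrete species; apparent-width
  parameters absorb residual heterogeneity but are not a distance
  distribution model.
* Detailed balance is not enforced — rates are free parameters.
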