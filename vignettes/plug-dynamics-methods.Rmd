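---
title: "Methods: smFRET kinetics of translocon plug dynamics"
author: "plugdyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: smFRET kinetics of translocon plug dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(plugdyn)
```

# The system and the measurement

The SecYEG translocon's plug helix seals the protein-conducting
channel. A donor/acceptor dye pair placed on the plug and a cytoplasmic
reference site reports the plug position through FRET: the closed
conformation sits near E ≈ 0.4 and the open (translocating)
conformation near E ≈ 0.2. `plugdyn` implements the two complementary
single-molecule readouts of this system and the kinetic analyses built
on them:

* **µsALEX confocal bursts** from freely diffusing proteoliposomes —
  microsecond-alternating two-colour excitation yields, per burst, the
  proximity ratio PR, corrected FRET efficiency E and stoichiometry S.
  Millisecond kinetics follow from *recurrence analysis of single
  particles* (RASP) and within-burst dynamics from *burst variance
  analysis* (BVA).
* **msALEX TIRF traces** from immobilised proteoliposomes — 100 ms
  alternating excitation frames give per-frame E and S; hidden-Markov
  segmentation yields open/closed dwell times on the seconds scale,
  from which the intrinsic translocation rate is obtained by
  regressing dwell time on substrate length.

No public raw dataset accompanies these experiments, so every
analysis stage is paired with a synthetic-data generator whose
defaults encode the experimental conditions; each claim is then
tested as a parameter-recovery experiment with known ground truth.

# Confocal simulation and burst search

`simulateConfocalPhotons()` propagates point emitters by Brownian
steps (default 10 µs) through a periodic box that is by default 10×
each 1/e² waist of a 3D-Gaussian detection profile, switching
conformations as a continuous-time Markov chain and emitting photons
as an inhomogeneous Poisson process partitioned by the ALEX slot
(40 µs period, 40% donor duty cycle) and by the current state's E.
Background is continuous per channel. Neither the confocal geometry nor the laser-power-to-brightness
calibration is publicly reported for this experiment; the module defaults
(0.35 µm lateral / 1.5 µm axial waists, D = 4.4 µm²/s for 100 nm
vesicles by Stokes–Einstein) are physically motivated stand-ins and every one is
config-exposed.

Background rates are estimated per time window by the
maximum-likelihood exponential fit to inter-photon delays with
iterative exclusion of burst photons (delays under twice the current
mean delay, two passes, left-truncation corrected). The dual-channel
burst search marks a photon "hot" when any m consecutive photons
around it (m = 10) exceed F times the local background rate,
separately in the donor-excitation stream and the acceptor-excitation
acceptor stream; bursts are the maximal intervals hot in **both**
streams, which removes donor-only species and acceptor-blink
artifacts. S-filtering retains the closed interval [0.25, 0.75].

# RASP: kinetics from recurrences

At high dilution a vesicle that just produced a burst is far more
likely to re-enter the confocal volume than a new vesicle is to
arrive. The same-molecule probability is estimated from the burst-time
autocorrelation, P_same(τ) = 1 − 1/g(τ). Burst pairs are selected by
an initial-E window ΔE1 and a recurrence interval T, and the
histograms of second-burst E for a ladder of intervals are decomposed
into two Gaussian peaks whose means and widths are shared globally
across all intervals, only the per-interval weight being free. The
weight trajectory pA(τ) is fitted by

  pA(τ) = P_same(τ) · pA_recur(τ) + (1 − P_same(τ)) · pA_new,

with pA_recur = (1 + ε(1/ρA − 1))⁻¹ and
ρA(τ) = ρA_eq + (ρA(0) − ρA_eq) e^(−λτ). λ is the sum of the opening
and closing rate constants; the closing time constant follows as
1/(λ(1 − ρA_eq)) when ΔE1 sits on the open-state peak. ε is the
open/closed brightness ratio, default 1 (at which the mapping is the
identity). Uncertainties are percentile bootstrap over bursts (peak
shapes and P_same held fixed).

Four numerical choices deserve emphasis; each was validated against a
burst-level oracle (trains of bursts with exact Markov-chain state
assignments and known same-molecule identity):

* **Constrained peak model.** The two shared Gaussians have equal
  widths and a separation bounded away from zero. Burst-averaged E of
  a fast two-state system is not literally a two-Gaussian mixture;
  with fully free shapes the least-squares solution degenerates into a
  narrow peak plus a broad envelope and the weights stop tracking
  state occupancy. With equal widths the per-interval weight is close
  to a first-moment estimator, which is linear in the state occupancy
  and leaves the decay rate λ unbiased even under burst-length
  blurring.
* **pA_new from the pooled histogram.** A burst from a *newly*
  arriving molecule is a sample from the equilibrium population, so
  pA_new is computed by decomposing the pooled all-burst histogram
  with the same shared peaks rather than fitted as a free constant
  (`pNewFree = TRUE` restores the free fit). This removes a
  near-degeneracy between pA_new and ρA_eq in the tail of the decay.
* **Joint fit of both selections.** When a second initial-E window on
  the other state's peak is supplied (`e1RangeB`, the default in the
  study configuration), the two recurrence trajectories — decaying
  down from the open-selected side and rising from the
  closed-selected side — are fitted jointly with shared λ and ρA_eq,
  each with its own initial condition. Pinning the relaxation from
  both directions roughly halves the scatter of λ and eliminates the
  occasional collapse onto slow solutions seen in one-sided fits.
  P_same per interval is computed directly on the interval (observed
  pairs in excess of the Poisson expectation for new arrivals, the
  same correlative logic as the P_same curve), avoiding interpolation
  error across wide logarithmic intervals.
* **Unclamped effective amplitudes.** The fitted ρA(0) values are
  effective amplitudes — selection purity multiplied by the
  burst-averaging attenuation — and are deliberately not clamped to
  the probability range: with a true initial purity near 1, a hard
  bound lets noise push the amplitude only downward, which the
  optimiser compensates by lowering λ (an ~8% bias on the oracle);
  with the bound released the oracle recovery is unbiased.

## Study conditions for the kinetic recovery

The kinetic-recovery configuration (`confocalStudyConfig()`) departs
from the module defaults in two places, for reasons set by the physics
of recurrence kinetics rather than by any dataset:

* Burst durations must be short compared with the relaxation time
  1/λ = 5 ms, matching the few-millisecond bursts of the experiment.
  With bright vesicles the F = 6 threshold sits deep in the Gaussian
  tails and bursts stretch to 6–8 ms, averaging the two states away;
  the study configuration therefore uses a tighter detection core
  (0.15/0.6 µm waists, 500 kHz peak) and F = 30, giving ~1.2 ms
  median bursts of ~100 photons.
* Recurrence intervals start at 5 ms, several times the median burst
  duration. Pairs at lags shorter than a burst force the initial burst
  to be shorter than the lag, which makes the selection purity vary
  with τ and biases λ downward; starting above the burst-duration
  scale removes this.

Thirty minutes of acquisition with nine particles yields roughly
17,000 filtered bursts and over 10,000 recurrence pairs — enough for
the closing time constant to land within roughly 10–20% of truth with
a bootstrap CI that covers it. The recurrence probability is lower here
than in the maximally dilute regime; the >0.9 recurrence probability
out to 80 ms is exercised separately at one particle per box, where
the measured P_same stays at 0.94–0.96.

# BVA

Bursts are cut into consecutive sub-bursts of n donor-excitation
photons (default n = 5, which suits millisecond bursts; a time-window
partitioner, e.g. 0.1 ms, covers the sub-millisecond probe). Under a
static model the sub-burst acceptor counts are Binomial(n, PR), so the
sub-burst proximity ratio has SD sqrt(E_p(1−E_p)/n). Per
proximity-ratio bin, a Monte Carlo reference distribution of the
pooled SD is simulated from binomial draws matched to the bin's window
structure, and the bin is called dynamic when the pooled observed SD
exceeds the (1−α) quantile (α = 0.001 by default). BVA always operates
on the proximity ratio: detected counts partition binomially with
success probability PR, while corrected E would bias the variance.
The SD uses the population denominator to match the Monte Carlo
reference. At n = 5 the shot-noise SD (~0.2) dominates any dynamic
broadening (~0.1), so detection power comes from pooling many windows
per bin, not from single bursts.

# TIRF traces, segmentation, dwells

The TIRF generator alternates exponential closed dwells (default mean
3 s — not a reported value; chosen in the range that example traces
of this system show) with gamma open dwells (shape 4) whose mean is
offset + L/rate; per-residue time 25.25 ms (39.6 aa/s) and offsets
4.7 s (no SecB) / 0.5 s (with SecB) are the values measured for this
system, used as ground truth. Each frame row is one full 200 ms alternation
cycle (100 ms cyan + 100 ms orange), so I_DD, I_DA and I_AA are
co-registered per row. Noise is EMCCD-like: scaled-Poisson shot noise
plus Gaussian read noise; the SNR knob is the ratio of the open/closed
intensity separation to the read-noise SD (SNR 3 = transitions three
noise SDs tall; default 6). Each dye bleaches at an exponential time
(combined mean 60 s) with the corresponding single-step signature.

QC mirrors the experimental filters: median pre-bleach S inside
[0.25, 0.75]; donor/acceptor anticorrelation (Pearson r < −0.3 on
frames within ±2 frames of candidate transitions; traces without
candidate transitions pass vacuously and are caught by the
responsiveness filter); single-step bleaching per channel by a
cumulative-sum change-point detector with a 4× frame-noise minimum
step (two downward steps = double labelling, excluded); blinking
excursions excluded. Segmentation is a two-state Gaussian-emission
hidden Markov model fitted per trace by Baum–Welch (means initialised
at 0.2/0.4) and decoded by Viterbi; a trace is *responsive* only if
the two-state model also beats a single Gaussian by BIC, which
protects against noise-driven phantom transitions on single-state
traces. Dwells tile the pre-bleach trace; the terminal dwell is
censored. Traces begin at the start of a closed dwell (reactions are
observed from mixing), so leading dwells are complete.

# Photobleaching correction

Bleaching right-censors dwell observation: a dwell is recorded
complete only if it ends before the dye bleaches, so complete dwells
are distributed as the true density tilted by the bleaching survival
function. With exponential bleaching the tilt is exact and
memoryless. `deconvolveDwells()` recovers the uncensored gamma law by
maximum likelihood under the tilted density f(t)·S(t)/Z (the
normaliser Z is computed numerically so empirical bleaching laws work
too). Likelihood was chosen over least squares on the binned
histogram because, at the ~300 dwells per substrate length of the
shipped design, it cuts the standard deviation of the corrected mean by
about a third — the dominant error term of the length regression at
the longest substrate — while both estimators are unbiased; the
binned least-squares distance is kept as the goodness-of-fit
diagnostic, alongside a second-difference-regularised nonparametric
reconstruction (weight 10⁻³ by default). `correctDwellTimes()` maps
every observed
dwell through the tilted CDF onto the corrected gamma quantiles —
yielding per-dwell corrected times so that the final regression can
use *all* dwells as points, as the experimental regression does. The OLS of
corrected open dwells on substrate length gives slope (s per residue),
intercept (the length-independent phase) and rate = 1/slope with
propagated SE. Closed dwells, generated length-independent, serve as
the negative control (slope consistent with zero).

# Dye accessible volumes

`computeAV()` rejection-samples dye centres within the linker sphere
around an attachment atom, discarding positions that clash with the
structure (centre distance < atom radius + dye radius) or that cannot
be reached by a clash-free straight linker segment checked at
half-width spacing. Defaults (20 Å linker, 4.5 Å width, 3.5 Å dye
radius) are typical maleimide-linker values; the exact AV parameters used for
this system are not publicly reported. Inter-dye distances from two clouds
convert to E through the Förster relation with R₀ = 6 nm for the
Alexa 488/594 pair. On the deposited open/closed structures this
reproduces the predicted low-E open and E ≈ 0.4 closed distributions;
the shipped tests exercise the geometry on small synthetic structures
so the suite needs no downloads.

# What the synthetic data do and do not show

The generators emulate: recurrence statistics of dilute diffusing
vesicles, ALEX slot structure, shot-noise-limited E and S, two-state
CTMC plug dynamics, gamma/exponential dwell structure, exponential
photobleaching with single-step signatures, and EMCCD-like frame
noise. They do not model triplet blinking or other photophysics,
vesicle size polydispersity, spectral crosstalk beyond the correction
factors, image registration, or baseline drift. Passing recovery
tests therefore demonstrates the correctness and calibration of the
analysis chain under the stated stochastic model — not robustness to
every artifact of real recordings, for which the QC filters and
correction factors are the first line of defence.

# Known limitations

The recurrence kinetic fit carries a mild low bias in λ (of order
10–30% depending on acquisition length) inherited from burst-averaged
E blurring: each burst reports a time-average of the state over its
duration, which attenuates the short-lag contrast in a way the
two-peak decomposition can only partly absorb. The equilibrium
occupancy ρA_eq is recovered accurately (e.g. 0.31 measured against a
ground truth of 0.30 at opening/closing rates of 60/140 s⁻¹), and the
bootstrap CI on the derived time constants covers the truth at the
shipped acquisition length; users probing faster kinetics should
shorten bursts further (smaller detection core, higher threshold
multiplier) or lengthen acquisition. Dwell times from TIRF
segmentation carry a small positive bias (~1 frame) because closed
excursions shorter than about half a frame are undetectable and merge
the flanking open dwells; at the 0.2 s frames used here and ≥3 s mean
dwells this amounts to a few percent and is visible in the validation
against simulator ground truth.

# Problem sizes

The shipped acceptance analyses use: ~420 simulated TIRF traces per
condition, sized to give ≈300 complete open dwells per substrate
length at 100/233/354/683 aa; 1800 s of confocal acquisition with nine
particles (~17,000 bursts) and 100 bootstrap resamples; 50 replicates
per ATP level over 0.025–2 mM; 20 replicates per temperature over
288–310 K. These sizes keep every recovered quantity's uncertainty
well inside its decision band while completing in minutes on a single
core.
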