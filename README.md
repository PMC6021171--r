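# plugdyn

Single-molecule FRET analysis of SecYEG plug dynamics: from raw
two-colour ALEX photon streams and TIRF intensity traces to two-state
kinetic rate constants, within-burst dynamics verdicts, and the
intrinsic protein-translocation rate.

The SecYEG translocon conducts pre-proteins across the bacterial inner
membrane, driven by the SecA ATPase. A dye pair spanning the channel's
plug helix reports its position by FRET — E ≈ 0.4 with the channel
closed, E ≈ 0.2 open. `plugdyn` implements the full analysis chain for
the two measurement modes of this system:

* **µsALEX confocal bursts** (freely diffusing proteoliposomes):
  time-dependent background estimation, sliding-window dual-channel
  burst search (DCBS), burst-wise proximity ratio / corrected E /
  stoichiometry with population-level corrections
  `E = (n_DA − l·n_DD − d·n_AA) / (γ·n_DD + n_DA − l·n_DD − d·n_AA)`,
  and S-filtering to [0.25, 0.75].
* **RASP** (recurrence analysis of single particles): same-molecule
  probability `P_same(τ) = 1 − 1/g(τ)` from the burst-time
  autocorrelation; recurrence transfer-efficiency histograms and 2D
  transition densities; global two-state fit
  `p_A(τ) = P_same·p_A^rec(τ) + (1 − P_same)·p_A^new` with
  `ρ_A(τ) = ρ_A^eq + (ρ_A(0) − ρ_A^eq)·e^{−λτ}`, giving λ (sum of
  opening and closing rate constants) and the opening/closing time
  constants, with bootstrap CIs.
* **BVA** (burst variance analysis): sub-burst partitioning, the
  shot-noise law `S_E = sqrt(E_p(1−E_p)/n)`, and Monte Carlo
  confidence thresholds (α = 0.001) for per-bin static/dynamic
  verdicts.
* **TIRF trace analysis**: per-frame E/S, stoichiometry /
  anticorrelation / single-step-bleach QC, two-state hidden-Markov
  segmentation, photobleaching-corrected dwell-time distributions
  (right-censoring deconvolution with gamma fits), and the OLS of
  dwell time against substrate length whose slope is the per-residue
  translocation time.
* **Dye accessible volumes**: Monte Carlo AV clouds on PDB/mmCIF
  structures and predicted FRET-efficiency distributions via
  `E = 1/(1 + (r/R₀)⁶)` (R₀ = 6 nm for Alexa 488/594).
* **Synthetic data** with full ground truth for every stage: Brownian
  two-state emitters in a confocal volume with ALEX timing (compiled
  core), and msALEX TIRF traces with gamma open dwells, exponential
  closed dwells and single-step photobleaching.

## Worked example

Simulate the substrate-length experiment (four proOmpA lengths, no
SecB) and recover the translocation rate through the full pipeline —
segmentation, photobleaching correction, OLS over all corrected
dwells:

```r
library(plugdyn)
rep <- runTirfPipeline(tirfStudyConfig(secB = FALSE, seed = 5))
rep$rate
#> RateFit: slope 0.02679 +/- 0.001 s/aa -> rate 37.3 +/- 1.4 aa/s
#>   intercept 4.49 +/- 0.4 s
```

The slope is the mean time to translocate one residue; its
reciprocal, ~37 aa/s for this draw of ~1400 dwells, is the intrinsic
translocation rate (ground truth 1000/25.25 ≈ 39.6 aa/s, within 1.5
standard errors), and the ~4.5 s intercept is the length-independent
slow phase seen without SecB (truth 4.7 s).

The millisecond side, on simulated confocal photon streams:

```r
rep <- runConfocalPipeline(confocalStudyConfig(kOpen = 100,
                                               kClose = 100,
                                               seed = 101))
rep$kinetics
#> Two-state kinetic fit (recurrence analysis)
#>   lambda = 245.5 1/s  [39.1, 333.3]
#>   rhoA_eq = 0.551, rhoA(0) = 1.135, pA_new = 0.531
#>   tau out of A = 9.08 ms  [6.83, 54.06]
#>   tau into A  = 7.39 ms
```

With the initial-E window on the open-state peak, "tau out of A" is
the plug-closing time constant (ground truth 10 ms at
k_open = k_close = 100 s⁻¹), bracketed by its bootstrap CI. The
fitted ρA(0) is an effective amplitude (selection purity times
burst-averaging attenuation) and may exceed 1; see the methods
vignette.

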