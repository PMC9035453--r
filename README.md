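# rmoct

Reflection-matrix optical coherence tomography (RM-OCT) simulation and
wavefront shaping in R.

## The problem

Multiple light scattering limits how deep a beam can be focused inside
turbid media such as biological tissue. Past roughly one transport mean
free path, ballistic photons are gone and a focused input degenerates into
speckle. A reflection-matrix approach attacks this without guide stars:
measure the medium's reflection matrix **R** (the complex linear map from
every incident mode to the backscattered camera field), decompose it by
SVD — the time-reversal decomposition `R = U S Vᵀ` — and use the strong
singular channels, which correspond to light that actually reached the
target plane, to (i) map the internal energy distribution and (ii) derive
matched incident wavefronts that push multiply scattered photons through
"open channels" to the target.

`rmoct` implements this computational pipeline end to end on a synthetic
scattering phantom:

- **Phantom simulator** — layered Gaussian random phase screens with
  split-step angular-spectrum propagation, calibrated so the stack's
  ballistic transmission after optical depth *d* (in scattering mean free
  paths, SMFP) is exactly `exp(-d)`; reciprocal double-pass reflection
  from a configurable target reflectivity map.
- **Scanning acquisition** — 31 × 31 (or 17 × 17 in the desk profile)
  linear phase ramps on an idealized SLM, ideal-lens focusing, camera
  conjugate to the target plane, idealized heterodyne lock-in
  demodulation, additive detection-noise floor.
- **Calibrated time-reversal model** — `tr_fit()` computes the SVD,
  selects the Tikhonov regularization parameter λ by the deviation
  criterion `η(λ) = ‖ê − e‖/‖e‖` on re-measured probe inputs (filter
  factors `f = s²/(s² + λ²)`), and classifies the singular spectrum into
  photon classes against a Marchenko–Pastur bulk-edge threshold.
- **Model energy matrix** — `E_m = V F S Vᴴ`, the virtual camera inside
  the sample: its per-scan-point intensity maps score focus quality
  (peak shift, encircled energy vs the 80% Airy criterion, FWHM).
- **Wavefront shaping** — matched wavefronts `k = V F S⁺ Uᴴ e_target` by
  regularized inversion, phase-only SLM projection, camera→SLM pitch
  resampling, and shaped re-acquisition for before/after comparison of
  energy delivery and open-channel photon fractions.

## Worked example

```r
library(rmoct)

cfg <- experiment_config(seed = 1, depths = c(7.2, 14.4))
rep <- run_protocol(cfg)   # steps 1-3: acquire, invert, re-acquire
print(rep)
```

```
Three-step shaping protocol report
  profile 'desk', seed 1, target beads
  depth   7.2 SMFP: ss  65.16% | ms1   9.44% | ms2  25.39% | median E_m enhancement 1.22
  depth  14.4 SMFP: ss  29.40% | ms1  14.72% | ms2  55.88% | median E_m enhancement 1.93
```

Reading the report: at 7.2 SMFP, 65% of the reflected energy sits in
singular channels above the Marchenko–Pastur threshold before shaping
(single-scattering-like photons, `ss`); loading the matched wavefronts
moves another 9.4 percentage points of energy above the threshold
(`ms1` — multiply scattered photons redirected into open channels,
the open-channel gain), while 25% stays beyond control (`ms2`). The
enhancement column compares the model-energy-matrix maps at the probe
points before and after shaping. Deeper (14.4 SMFP) the controllable
share shrinks and the uncontrolled share grows, mirroring the depth
dependence of the photon taxonomy.

The fitted model itself is a first-class object:

```r
s1  <- rep$step1$per_depth[[1]]
fit <- s1$fit
summary(fit)
#> Calibrated time-reversal decomposition (1024 x 289)
#>   leading singular values: 0.3192, 0.2382, 0.2182, 0.2142, 0.2073
#>   lambda = 0.1 (deviation eta = 0.977)
#>   filter keeps 54.3% of reflected energy
#>   threshold 0.05009: 65.16% of energy above
plot(fit)                        # singular spectrum + eta(lambda) curve
m <- energy_map_at_point(s1$em, c(9, 9))
focus_metrics(m, c(9, 9))        # peak shift, central fraction, FWHM
```

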