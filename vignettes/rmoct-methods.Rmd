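---
title: "Calibrated time-reversal of reflection matrices: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calibrated time-reversal of reflection matrices: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the science inside `rmoct`: the forward model of
the synthetic scattering phantom, the time-reversal decomposition of the
reflection matrix and its Tikhonov calibration, the model energy matrix,
the wavefront-shaping protocol, the numerical and design choices that
were genuinely open, and the limitations of the synthetic study. No
empirical claim is made here that the test suite or `scripts/acceptance.R`
does not itself compute.

## 1. Forward model: the synthetic phantom

The medium is a stack of `n_screens` thin random phase screens with
Gaussian statistics and Gaussian autocorrelation (correlation length 4
pixels), separated by free-space gaps spanning the physical thickness
`depth_smfp * smfp` micrometres. Propagation between screens uses the
exact (non-paraxial) angular-spectrum kernel on an FFT grid; with the
default pixel pitch above half a wavelength every discrete frequency is
propagating, so each free-space step is unitary and the screens are
unit-modulus — total power is conserved to numerical precision until the
absorbing boundary, whose losses are tracked separately.

**SMFP calibration.** For a Gaussian random phase of pointwise standard
deviation $\sigma$ the ensemble-mean transmitted amplitude of one screen
is $e^{-\sigma^2/2}$, so a stack of $n$ screens with
$\sigma = \sqrt{d/n}$ has ballistic power transmission exactly $e^{-d}$:
optical depth $d$ is measured in scattering mean free paths by
construction. `ballistic_transmission()` verifies this by Monte Carlo,
averaging the *complex* on-axis amplitude across realizations before
squaring so that the diffuse speckle contribution at the DC frequency
(random phase across realizations) averages out. The default screen
density is two per SMFP of depth — enough for diffusive behaviour at the
deepest settings (29 screens at 14.4 SMFP).

**Reflection geometry.** A double pass: propagate in, multiply by the
target-plane reflectivity map, propagate back through the *same* frozen
screens in reversed order. Because each free-space step and each screen
is a symmetric operator in the pixel basis and the return path reverses
the sequence, the monostatic pixel-basis reflection matrix is symmetric
— optical reciprocity, verified to $10^{-6}$ relative in the tests.

**Geometry margins.** The pixel grid extends 25% beyond the scanned
field of view, at the same pixel pitch, and the cosine absorbing frame
lives entirely in that margin; the camera records only the central
region covering the scanned FOV (camera ROI). Without the margin the
absorber clips edge scan beams (about 30% of shallow scan points then
fail the focus criterion); without the ROI crop, deep diffuse light that
a real imaging system would never collect stays in the measurement and
the depth dependence of the signal disappears.

## 2. Acquisition model

Each scan point is addressed by a linear phase ramp on the SLM conjugate
(Fourier) plane; an ideal lens model (a centred FFT plus free-space
back-propagation over the phantom thickness) turns ramp $i$ into a unit
power converging beam whose free-space focus lands on scan position $i$
at the target depth. The camera is conjugated to the target plane
through free space — the optics undo the free-space part of the return
trip, not the scattering — so in the absence of scattering the
reflection matrix is diagonal. Columns are the row-major reshaped
complex camera fields, one per input, in row-major scan order;
`reshape_to_2d()`/`fill_rm_column()` are exact inverses.

Heterodyne detection is modelled at its idealized endpoint:
`beat_frames()` generates intensity frames of the beat between the
sample field and a frequency-shifted reference, and
`lockin_demodulate()` recovers amplitude and phase exactly by quadrature
projection over whole beat periods (a 40 kHz beat sampled at no fewer
than 4 frames per period; fewer raises an aliasing error). Camera-pitch
phase maps are upsampled to the 5x finer SLM pitch by interpolating the
unit-modulus phasor, never the raw phase, which makes the operation safe
across the $\pm\pi$ branch cut.

**Detection noise.** The acquisition adds complex Gaussian noise with a
*fixed per-pixel floor* (`noise_sd`), so the effective SNR falls with
depth as the returned signal weakens — the regime of deep heterodyne
measurements. The floor is the one genuinely free parameter of the
study; see section 6.

## 3. The calibrated time-reversal model

`tr_fit()` computes the thin SVD of the reflection matrix,
$R = U\,S\,V^{T}$ with singular values $s_1 \ge s_2 \ge \dots$ (the
stored $V$ carries the conjugated right singular vectors so the
reconstruction reads exactly $U S V^T$; per-column phases are fixed by
making the largest entry of each $V$ column real positive, for
reproducibility). The regularized inverse is the Tikhonov-filtered
pseudoinverse

$$\hat e_{\mathrm{in}} = \bar V\,F\,S^{+}\,U^{H}\, e_{\mathrm{out}},
\qquad f_i = \frac{s_i^2}{s_i^2 + \lambda^2},$$

which equals the ridge closed form
$(R^H R + \lambda^2 I)^{-1} R^H e_{\mathrm{out}}$ — the package asserts
this equivalence to $10^{-10}$ against a dense solve. Filter factors
damp the weak channels that amplify noise; $\lambda = 0$ recovers the
bare pseudoinverse, $\lambda \to \infty$ the (scaled) time-reversal
conjugation $R^H$.

**Choosing $\lambda$ — the deviation criterion.** For each candidate on
a log-spaced grid from $10^{-8}$ to $10^{8}$, the filtered inverse is
applied to independently re-measured outputs of a random 10% of the scan
inputs and scored by the normalized deviation
$\eta(\lambda) = \overline{\lVert \hat e - e \rVert / \lVert e \rVert}$
against the known coefficients; the minimizing $\lambda$ is selected and
the whole curve retained. Noiseless probes drive $\eta$ to the floor at
the smallest grid value; rising noise pushes the minimum up — both
behaviours are property-tested. A literal hold-out of scan inputs from
the matrix build does not work here: the scan basis is orthonormal, so a
held-out input has (near-)zero coefficients in the retained basis and
the criterion degenerates; fresh-noise re-measurement preserves the
cross-validation intent.

**Photon classification.** The reflected energy $\sum s_i^2$ is
partitioned at a singular-value threshold. The default threshold is
random-matrix based: the noise scale is fitted from the *median* squared
singular value under the Marchenko–Pastur null (robust to a few strong
channels) and the threshold is the fitted bulk edge
$\sigma(1 + \sqrt{c})$. Above-threshold energy before shaping is
attributed to single-scattering-like photons; the additional
above-threshold energy after shaping to multiply scattered photons
redirected into open channels (the open-channel gain, which may be
negative and is reported signed); the remainder never reaches the
target plane. An eigenstate-count mode is available alongside the
energy-weighted default, which we prefer because energy is quadratic in
the field amplitude.

## 4. Model energy matrix and focus metrics

The model energy matrix is the Hermitian filtered time-reversal form
$E_m = V\,F S\,V^{H}$: its column for scan point $i$, squared moduli
reshaped to the scan grid, maps how the energy launched toward $i$
distributes over the target plane — a camera inside the sample. The
conjugate transpose matters: with a plain transpose the product is not
invariant under the SVD's per-column phase ambiguity and even an
identity reflection matrix would fail to give delta maps; the Hermitian
form is convention-free and reproduces the identity limit exactly
(tested against a brute-force triple product).

`focus_metrics()` scores a map by: peak position (lexicographic
tie-break), peak shift from the addressed point, encircled energy in a
central disk (default radius 1.5 scan pixels, the first Airy null of
the default scan geometry), and FWHM by linear contour interpolation at
half peak. A map is diffraction-limited when the peak sits on the
addressed point and at least 80% of the energy is in the central disk —
for an ideal sampled Airy pattern the encircled energy inside the first
dark ring is $1 - J_0^2(v_1) - J_1^2(v_1) \approx 0.838$, comfortably
above the criterion. `enhancement()` is the ratio of in-disk energy
between two maps sharing one acquisition normalization.

## 5. Wavefront shaping protocol

Step 1 measures the scanning reflection matrix per depth and fits the
calibrated decomposition. Step 2 inverts it for every target point:
$k(i) = \bar V F S^{+} U^{H} \delta_i$ with $\delta_i$ a camera-pixel
impulse at the target, normalized to unit power, reshaped to 2D and
projected to phase-only (the SLM constraint; an amplitude-retaining mode
exists, and the phase-only delivery is property-tested never to beat
it). A patch-shaped desired output is deliberately not the default: the
pixel impulse is the minimal reading, and widening it does not change
the information content of the objective. Step 3 re-acquires against
the *same frozen phantom* — a staleness guard refuses mismatched
realizations — and reports photon-class fractions, the open-channel
gain, energy-map enhancement at the probe points, and the simulator's
ground-truth internal delivery.

Phase-only modulation costs the classical factor $\pi/4$ of the focal
intensity relative to full conjugation; the package reproduces this on
random unitary matrices at $N = 256$ within 10%.

## 6. Frozen study conditions

All synthetic studies run at fixed, pre-registered conditions:

| quantity | value | why |
|---|---|---|
| field of view | 70 µm scanned, grid margin +25% | printed experimental FOV; absorber outside the scan |
| wavelength | 0.8 µm | ultrafast-laser band of the heterodyne setup |
| scan grid | 31×31 (full) / 17×17 (desk) | full matches the experiment; desk keeps multi-seed studies minutes-scale |
| pixel grid | 80 px (full) / 40 px (desk) | camera ROI then covers the scan FOV with 64²/32² outputs |
| SMFP | 52.8 µm | thickness table: 14.4 SMFP = 760 µm |
| depths | 2.4, 4.8, 7.2, 9.6, 14.4 SMFP | the five imaging depths of the study design |
| screens | 2 per SMFP, correlation 4 px | diffusive at depth without a Maxwell solver |
| probe points | (6,6), (6,26), (16,16), (26,6), (26,26); scaled to (4,4)… on the desk scan | the examined positions, corners + centre |
| detection floor | `noise_sd = 1e-3` | see below |
| targets | mirror plane (unshaped mapping) / 5 beads at the probes (shaping) | bulk-reflective surrogate vs discrete examined scatterers |

The detection floor was calibrated once against the *observable regime*
of deep reflection measurements — a small, depth-decreasing
strong-channel fraction and unshaped map intensities orders of magnitude
below the shallow reference — and then frozen. At this floor the
deviation criterion selects a non-trivial $\lambda$ at every depth and
the open-channel gain at 7.2 SMFP is robustly positive (median about
+10 percentage points over ten seeds). A floor twice as high drowns the
shaped signal and reverses the sign of that gain; a floor much lower
makes every channel "strong" and the classification vacuous.

Most tests use the desk profile; the acceptance script reports, among
others, the ballistic calibration at 9.6 SMFP, the 7.2-SMFP photon
fractions and gain, and the 14.4-SMFP enhancement, each with the number
of seeds or realizations used.

## 7. Numerical choices

- Singular-value ties and map-peak ties break lexicographically;
  determinism end to end under a fixed seed is asserted byte-for-byte.
- The evanescent part of the angular spectrum is zeroed; default grids
  have none.
- Zero-amplitude pixels get phase 0 under phase-only projection;
  all-zero fields, empty spectra, all-zero references and out-of-range
  points raise errors rather than propagate NaNs.
- Every stochastic stage (screens, noise, probe subsets) draws from a
  private, seeded RNG stream and restores the caller's stream.

## 8. What the synthetic study does and does not show

The simulator reproduces: exact SMFP semantics, reciprocity, speckle
statistics, the Marchenko–Pastur bulk of noisy acquisitions, the
depth-degradation of unshaped internal maps, and the redirection of
reflected energy into strong (open) channels by shaped wavefronts.

It deliberately omits: vectorial light, bulk absorption, dynamic media,
broadband pulses and coherence gating, real SLM/camera hardware, and
bulk backscatter from inside the medium (all detected light has
interacted with the target plane).

The sharpest consequence concerns *positional* energy delivery at
extreme depth. The inversion objective — a camera impulse at the target
pixel — carries positional information only through the ballistic
correlation of each reflector's camera speckle, which decays like
$e^{-d}$. A monochromatic phase-screen simulator retains essentially
none of it at 14.4 SMFP, so the shaped beam concentrates energy on the
reflector *set* but cannot choose reliably among reflectors: the
measured in-disk enhancement at the addressed point saturates near
unity-to-a-few (the suite reports a median of about 1.7 across ten
seeds) instead of the order of magnitude the physical experiment
achieves with ultrashort-pulse time gating and confocal heterodyne
detection. Ideal phase conjugation through the same phantoms delivers
two orders of magnitude, so the ceiling is informational, not physical:
passing or failing that one criterion speaks to the surrogate's
measurement model, not to the inversion machinery, which is verified
against its oracles throughout.
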