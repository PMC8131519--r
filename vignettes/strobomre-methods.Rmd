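---
title: "Time-resolved multifrequency MR elastography: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Time-resolved multifrequency MR elastography: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(stroboMRE)
```

## The measurement problem

Magnetic resonance elastography (MRE) drives low-amplitude shear vibrations
into tissue and encodes the resulting micrometre displacements into the
phase of MR images. Inverting the wave equation voxel-by-voxel yields maps
of the complex shear modulus $G^* = |G^*| e^{i\varphi}$: the magnitude
$|G^*|$ (stiffness, Pa) and the loss angle $\varphi \in [0, \pi/2]$ (the
viscous-to-elastic ratio). Conventional MRE needs minutes of gated
acquisition, which blinds it to fast physiology such as the intracranial
response to a Valsalva maneuver.

`stroboMRE` implements the time-resolved alternative: a single-shot
acquisition with repetition time $TR = 62$ ms continuously samples three
simultaneous vibrations (30.03, 30.91 and 31.8 Hz; a matched regimen at
40.77, 41.67 and 42.55 Hz is also supported), encoding the three Cartesian
motion components in an interleave of consecutive shots. One
viscoelasticity frame consumes $3 \times TR = 186$ ms, i.e. about 5.4
frames per second, and a 90-s scan of 1,458 images yields 486 stiffness and
loss-angle map pairs. Because there is no scanner in the loop, the package
pairs the reconstruction chain with a physically structured simulator, so
that every stage is testable against known ground truth.

## Stroboscopic sampling and aliased-frequency decomposition

Each motion component is revisited every $3 TR = 186$ ms, a per-component
sampling rate of $f_s = 5.376$ Hz. A vibration at $f$ Hz therefore appears
at its aliased position: with $r = f \bmod f_s$, the tone lands at $r$ when
$r \le f_s/2$ and at $f_s - r$ with reversed rotation sense otherwise. The
three default tones alias to 2.228, 1.348 and 0.458 Hz, all reversed — and
the 42-Hz regimen aliases to nearly the same positions (within 0.02 Hz),
which is what makes the two regimens directly comparable
(`aliasFrequency()`).

`decomposeSeries()` separates the tones per voxel and component: a global
FFT over the full series, multiplication of the positive half-spectrum by
$2\exp(-(f - f_a)^2 / 2\sigma^2)$ with $\sigma = 0.1$ Hz (zeroing the
negative half — a one-sided, inverse-Hilbert construction whose factor 2
preserves tone amplitude), inverse FFT to the analytic signal,
demodulation by $e^{-i 2\pi f_a t}$ at the true per-image timestamps, and
conjugation for reversed aliases. The Gaussian bandwidth sets the temporal
resolution: the envelope impulse response is Gaussian with
$\sigma_t = 1/(2\pi \cdot 0.1\,\mathrm{Hz}) \approx 1.6$ s, and a step
modulation is recovered with a 10–90% rise time of $2.563\,\sigma_t
\approx 4.1$ s. The global FFT implies periodic boundaries, so 5-s margins
are discarded at both ends (`trimMargins()`), leaving an 80-s observation
window.

Two conventions deserve a note. Frames are timestamped at the *middle*
image of each three-image interleave; this is what makes 432 of the 486
frames survive the 5-s margins. And each per-component series is processed
on its own 5.376-Hz time grid with no temporal interpolation — the three
images of a frame are treated as simultaneous.

## Preprocessing: complex smoothing and least-squares unwrapping

Raw complex images are smoothed with a normalized separable Gaussian kernel
of $\sigma = 0.65$ px (mirror boundary) *before* the phase is taken;
smoothing the complex signal avoids wrap artefacts and implicitly weights
phase by magnitude. The wrapped phase is then unwrapped per image by
gradient unwrapping: forward differences modulo $2\pi$, integrated by
solving the discrete Poisson equation with Neumann boundaries through the
DCT (realized as dense orthonormal DCT-II matrix products at this image
size). The solution is exact up to a constant wherever true gradients stay
below $\pi$/px, and is residue-free by construction.

The free constant matters more than it may appear: the encoded wave's
*spatial mean* oscillates at the vibration frequencies, and a per-frame
convention that discards it (for example forcing zero-mean output) removes
exactly the signal component the temporal decomposition needs. The
unwrapper therefore anchors its output congruent (mod $2\pi$) with its
input through a magnitude²-weighted circular mean of the wrapped residual.

## MDEV inversion

Each frame's nine wave images $u_{f,c}$ (three frequencies × three
components) are pooled by the amplitude-weighted algebraic Helmholtz
estimator (multifrequency dual elasto-visco inversion):

$$|G^*|(\mathbf{x}) = \rho\,
  \frac{\sum_{f,c} \omega_f^2\, |u_{f,c}(\mathbf{x})|}
       {\sum_{f,c} |\Delta u_{f,c}(\mathbf{x})|},
\qquad
\varphi(\mathbf{x}) = \arccos\!\left[
  - \frac{\sum_{f,c} \mathrm{Re}\!\left(\Delta u_{f,c} \overline{u_{f,c}}\right)}
         {\sum_{f,c} |\Delta u_{f,c}|\,|u_{f,c}|}\right],$$

with $\Delta$ the five-point discrete Laplacian (1-px border invalid), the
$\arccos$ argument clipped to $[-1, 1]$, $\rho = 1000$ kg/m³ (the standard
brain-MRE assumption), and zero-denominator pixels masked. The literature
also averages per-pair $\arccos$ values instead of weighting inside the
$\arccos$; the two coincide on homogeneous plane waves, and the
amplitude-weighted form above is the package's fixed choice, recorded in
the output provenance. Both maps are invariant to per-pair unit-modulus
rescaling of the fields — so the motion-encoding sensitivity cancels — and
scale linearly in $\rho$. On analytic plane waves at 21 px/wavelength the
only bias is the discrete dispersion $k_\mathrm{eff}^2 = (2 - 2\cos
kh)/h^2$, below 1% in $|G^*|$ and 0.01 rad in $\varphi$.

A single-frequency variant (`invertSeries(useFrequencies = i)`) exists
purely for the stability comparison: pooling nine images per frame instead
of three demonstrably lowers the baseline coefficient of variation of the
ROI-mean time courses.

## The synthetic acquisition

The simulator is a first-class component, not a fixture. Its phantom
(`brainPhantom()`) is a 2-D disc of homogeneous viscoelastic tissue
($|G^*| = 1370$ Pa, $\varphi = 0.800$ rad — group-mean baseline values)
with an MR magnitude template of about 50 arbitrary units in tissue,
about 5 in CSF-like holes (two elliptical ventricles plus a ring of small
sulcus-like holes), and 8 in the extracranial surround — a scale on which
the empirical analysis thresholds (magnitude 10, stiffness 950 Pa) are
meaningful.

Wavefields solve the heterogeneous Helmholtz equation $G^*(\mathbf{x})
\Delta u + \rho \omega^2 u = 0$ by sparse finite differences (the complex
system in its 2N real form, one sparse LU per modulus level serving all
right-hand sides). Displacement is prescribed on the skull-like disc rim
and inside the CSF holes — in vivo, shear enters the slice both through
the skull and via fluid spaces, and at $\varphi = 0.8$ the penetration
depth is only ~16 mm, so interior sources are what keeps mid-tissue
amplitudes above the noise floor, exactly as ventricles and sulci do in
real scans. The extracranial layer is solved as a passive medium (the
scalp vibrates with the skull) with zero displacement clamped at the FoV
border; a hard field edge at the rim would plant phase-wrap residues that
the global least-squares unwrapper smears across the whole image. Each
vibration frequency is driven through a rotated set of three damped
plane-wave source patterns, mirroring the experiment's separate driver
pairs per frequency; rotation also keeps the three tones' phase gradients
from aligning into wrap events. Faint scalp signal (magnitude 8 rather
than air) keeps the background phase residue-free for the same reason; an
air-like background remains available via `outsideMagnitude = 0`.

Motion encoding reduces to a single sensitivity $\xi$ (rad per metre of
displacement); the fractional-encoding efficiency integral is out of
scope. Image $k$ at time $t_k = k\,TR$ stores $M(\mathbf{x})
\exp\{i \xi \sum_f \mathrm{Re}[u_{f,c}(\mathbf{x}; t_k) e^{i 2\pi f
t_k}]\}$ plus i.i.d. complex Gaussian noise; the seed fully determines the
output.

### The maneuver profile

`maneuverProfile()` programs the slow physiology: a stiffness multiplier
$m(t)$ that is exactly 1 at baseline, rises into a calibrated early
overshoot (default +6.7% peaking 2.4 s after onset), drops briefly, ramps
to a +2.5% plateau while the maneuver is held, shows a second calibrated
overshoot after release (+7.4% at 5.5 s), and relaxes exponentially
($\tau = 8$ s); and a loss angle reduced by 2.1% while the maneuver is
held. Amplitudes and delays are group-mean in vivo values; the shape
parameters are simulator choices: Gaussian bumps of $\sigma = 3.2$ s
(early) and 3.5 s (late) are wide enough to survive the 1.6-s analytic
filter within the recovery tolerances yet sharp enough that their argmax
is identifiable against frame noise, the short post-peak drop (ramp
engaging 8 s after onset) reproduces the observed dip between the early
overshoot and the climb, and the early bump's leading tail (windowed to
zero 9 s before onset) emulates the preparatory breath-hold that precedes
the maneuver in the protocol. Bump centres and amplitudes are calibrated
numerically at construction so the *programmed* maxima hit the configured
values exactly — they are the ground truth that recovery tests compare
against.

Stiffness varies slowly against the wave period, so fields are re-solved
quasi-statically: only when the modulation moves to a new 0.1% bin
(log-magnitude and loss-angle bins, cached and shared across noise
realizations). The prescribed source patterns are re-evaluated in the
modulated medium — the transmitted wavelength follows the instantaneous
stiffness — because patterns frozen at the baseline wavenumber would leak
modulation-free values into adjacent tissue through the spatial smoothing
and attenuate the recovered response by roughly a fifth.

### Noise calibration

Two reported diagnostics pin the noise model. The magnitude SNR,
$20\log_{10}$(mean ROI magnitude / background noise SD) with the
background defined by the same magnitude-10 support threshold as the ROI,
sits near 29 dB at the default complex noise SD of 1.8. The
wave-displacement SNR (WSNR) divides the RMS decomposed-field amplitude by
a blind noise estimate — the median absolute finest-level diagonal wavelet
coefficient over 0.6745, Daubechies-4 by default (waves and noise separate
well in the wavelet domain; the second vanishing moment keeps ~20-px
shear wavelengths out of the finest diagonal subband, where a Haar filter
would leak them). At the default drive (encoding sensitivity 80,000 rad/m,
30 µm boundary displacement) the reported WSNR sits in the upper 30s dB —
the upper end of the in vivo range — a deliberate choice: at this noise
level the single-run peak *delays* remain identifiable to within half a
second, which is what the recovery suites require. Note the blind
estimator reads a few dB high on pipeline fields because the upstream
spatial smoothing correlates the noise that reaches the finest subband.

## Analysis conventions

The ROI mimics the published procedure: a drawn parenchymal region — here
the tissue mask eroded two pixels away from every driven source pixel,
`parenchymaPolygon()` — intersected with the empirical thresholds
(time-averaged magnitude > 10, time-averaged $|G^*|$ > 950 Pa) and the
inversion-valid set. Named phases (BSL 2.5–22.5 s, ESM 32.5–47.5 s, LRM
52.5–57.5 s, REC 70–80 s) exclude transition periods; difference series
subtract the baseline-phase mean; overshoots are the argmax of the
difference series within 10 s of onset and 15 s of release (about ±4 SD
around the reported delays); the coefficient of variation is $100 \cdot
\mathrm{SD}/\mathrm{mean}$ over the baseline frames.

## Problem sizes and what the tests show

The package's default configuration is the full protocol: 96×96 at
2×2×5 mm, 1,458 images. One complete default run (solve, sample,
preprocess, decompose, invert, analyze) takes on the order of two minutes
on a single core. The stochastic suites — ten-seed maneuver recovery and
the multifrequency-vs-single-frequency CV comparison — run at 64×64 with
3-mm in-plane voxels (matched 192-mm field of view, 14 px per wavelength)
and, for the CV comparison, a 22-s steady acquisition; these are the
package's standard desk-scale study sizes. The deterministic oracle
suites (plane-wave inversion, dispersion, alias arithmetic, unwrapping,
filter responses) are grid-size independent.

What passing tests do and do not show: the simulator emulates narrowband
triple-tone shear fields, quasi-static modulus modulation, fractional
encoding into wrapped phase and complex Gaussian noise — it does not
emulate spiral k-space readout, coil combination, physiological motion,
3-D wave propagation, poroelastic or anisotropic behaviour, or
heterogeneous baseline stiffness. Recovery within tolerance here
demonstrates that the *reconstruction chain* is faithful under the stated
physics; it is not evidence about any particular in vivo dataset.

## Numerical choices and degenerate inputs

* Reflection boundaries for smoothing; Neumann/DCT boundaries for the
  Poisson unwrap; no masking during unwrapping (masks act downstream).
* Solver guard: the grid must resolve at least 8 px per shear wavelength,
  otherwise the solve aborts with diagnostics; singular systems are
  reported with frequency and grid size.
* Apparent-frequency hygiene: tones on a spectral fold point are rejected;
  separations below $4\sigma$ warn, below $2\sigma$ abort naming the pair.
* Degenerate inputs: all-zero phase unwraps to zeros; empty field sets and
  mismatched shapes are errors; zero inversion denominators are masked,
  not propagated; a zero blind-noise estimate returns `Inf` WSNR with a
  warning; an empty ROI after thresholding is an error.
* Determinism: a single integer seed drives the only random element
  (image noise); identical configuration and seed reproduce every output
  bit-identically.

## Known limitations

The 2-D scalar model treats the three "Cartesian components" as three
independent boundary-source patterns of one scalar field. Absolute
pixel-level $|G^*|$ and $\varphi$ under noise carry the known MDEV biases
(noise in the Laplacian denominator biases stiffness down and pushes the
loss angle toward $\pi/2$); the analysis thresholds remove the worst
pixels, and all recovery criteria are relative to each run's own baseline,
which cancels static bias. Gradient unwrapping cannot recover true phase
gradients above $\pi$/px (aliased irreducibly, documented in
`wrappedGradient()`). The blind WSNR estimator assumes spatially white
noise and overstates the ratio when noise is pre-smoothed. Frequencies
whose third-order intermodulation products fall inside a passband can
interfere at high phase amplitudes; the default drive keeps single-tone
amplitudes near 1.2 rad where this effect is negligible at the default
grid.
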