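# stroboMRE

Time-resolved multifrequency MR elastography (MRE) in R: reconstruction of
stiffness and loss-angle map *series* from stroboscopically sampled
triple-frequency shear vibrations, plus a physically structured simulator so
the whole chain can be exercised and validated without a scanner.

## The problem and who this is for

MRE encodes externally driven shear waves into MR image phase and inverts
the wave equation into maps of the complex shear modulus
G\* = |G\*|·e^{iφ} — stiffness |G\*| (Pa) and loss angle φ (rad). Gated
acquisitions need minutes per map, hiding fast physiology such as the
intracranial response to a Valsalva maneuver. The time-resolved alternative
samples three simultaneous vibrations (30.03, 30.91, 31.8 Hz) continuously
with a 62-ms single-shot sequence, interleaving the three motion-encoding
components over consecutive shots: one viscoelasticity frame per
3 × TR = 186 ms, about 5.4 Hz, 486 map pairs from a 90-s scan of 1,458
images. This package is for image-analysis researchers who want to study,
extend, or stress-test that reconstruction.

The chain, stage by stage:

1. **Simulate** (`brainPhantom()`, `wavefieldSeries()`,
   `sampleAcquisition()`): a 2-D viscoelastic phantom (baseline
   1370 Pa / 0.800 rad) driven at its skull-like rim and CSF-like holes,
   solved with sparse finite differences for the heterogeneous Helmholtz
   equation G\*Δu + ρω²u = 0; a slow maneuver profile modulates |G\*| and φ
   (calibrated overshoots of +6.7% at 2.4 s after onset and +7.4% at 5.5 s
   after release, a −2.1% loss-angle dip); fractional motion encoding maps
   displacement to wrapped image phase; complex Gaussian noise is added at
   a magnitude SNR near 29 dB.
2. **Preprocess** (`preprocessSeries()`): Gaussian smoothing of the complex
   images (σ = 0.65 px), then per-image least-squares gradient unwrapping
   (Poisson/DCT).
3. **Decompose** (`aliasFrequency()`, `decomposeSeries()`): the
   stroboscopically undersampled tones appear at aliased positions
   (2.228, 1.348, 0.458 Hz at the 5.376-Hz per-component rate); one-sided
   Gaussian bandpass filters (σ = 0.1 Hz) and analytic-signal demodulation
   recover one complex wave image per frequency, component and frame —
   4,374 from 1,458 inputs.
4. **Invert** (`mdevInvert()`, `invertSeries()`): multifrequency dual
   elasto-visco (MDEV) inversion pools each frame's nine wave images,

   |G\*| = ρ · Σ ω² |u| / Σ |Δu|,  φ = arccos[ −Σ Re(Δu·ū) / Σ |Δu||u| ],

   with a five-point Laplacian — 486 consecutive |G\*| and φ maps.
5. **Analyze** (`trimMargins()`, `makeROI()`, `roiTimeCourse()`,
   `detectPeak()`, …): 5-s transient margins leave an 80-s window; the ROI
   combines a parenchymal polygon with empirical thresholds (magnitude
   > 10, |G\*| > 950 Pa); phase-interval statistics, overshoot peaks and
   delays, baseline coefficient of variation, SNR and blind wavelet-based
   wave-SNR diagnostics.

## Worked example

A complete default-protocol run (96 × 96, 1,458 images, ~2 min on one
core):

```r
library(stroboMRE)
res <- runPipeline(pipelineConfig(), seed = 1)
res$peaks
#>     event event_time_s  peak_pa      pct delay_s
#> 1   onset           30 75.49...  6.64...   2.232
#> 2 release           50 73.9...   6.50...   5.301
str(res$summary[c("early_pct", "late_pct", "phi_dip_pct",
                  "cv_gstar_pct", "snr_db")])
#> $ early_pct   : num 6.64
#> $ late_pct    : num 6.5
#> $ phi_dip_pct : num -2.02
#> $ cv_gstar_pct: num 0.112
#> $ snr_db      : num 29
```

Reading: the simulator programmed a +6.7% stiffness overshoot 2.4 s after
maneuver onset and +7.4% at 5.5 s after release with a −2.1% loss-angle
dip; the reconstructed ROI time course recovers 6.6% at 2.23 s, 6.5% at
5.30 s and −2.0% — inside the expected attenuation of the 1.6-s analytic
bandpass — with a baseline coefficient of variation of ~0.1% and the
calibrated 29-dB magnitude SNR. `runPipeline(..., outDir = "out/")` writes
the elastogram NIfTI volumes, CSV time courses and the resolved YAML
configuration. A thin command-line front end is installed at
`inst/cli/strobomre` (`simulate`, `run`, `analyze` subcommands).

External data enter through `readRawSeries()` (paired magnitude/phase
NIfTI volumes with a YAML sidecar giving TR, interleave order, vibration
frequencies and voxel size), after which the same stages apply.

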