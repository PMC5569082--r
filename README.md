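# ptoctr — photothermal OCT signal analysis

Phase-sensitive photothermal optical coherence tomography (PT-OCT) images
absorbers — melanin in the retinal pigment epithelium, gold nanorods
accumulating in neovascular lesions — by modulating a heating laser and
reading the induced periodic change in optical path length (OPL) out of
the OCT phase. The phase of light returning from depth `z` responds as

    ΔΦ = 4 π n ΔOPL(z) / λ0

so the amplitude of the phase oscillation at the modulation frequency,
converted to nanometers of OPL, is a per-pixel measure of local
absorption. `ptoctr` is a complete, tested implementation of that
measurement for researchers developing or validating PT-OCT processing:

* **Forward simulator** (`make_phantom()`, `simulate_mscan()`,
  `simulate_volume()`): raw spectral M-scan interferograms with known
  photothermal ground truth — pigmented/albino retina phantoms, a
  nanorod-labelled lesion model, power series, breathing motion and
  corrupted A-scans, all seeded.
* **Spectral-domain reconstruction** (`resample_to_wavenumber()`,
  `estimate_dispersion()`, `chirpz_to_depth()`): cubic k-resampling,
  sharpness-optimized dispersion compensation, and a Bluestein chirp-Z
  depth transform with arbitrary zoomed windows (FFT-exact on the full
  range).
* **Lock-in signal extraction** (`temporal_derivative()`,
  `lockin_amplitude()`, `to_opl()`, `process_mscan()`): wrapped phase
  differencing, exact single-tone amplitude at the drive frequency,
  noise-floor subtraction, nm conversion, SNR masking.
* **Motion correction** (`estimate_shift()`, `correct_bscan()`,
  `interpolate_missing()`): per-A-scan axial registration to a reference
  volume, identical offsets applied to the PT-OCT image, linear
  interpolation of corrupted columns.
* **Quantification** (`axial_profile()`, `find_peak_fwhm()`,
  `background_stats()`, `lesion_mean()`, `enface_projection()`): layer
  peak and FWHM, peak-to-background, lesion-ROI means with the
  40,000-pixel inclusion filter, green-channel overlays and TIFF export.
* **Statistics** (`mann_whitney_exact()`, `linear_fit_origin()`,
  `compare_groups()`, `power_series_analysis()`): exact two-tailed
  Mann-Whitney U by full enumeration, and through-origin regression with
  a heteroscedasticity-robust 95% CI.

## Worked example

Simulate a mirror carrying a 5 nm OPL oscillation (pure-sine drive,
noiseless) and recover it through the full pipeline:

```r
library(ptoctr)

cfg <- acq_config(n_spectrometer_pixels = 512)   # 700 repeats, 500 Hz drive
phantom <- make_phantom("single_reflector", reflector_depth = 200,
                        kappa = 5, thermal_mode = "pure_sine", seed = 1)
raw <- simulate_mscan(phantom, cfg, power = 1)   # 5 nm at 1 mW
profile <- process_mscan(raw, depth_window_um = c(150, 250), n_out = 128)
profile
#> ptoct_profile: 128 depth px (150.0-249.2 um); peak 5 nm at 191.4 um

i <- which.max(profile$oct_db)                   # the mirror's depth pixel
c(depth_um = profile$depth_grid[i], ptoct_nm = profile$opl_amplitude[i])
#>  depth_um  ptoct_nm
#>  200.0000    4.9993
```

The mirror sits at 200 µm and reads 4.999 nm — the 5 nm drive within
0.02% (every unmasked pixel within the mirror's point-spread function
reads the same amplitude, so the profile is flat-topped around the peak).
The study-level statistics have the same closed-form anchors:

```r
mann_whitney_exact(1:6, 7:12)        # complete separation of 6 vs 6 eyes
#> Mann-Whitney U = 0 (n = 6, 6), two-tailed p = 0.002165 [exact]

tab <- simulate_power_cohort(n_eyes = 6, powers = c(0.4, 1, 2, 4, 8, 10),
                             slope = 1.56, cv = 0.2, seed = 1)
power_series_analysis(tab)$fit
#> through-origin fit: slope 1.54 [95% CI 1.357, 1.723], R^2 0.938 (n = 36)
```

The exact p of 0.0022 is the familiar floor for 6-vs-6 designs; the
through-origin fit recovers the generating 1.56 nm/mW responsivity
inside its confidence interval under 20% between-eye noise.

## The analysis workflow

The numbered scripts under `analysis/` run the study end to end on
simulated data and write tables under `results/`:

| script | what it does |
|---|---|
| `01_simulate_phantoms.R` | builds the retina and lesion phantoms, writes raw containers |
| `02_reconstruct_ptoct.R` | reconstructs OCT/PT-OCT volumes, exports overlays, writes axial profiles |
| `03_motion_correction.R` | breathing simulation, registration, dropout interpolation, trace recovery |
| `04_power_series.R` | six-eye power series: retina-band means, FWHM, background, ratio |
| `05_group_statistics.R` | pigmented vs albino, nanorod vs control, detection limit, responsivity fit |

Run them in order from the repository root
(`Rscript analysis/01_simulate_phantoms.R`, ...).

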