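---
title: "Photothermal OCT signal analysis: models, parameters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Photothermal OCT signal analysis: models, parameters and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The measurement

Photothermal optical coherence tomography (PT-OCT) detects absorbers inside
a scattering sample by driving them with an amplitude-modulated laser and
reading the resulting periodic change in optical path length (OPL) out of
the phase of a phase-sensitive OCT acquisition. Heating by the modulated
beam changes the local refractive index and thermoelastically expands the
tissue; both change the optical path above and around the absorber. For a
field reflected from depth $z$, the OCT phase responds as

$$\Delta\Phi = \frac{4 \pi n\, \Delta \mathrm{OPL}(z)}{\lambda_0},$$

with $n$ the sample's group index and $\lambda_0$ the source center
wavelength. Repeated A-scans at one lateral position (an M-scan) sample
$\Delta\Phi(t)$ over many heating/cooling cycles; the amplitude of the
phase oscillation at the known drive frequency, converted to nanometers of
OPL, is the PT-OCT signal. `ptoctr` implements this end to end: a forward
simulator of raw spectrometer data with known ground truth, spectral-domain
reconstruction, lock-in extraction, motion correction, layer/lesion
quantification and the study-level statistics.

The default acquisition (`acq_config()`) is a 2048-pixel spectrometer at a
10 kHz line rate, an 860 nm / 40 nm-bandwidth source, a 500 Hz square-wave
drive at 50% duty cycle, and 700 repeated A-scans per position — so each
M-scan spans 35 modulation periods, and the theoretical axial resolution
`axial_resolution(860, 40)` is 8.16 µm in air (≈ 5.9 µm at $n = 1.38$).

# Forward model

`simulate_mscan()` renders the interferogram of one lateral position as

$$S(k_i, t) = G(k_i)\Big[D + \sum_j a_j \cos\big(2 k_i n z_j + \phi_j(t) +
\theta(k_i)\big)\Big] + \varepsilon,$$

with $G$ a Gaussian source envelope, $D$ a reference-arm offset chosen so
counts stay non-negative, $\theta(k) = a_2 (k-k_0)^2 + a_3 (k-k_0)^3$ an
optional dispersion phase, and wavelengths sampled linearly in pixel index
over $\lambda_0 \pm 1.5\,\Delta\lambda$ (a typical spectrometer
calibration; the paper-level analysis never depends on its details). The
photothermal phase of reflector $j$ is
$\phi_j(t) = (4\pi n/\lambda_0)\, A_j\, w(t) + b(t)$, where $w(t)$ is the
unit-amplitude centered modulation waveform, $b(t)$ common-mode phase
noise, and $A_j$ the ground-truth OPL oscillation amplitude at that
reflector.

**Amplitude convention.** $A_j$ is the oscillation amplitude — half the
peak-to-peak OPL excursion. The drive $w(t)$ is therefore centered and
normalized: in `pure_sine` mode $w = \sin 2\pi f_0 t$, so the Fourier
component at $f_0$ is exactly $A_j$ and every recovery experiment has a
closed form; in `square_lowpass` mode $w$ is the periodic steady-state
first-order response (time constant $\tau$, default 0.2 ms — a plausible
tissue thermal scale) to the ±1 square drive, whose fundamental is
$(4/\pi) A_j$ attenuated by the low-pass. The reported signal is always
the $f_0$ Fourier amplitude, which is what a spectral peak measures.

**Thermal coupling with depth.** Because the OPL change accumulates along
the beam and heat spreads from the absorbing layer, the signal is not
strictly local. `true_amplitude()` offers three operators, all exactly
linear in power and concentration: `local` ($A = \kappa P C$, for
closed-form validation), `cumulative` (sum of all absorber at and above
$z$ — pure path-length accumulation, which turns a thin absorbing layer
into a non-decaying step below it), and `diffusive` (the default for
tissue phantoms): an exponential kernel of confinement length 15 µm,
giving a peaked layer signal plus background above and below the layer —
the behavior actually seen in retinal profiles, where background grows
with laser power. The responsivity default $\kappa = 1.56$ nm/(mW·unit)
makes a unit local absorber yield 1.56 nm/mW, the convenient scale for
power-series recovery experiments.

**Phantoms.** `make_phantom()` builds five geometries: a single mirror
(validation), pigmented and albino retinas (ILM, weak inner-retina
scatterers, an RPE melanin band — Gaussian, 15 µm FWHM, total content 2
units — and a weak broad choroidal band; the albino shares the scattering
structure with zero absorber), and a dome-shaped subretinal lesion above
the RPE with (`lcnv_lesion`) or without (`lcnv_control`) a uniform
nanorod load. The RPE content (2 units) was set so the 1 mW peak sits
about 3–4× above the ~0.5 nm sensitivity floor, the regime the study's
profiles show; the nanorod load (0.8 units per column) adds ≈ 3 nm over
the melanin background at 8 mW. `make_eye_cohort()` adds between-eye
biology: RPE band width CV 15%, melanin content log-normal CV 25%, and
2 µm reflector jitter per column. Noise defaults for tissue phantoms are
$\sigma_\phi = 0.05$ rad common-mode phase noise per sample plus a small
additive spectral noise; at 700 repeats this calibrates to a noise floor
of ≈ 0.5 nm at a bright reflector. The breathing surrogate is a 1–2 Hz
sinusoid plus linear drift (default amplitude 5 px), applied per M-scan
position; dropout columns are decorrelated speckle.

What the generator does *not* emulate: developed speckle statistics,
bioheat-equation temperature fields, eye optics, lateral motion, and
scanner duty-cycle effects. Tests passing on these phantoms therefore
validate the *processing* — reconstruction fidelity, lock-in calibration,
statistical machinery — not the biological magnitudes themselves.

# Reconstruction

`resample_to_wavenumber()` interpolates each spectrum onto a uniform
$k = 2\pi/\lambda$ grid with cubic splines (the accepted accuracy/cost
compromise; endpoints are preserved and an already-uniform grid passes
through unchanged). `chirpz_to_depth()` evaluates
$X(z) = \sum_j S(k_j)\, e^{-2 i n k_j z}$ on an arbitrary uniform depth
window via Bluestein's chirp-Z algorithm; with the window equal to the
full unambiguous range and as many outputs as inputs it reproduces the
FFT bin-for-bin (tested to 1e-9 relative), and zoomed windows give
sub-pixel depth sampling at no extra acquisition cost. The default window
is the upper half-range, excluding the complex-conjugate mirror image.

Dispersion compensation multiplies the spectra by $e^{-i\theta(k)}$;
`estimate_dispersion()` finds $(a_2, a_3)$ by maximizing the
reconstructed peak intensity (coarse grid over $a_2$, Nelder–Mead
refinement of both, a restart to avoid simplex collapse — deterministic
given the data). Orders above $a_3$ are not identifiable at desk scale
and are not modelled. Flat or structureless input returns the identity
model with a warning.

**Background handling.** Three background estimates coexist, each with
its role:

* `subtract_background()` — the temporal mean per spectrometer pixel;
  removes the source term and fixed-pattern noise, the classical choice
  for *intensity* imaging of repeated acquisitions.
* `remove_source_envelope()` — a degree-20 polynomial fit to the
  temporal-mean spectrum; removes the smooth source/DC component while
  leaving *static fringes* intact.
* `analytic_signal()` plus a Tukey(0.25) spectral taper.

`process_mscan()` uses the last two for the phase pathway. The reason is
numerical rather than cosmetic: at the low bulk-phase-drift of simulated
(and well-stabilized) data the temporal mean contains the fringe itself,
and subtracting it replaces the field $r\,e^{i\phi(t)}$ at a reflector
with $r(e^{i\phi(t)} - \langle e^{i\phi}\rangle)$, whose argument no
longer tracks $\phi(t)$ — the phase is destroyed exactly when the data
are cleanest. (In vivo, bulk drift ≫ 2π averages the mean fringe to zero,
which is why the classical subtraction is harmless there.) The envelope
fit, taper and analytic-signal step instead suppress the three sources of
*static interference* at imaging depths — the zero-delay term, window-
truncation tails, and the conjugate image — without touching per-sample
fringe phase. The residual static-to-fringe interference after these
steps is below 1%, which is what bounds the end-to-end amplitude error.

**Pixel validity.** The phase of a pixel is meaningful only where one
coherent component dominates. `process_mscan()` masks pixels that (i)
have zero magnitude at any time sample, (ii) sit less than 5 dB above
the empty-depth floor (10th percentile of the window), (iii) lie more
than 50 dB below the brightest pixel (phase-sensitive OCT cannot use
phase that deep in the dynamic range), or (iv) show deep
destructive-interference dips over time (minimum magnitude below half
the median), where the argument flips sign regardless of drive. Masked
pixels report zero signal, matching the display convention of overlays
that show signal only in tissue.

# Lock-in and noise floor

The per-pixel phase series is differenced with re-wrapping to
$(-\pi, \pi]$ (`temporal_derivative()`): constant offsets vanish, linear
bulk drift becomes a constant, and the statistic is immune to $2\pi$
wrapping while the true per-sample increment stays below $\pi$.
`lockin_amplitude()` then reads the drive component. Because the first
difference of 700 samples leaves 699 — for which 500 Hz at 10 kHz is not
an integer bin — the default estimator solves the exact two-term
Dirichlet window model of a single tone at the known $f_0$ (amplitude and
phase from one complex DFT value), which is machine-precision for a pure
tone of any non-integer cycle count; the plain nearest-bin magnitude read
is available as `method = "bin"` and agrees to ~1%. The result is divided
by the first-difference transfer function $2\sin(\pi f_0/f_s)$ so the
reported quantity is the amplitude of the phase oscillation itself, and
converted to nm via `to_opl()`.

The noise floor is the median magnitude of the differenced series'
single-sided spectrum, excluding DC, $f_0$ and $2 f_0$ (± 2 bins each),
converted identically, and subtracted from the signal with clipping at
zero. Note this floor is *conservative*: differencing shapes white phase
noise as $2|\sin(\pi f/f_s)|$, so the across-band median overstates the
noise actually present at $f_0$ by roughly fourfold, and recovered
amplitudes are biased down by a fraction of the floor. The package keeps
this convention because (a) it is the natural reading of
"amplitude away from the peak", (b) it makes the zero-drive null exact —
at $P = 0$ the floor-subtracted signal is identically zero — and (c) all
downstream comparisons use it consistently. The bias is what produces
two study-level behaviors reproduced by the tests without any
nonlinearity in the ground truth: the mean background rises
super-linearly with laser power (pixels emerge from under the floor) and
the peak-to-background ratio falls monotonically.

# Motion correction

Breathing moves the retina axially between A-scans. `estimate_shift()`
registers each OCT A-scan to a motion-free reference volume by
FFT-based, zero-padded (non-circular) normalized cross-correlation on
mean-centered columns, with optional subpixel refinement on an upsampled
local DFT grid. `correct_bscan()` applies the same vertical offset to the
simultaneous PT-OCT A-scan — integer offsets by default, so the nm image
is translated but never resampled; fractional shifts are supported and
off by default. Shifts are non-circular: vacated pixels are zero-filled
and excluded from statistics. Columns with normalized correlation below
0.5 (a decorrelated A-scan cannot reach this against structured tissue)
are declared corrupted and rebuilt by 1-D lateral linear interpolation
between nearest valid neighbors (`interpolate_missing()`), with
nearest-valid extension at image edges. On simulated breathing of up to
10 px the integer-mode recovery error is below 1 px; correcting an
already-corrected B-scan finds offsets of 0.

# Quantification

`axial_profile()` averages a corrected PT-OCT B-scan over A-scans per
depth, excluding flagged pixels. `find_peak_fwhm()` takes the global
maximum (plateau center on ties), walks out to the half-maximum
crossings with linear sub-pixel interpolation, and truncates with a
warning if a side never falls below half. `background_stats()` averages
the profile outside the half-maximum band dilated by a 1-pixel margin
and forms the peak-to-background ratio (undefined, not infinite, when
the background is zero). `lesion_mean()` averages PT-OCT voxels inside a
frozen ROI mask and applies the study's inclusion filter — total mask
area (pixels summed across B-scans) strictly greater than 40,000 px by
default; masks are consumed from files (`read_roi_mask()`) or rebuilt
from simulator geometry (`lesion_mask_from_truth()`), never drawn
interactively, preserving the separation between structural selection
and PT-OCT statistics. `enface_projection()` gives mean-over-depth
projections with the PT-OCT signal in the green channel, the display
convention of the overlays (range `[0, 99th percentile]`, recorded in
the export metadata).

The per-eye summary used for group comparisons is the mean over the
retina band (between the ILM and choroid-end proxies of the phantom) for
the pigmented/albino contrast, and the lesion-ROI mean for the nanorod
study. Note the retina-band mean is a diluted version of the RPE peak
(the band is mostly non-absorbing), so its responsivity in nm/mW is
smaller than the κ of the band itself; the closed-form responsivity
recovery uses the single-reflector phantom where the two coincide.

# Statistics

`mann_whitney_exact()` computes U from midranks and, for groups of up to
8 without ties, the exact two-tailed p by full enumeration of all
$\binom{n_1+n_2}{n_1}$ labelings, doubling the smaller tail (capped at
1). Complete separation of 6 vs 6 gives $p = 2/924 \approx 0.0022$; the
enumeration agrees with `wilcox.test`'s exact p over all $n \le 6$ in a
property test. Ties or larger groups fall back to the normal
approximation with continuity and tie correction. No multiple-testing
correction is applied — comparisons are few and pre-registered — and the
output annotates their number.

`linear_fit_origin()` fits $y = \beta x$ with $\hat\beta = \sum x y /
\sum x^2$ and reports $R^2$ against the *centered* total sum of squares
(the uncentered convention is available behind a warning, as it flatters
through-origin fits). The 95% CI uses a heteroscedasticity-robust (HC3
sandwich) standard error with $t$ degrees of freedom equal to the number
of distinct non-zero x levels minus one: photothermal signals carry
noise proportional to the signal, so residual variance grows as $x^2$
and the classical homoscedastic CI covers the true slope in only ~70% of
20%-noise simulations, while this CI covers at 95–98% (a Monte-Carlo
property test pins coverage to [90%, 99%]). For a balanced design the
slope from all per-eye points equals the fit of per-power means, so
`power_series_analysis()` fits the pooled points and reports per-power
descriptives plus detection flags (powers whose group does not differ
from the 0 mW group at p < 0.05 — the detection-limit report).

# Problem sizes and numerical choices

The validation experiments run on reduced problem sizes chosen once: 512
spectrometer pixels (full 2048 only where the spectrometer itself is
under test), 700 repeats where the study's lock-in conditions matter
(modulation-period count, sensitivity, FWHM invariance), 140–200 repeats
for geometric and monotonicity checks, 4–8 A-scans per B-scan profile,
and reconstruction windows of 60–340 µm at ~1–2 µm per pixel. Key
tolerances: chirp-Z vs FFT 1e-9 relative; closed-form amplitude recovery
1%; dispersion coefficients 5%; motion recovery 1 px (integer mode);
FWHM invariance at exact-test p > 0.05 over 6 replicate eyes.

# Known limitations

* The simulator's noise model (common-mode phase noise + additive
  spectral noise) omits decorrelation noise from flow and tissue
  motion within an M-scan; absolute sensitivities in vivo will differ.
* The conservative noise-floor convention biases small amplitudes
  downward; comparisons remain valid because it is applied uniformly,
  but absolute nm values near the floor are underestimates.
* The cumulative coupling mode is exposed but not the retina default;
  inverting cumulative phase to depth-resolved absorber concentration is
  out of scope.
* Registration is axial-only, matching the acquisition's artifact mode;
  lateral motion is neither simulated nor corrected.
* Exact Mann-Whitney p-values require tie-free data; clipped
  zero-signal groups (e.g. albino eyes) contain ties and fall back to
  the normal approximation.
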