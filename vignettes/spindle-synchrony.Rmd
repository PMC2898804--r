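---
title: "Simulated MEG/EEG sleep spindles and source-space synchrony: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulated MEG/EEG sleep spindles and source-space synchrony: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The question the package addresses

Sleep spindles — waxing-and-waning 10–15 Hz bursts lasting roughly half a
second to a second during stage-2 NREM sleep — look very different in
simultaneously recorded EEG and MEG: EEG spindles are highly correlated
across the scalp, while MEG spindle activity shifts rapidly in location,
frequency and phase. Source modeling of real recordings suggests the same
dissociation persists in source space: cortical activity estimated from EEG
is diffusely synchronous, while activity estimated from MEG at the same
moments is focal and asynchronous. A proposed physiological reading is that
the two measurements are differentially sensitive to two thalamocortical
projection systems: the *matrix* system (widespread, layer-I-terminating
projections that could synchronize large cortical territories) and the
*core* system (focal, layer-IV-terminating projections driving individual
cortical patches).

`spindlesync` turns that interpretation into a testable forward simulation.
It generates ground-truth source activity from an explicit matrix + core
model on a folded cortical surrogate, renders realistic 60-channel EEG and
306-channel MEG, runs the same noise-normalized minimum-norm (dSPM) source
estimation a real study would use, and measures source-space synchrony. The
simulation succeeds if — and only if — both generator systems are present
does the analysis reproduce the dissociation: high within-EEG source
correlation, low within-MEG correlation, and an intermediate combined
solution.

## Geometry: head, sensors, cortex surrogate

The head is three concentric spheres (brain/skull/scalp, default radii
80/85/92 mm, conductivities 0.33/0.0042/0.33 S/m). EEG uses 60 electrodes
quasi-uniform over the upper scalp (Fibonacci lattice); MEG uses 102 sites
25 mm outside the scalp, each with a radial magnetometer and two orthogonal
planar gradiometers (two-point finite difference, 16.8 mm baseline), i.e.
306 channels.

The cortical surrogate is a radially perturbed sphere,
`r(θ, φ) = r0 (1 + a sin(wθ) cos(wφ))`, with outward analytic normals and
dipoles quasi-uniform on the surface (default 642 per hemisphere at desk
scale; the construction scales to the ~3200/hemisphere of a decimated
cortical reconstruction, and the spacing test uses that scale). Folding is
the essential feature: with `a = 0.2`, `w = 12` neighbouring normals can
differ by >120°, so synchronously active neighbours partially cancel at the
sensors, as on real sulcal banks. The mean radius default of 60 mm keeps the
deepest and most superficial dipoles (48–72 mm) inside the brain shell with
enough clearance for the EEG series to converge.

## Forward models

EEG potentials come from the three-shell concentric-sphere solution as a
truncated Legendre series (default order 60). Instead of transcribing a
published coefficient formula, the per-harmonic radial coefficient is
obtained by solving the 5×5 linear system expressing continuity of potential
and normal current at the two internal boundaries and zero current at the
scalp; with equal conductivities this reproduces the classical homogeneous
factor (2n+1)/n to machine precision, and the tests compare against an
independently derived closed form. The series tail is monitored; if the last
term exceeds 1e−6 of the partial sum the forward errors out rather than
returning an unconverged value. Potentials are average-referenced.

MEG uses the Sarvas closed form for a spherically symmetric conductor.
Magnetometers read the field along the coil normal; planar gradiometers read
the two-point finite difference of that component along their derivative
direction. Radial dipoles are magnetically silent in this geometry, a
property the tests assert at 1e−12 relative.

Gain matrices hold three columns per source (unit dipoles along the global
axes); the dSPM power is invariant to rotations of that basis, so no
surface-local frame is needed.

## The generator

Each subject contributes 12 spindle events (7 subjects by default, ~85
events, the emulated study design) laid out sequentially with 5.5–6.5 s
gaps; 100 quiet 600 ms epochs per subject are tiled into the gaps. Durations
are drawn from a Beta(0.273, 0.460) rescaled to 483–1123 ms — the unique
Beta matching the target mean (721 ms) and SD (235 ms) inside the target
range, which a truncated normal cannot do. All oscillation frequencies are
uniform on 10–15 Hz.

*Matrix system*: every source oscillates with one frequency and phase under
a Hann envelope spanning the event, scaled by a smooth strictly positive
spatial map (exponential of a low-order harmonic field, log-SD 0.5) — a
single diffusely synchronous generator.

*Core system*: 8–14 patches per spindle, each a geodesic disc (radius 8 mm)
of sources sharing one waveform with its own frequency, phase and a short
active burst (15–35% of the spindle, placed uniformly at random), emulating
focal generators that shift in location and time within one spindle. Patch
centers are drawn among the quarter of sources whose normals are most
tangential to the skull: core generators live on sulcal walls, which is
precisely why MEG sees them and EEG barely does. The 8 mm radius keeps a
patch on a single fold bank (half the default fold wavelength), so its
dipoles share orientation.

*Background*: 250 uniformly placed noise dipoles with 1/f-shaped stationary
activity (power slope −1 over 1–40 Hz), standing in for non-spindle brain
activity. Sensor noise is white per channel kind.

### Amplitude calibration

Source amplitudes are free parameters of the model; the defaults were fixed
once, at design time, against two kinds of constraints:

1. *Physiology at the sensors.* EEG spindles of a few tens of µV, planar
   gradiometer spindles of order 10²  fT/cm, magnetometer noise ~40 fT and
   gradiometer noise ~16 fT/cm (plausible for a 40 Hz bandwidth), EEG
   channel noise 9 µV interpreted as total non-neural noise (amplifier,
   electrode, residual artifact).
2. *The structural regime the model asserts.* In whitened sensor units the
   defaults put the matrix system far above the EEG floor (so EEG-derived
   sources are synchronous), modestly above the MEG floor (so a matrix-only
   simulation is synchronous in MEG too), and the core system several times
   above the matrix at MEG while at or below the noise floor in EEG (so MEG
   is dominated by the asynchronous patches and a core-only simulation
   leaves EEG noise-like).

Defaults: matrix 20 nA·m per source, core 50 nA·m per source (~4 sources
per patch at desk scale, ~200 nA·m per patch), background 0.9 nA·m RMS per
dipole. These are ordinary magnitudes for sleep-spindle source models.

## Inverse: noise-normalized minimum norm (dSPM)

The noise covariance is diagonal. In the baseline mode it follows the
evoked-response convention: the ~100 quiet epochs (band-passed 10–15 Hz) are
averaged sample-wise and the per-channel variance of the average is used —
this scales the covariance by ~1/K, and the same covariance whitens the data
and normalizes the estimate, so the F statistic stays internally calibrated.
The empty-room mode uses the per-channel variance of a long sensor-only
recording (MEG only; EEG has no empty-room analog and is refused).

Operators are computed in whitened coordinates: rows of gain and data are
divided by the channel noise SD, after which
`W = R G' (G R G' + λ² I)⁻¹` with `R = I` (no depth weighting) and
`λ² = trace(G R G') / (n_channels · snr²)`. For source *i* and sample *t*

&nbsp;&nbsp;`F(i,t) = ‖(W x(t))_i‖² / (3 · dspm_norm[i])`,

where `dspm_norm[i]` is the mean noise variance of the source's three
components (so the denominator is the summed component noise variance and
`E[F] = 1` under pure noise); the stored value is √F. Each source also
carries a Satterthwaite effective dof computed from the eigenvalues of its
3×3 noise-covariance block: with equal component variances it is 3
(the classical three-component F-test), and it correctly drops toward 2 for
MEG on a sphere, where the radial component is silent. `f_significance`
refers the time-averaged F to an F distribution with that numerator dof
(times the number of samples averaged, assuming independent samples) — with
a fixed numerator dof of 3 the null p-values would be visibly non-uniform.

The *combined* solution whitens each modality by its own covariance, then by
default rescales each block to equal total gain power before stacking. The
relative amplitude scaling a joint EEG+MEG fit should assume is not
identifiable without an external calibration source, so the default gives
both spatial patterns equal a priori weight; the noise normalization
accounts for the rescaling, keeping F calibrated. `modality_weighting =
"none"` restores the plain stack.

The pipeline inverts MEG from the planar gradiometers alone (the channels
the gradiometer-based source analyses use); magnetometers are simulated and
recorded but excluded from the default inverse. The pipeline's
regularization default is `snr = 4`: with the averaged-epoch covariance
convention, single-trial spindle data sit far above the nominal noise level,
and at `snr = 1` the solution is smoothed so heavily that every source time
course is dominated by the same global point-spread leak — all synchrony
contrasts collapse, for asynchronous and synchronous generators alike. The
lower-level `compute_inverse_operator` keeps the conventional `snr = 1`
default for unaveraged data.

### Magnitude versus signed time courses

`apply_dspm` can return the nonnegative √F (default) or the signed,
noise-normalized component along the source's surface normal. The
correlation statistics operate on the magnitudes: the stacked activity plots
and the within-modality correlation statistics describe nonnegative
"activity", and on a folded surface the signed normal component flips sign
between opposing fold banks, which empirically drives all within-modality
correlations to ~0 regardless of generator synchrony. The signed variant is
retained because it carries oscillatory phase — it is the right input for
demonstrating that zero-lag correlation is phase-sensitive while coherence
is not, which the test suite does with constructed quadrature pairs.

## Synchrony statistics

*Mean pairwise correlation* over all unordered distinct source pairs
(self-pairs excluded; ~21 million pairs at 6500 sources) uses the identity
`mean_r = (‖Σ_j z_j‖²/T − n) / (n(n−1))` on rows standardized to zero mean
and unit population variance — O(nT) instead of O(n²T) — with the
brute-force double loop retained and tested to 1e−12 agreement.
Zero-variance rows are excluded with a message.

*Between-modality correlation* correlates the same dipole's EEG- and
MEG-derived time courses and averages over sources.

*Welch coherence* is the band-averaged magnitude-squared coherence from
Hann-windowed 50%-overlapping segment-averaged periodograms (default
256-sample segments; per-spindle the pipeline uses the largest power of two
that yields at least two segments). A single segment would make coherence
identically 1 and is rejected.

*MVDR (Capon) coherence* builds, per frequency, the distortionless
data-adaptive filters `h = R⁻¹e / (eᴴR⁻¹e)` from L×L tap covariances
(default L = 64; per-spindle L ≈ T/20, at least 8) with diagonal loading
1e−6 of the mean tap variance, and takes
`|h_xᴴ R_xy h_y|² / (S_x S_y)` averaged over a band grid — bounded by 1 via
Cauchy–Schwarz, and exactly 1 for identical inputs. Several published MVDR
cross-spectral constructions exist; this one was chosen because its
coherence is provably in [0, 1] and it reproduces MVDR's defining behavior,
validated in the tests: the adaptive filters null nearby off-frequency
tones that a few-segment fixed-window Welch estimate blurs into spuriously
high coherence.

*Maximum maps*: per-source maximum √F over a spindle, averaged over spindles
and normalized to a maximum of exactly 1; map similarity is the Pearson
correlation over sources.

Aggregation is two-level throughout: statistics are averaged over spindles
within subject, then means ± SDs are taken across subjects.

## Numerical choices and degenerate inputs

* EEG shell coefficients: 5×5 boundary solves per harmonic with radii
  normalized to the scalp radius and column equilibration; stable to order
  ≳150.
* Filters: 4th-order Butterworth, forward–backward (`signal::filtfilt`), so
  passband phase is zero; records shorter than ~3 filter lengths are
  rejected rather than silently contaminated by edge effects.
* All-zero gain column triplets abort operator construction with the source
  indices named; non-positive channel variances abort covariance estimation.
* Dipoles at the sphere center are valid for MEG (field identically zero);
  dipoles on or outside the inner shell are rejected.
* The per-source coherence statistics subsample sources (default 128,
  fixed-seed) to keep the per-spindle cost linear; correlations always use
  all sources.
* Every random draw flows from explicit seeds through an RNG-state-local
  helper, so identical seeds give bit-identical recordings and reports and
  the global RNG stream is never disturbed.

## Desk-scale problem sizes

The default experiment runs 642 sources/hemisphere, 60 + 306 channels,
500 Hz, ~90 s of recording per subject; one subject with 12 spindles
(simulation, filtering, three inverse operators, all statistics) completes
in well under a minute on one core, and the full 7-subject design in a few
minutes. The structural contrasts are asserted at this scale; the geometry
and statistics code paths are the same ones a full-scale run would use.

## What the generator does and does not emulate

Emulated: channel counts and kinds, sampling and filtering, the target
spindle count/duration distribution and quiet-epoch design, folded-cortex
cancellation, MEG radial insensitivity, diffuse-synchronous versus
focal-shifting generator systems, baseline versus empty-room noise
normalization.

Not emulated: realistic cortical geometry and BEM/FEM conduction (spheres
instead), CSF and white-matter anisotropy, K-complexes, vertex waves, slow
oscillations, ECG and other artifacts, expert spindle marking (ground-truth
annotations are used), inter-subject anatomical variability (subjects differ
only by seed), and any claim about absolute amplitudes of real recordings
beyond order-of-magnitude plausibility. Passing tests therefore show that
the analysis pipeline recovers the designed source-space structure through
realistic sensor physics — not that real spindles must be generated this
way.

## Known limitations

The spherical forward model understates the EEG/MEG selectivity a real
folded cortex provides, so the simulated MEG within-modality correlation
(~0.4–0.6 under defaults) sits above values observed in analyses of real
recordings (~0.1–0.15) even though the EEG≫MEG ordering and both single-system controls
are robust. The signed-component statistics are sensitive to the surrogate's
orientation field in a way real anatomically constrained estimates may not
be. The MVDR cross-spectral construction is one of several in the
literature; its absolute values should be compared across conditions, not
across implementations.
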