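---
title: "Methods: frequency-domain multi-distance NIRS analysis of TMS-evoked hemodynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: frequency-domain multi-distance NIRS analysis of TMS-evoked hemodynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fdmdnirs)
```

## The measurement and the model

Frequency-domain multi-distance (FDMD) NIRS shines intensity-modulated
near-infrared light (here 690 and 830 nm, modulated at 110 MHz) into the
scalp and records, at several source–detector separations $r$ (2, 2.5, 3,
3.5 cm), three quantities per sample: the mean intensity $I_{DC}$, the
modulation amplitude $I_{AC}$, and the phase of the detected
photon-density wave. In a homogeneous medium these vary linearly with
distance after the geometric correction:

$$\ln(r^2 I_{AC}) = r\,S_{AC} + C_{AC}, \qquad
  \ln(r^2 I_{DC}) = r\,S_{DC} + C_{DC}, \qquad
  \text{phase} = r\,S_{phase} + C_{phase}.$$

The package fits these three regressions by ordinary least squares at
every sample and wavelength (`fit_multidistance`). The AC and phase slopes
determine the tissue's absorption and reduced scattering coefficients in
closed form (`invert_optical`): writing $a = |S_{AC}|$,

$$\mu_a = \frac{\omega}{2v}\left(\frac{a}{S_{phase}} -
  \frac{S_{phase}}{a}\right), \qquad
  \mu_s' = \frac{a^2 - S_{phase}^2}{3\mu_a} - \mu_a,$$

with $\omega$ the angular modulation frequency and $v$ the speed of light
in tissue ($c/1.4$; the refractive index is configurable). The AC/phase
pair is used because both are insensitive to ambient light; the DC fit is
reported as a diagnostic only. Absorption at the two wavelengths is then
solved for oxy- and deoxyhemoglobin through the extinction-coefficient
matrix (`solve_chromophores`), and total hemoglobin — the blood-volume
proxy — is their exact per-sample sum.

The slope pair maps to $(\mu_a, \mu_s')$ through the complex attenuation
wavenumber of the photon-density wave,

$$k_r^2 - k_i^2 = 3\mu_a(\mu_a + \mu_s'), \qquad
  2 k_r k_i = 3 (\mu_a + \mu_s')\,\omega / v,$$

with $S_{AC} = -k_r$ and $S_{phase} = k_i$. The synthetic forward model
(`forward_fd`) emits signals with exactly this structure and a $1/r^2$
geometric factor, so the three regressions are exactly linear for
noise-free input and the inversion is exactly testable: the test suite
verifies round-trip recovery of 1000 random $(\mu_a, \mu_s')$ pairs to
better than $10^{-8}$ relative error. We use the full
$3\mu_a(\mu_a+\mu_s')$ form rather than the $\mu_s' \gg \mu_a$
approximation because the closed-form inversion above is exact under it.
Real semi-infinite boundary corrections (extrapolated-boundary Green's
functions, multi-layer models) are deliberately out of scope: the fitted
model *is* the linear-in-$r$ form above, and keeping the forward model
self-consistent with it makes every stage verifiable.

### Extinction coefficients

The packaged defaults are the widely used compiled adult hemoglobin
spectra values, in $1/(\mathrm{mM\,cm})$, base-10 convention
($\mu_a = \ln 10 \sum_c \varepsilon_c C_c$):

| wavelength | HbO$_2$ | HHb |
|---|---|---|
| 690 nm | 0.276 | 2.052 |
| 830 nm | 0.974 | 0.693 |

The 2×2 matrix is well conditioned (condition number ≈ 3); a singular or
near-singular table is rejected at construction. Water and lipid
absorption are ignored — only the two hemoglobin species are computed.
The table is fully overridable via `extinction_table()` or the YAML
config.

## Quality control

Per-sample validity requires the coefficient of determination of **both**
the AC-amplitude fit and the phase fit to reach 0.97 at **both**
wavelengths (`qc_mask`). The per-wavelength gating and the
both-wavelengths rule are a design choice: the chromophore solve needs
both wavelengths, so a sample that fails at either cannot yield
concentrations. $R^2$ of a zero-variance response is defined as 0 (the
textbook formula is 0/0), which forces flat-line channels to fail the
gate rather than pass it vacuously. The DC $R^2$ is reported but not
gated. OLS slope p-values are carried in the diagnostics output but are
not used as a gate.

At the event level, a stimulus is discarded when more than one third of
its 6 s post-stimulus window is invalid, or when the window overlaps a
motion-artifact interval (`apply_event_qc`). In synthetic mode the
artifact intervals are the simulator's ground-truth labels; for real
recordings a threshold detector would replace them, and the interface
accepts any interval list.

## Filtering, segmentation, normalization

Chromophore series are band-passed at 0.02–0.7 Hz with a 1001-tap Hanning
windowed-sinc kernel (`design_bandpass`): the low edge removes slow
baseline drift, the high edge removes cardiac pulsation (≈1.1 Hz). The
kernel is made exactly DC-free by subtracting its mean (a symmetric
constant offset) and its gain is normalized to 1 at the geometric mean of
the cutoffs ($\approx 0.118$ Hz); the tests verify gain ≤ 0.01 at DC,
within 5% of unity at 0.1 Hz, and ≤ 0.1 at 1.1 Hz. Application is
zero-phase: the symmetric kernel is applied by centered convolution with
reflection padding (`apply_filter`). Filtering order follows the
processing chain: the $R^2$ gate acts on raw optical fits, the bandpass on
the chromophore series, segmentation afterwards.

Three consequences are handled explicitly:

* **Invalid samples** are linearly interpolated before convolution so
  they cannot poison their neighborhood, and the validity mask is then
  dilated by half the kernel width (500 samples ≈ 48 s) around every
  invalid run — everything the interpolated values could have touched is
  marked invalid. This makes isolated artifacts expensive, which is the
  conservative choice.
* **Edges**: the first and last half-kernel of samples sit on reflected
  padding; segments touching them are dropped with reason
  `"filter edge"`. Sessions therefore include a 60 s lead-in before the
  first stimulus block and a 60 s tail.
* **The additivity identity**: total hemoglobin is re-derived as the sum
  of the filtered HbO$_2$ and HHb, so tHb = HbO$_2$ + HHb holds exactly
  after filtering.

Segmentation (`segment_events`) cuts the $(0, 6]$ s window after each
stimulus (62 samples at 10.4 Hz). The baseline is the sample nearest the
stimulus onset — the literal reading of treating the stimulation time as
baseline — with an optional `"pre-window"` mode (mean over the 0.5 s
before onset) because single-sample baselines are noise-sensitive; the
choice is a documented trade-off, onset-sample is the default. The
normalized signal is percent change relative to the absolute
concentration at baseline:
$100\,(x(t) - x(0)) / |x_{abs}(0)|$. Because the bandpass removes the
absolute level, the filter stores the mean concentration it removed and
segmentation adds it back into the denominator — a +14% evoked excursion
reads as 14, matching the percent scale on which group effects are
reported. The exact normalization formula is not uniquely determined by
the processing description it implements; percent-of-baseline is adopted
and flagged as an interpretation. Baselines below $10^{-3}$ µM trigger a
division guard (`"unstable baseline"`).

## The synthetic session generator

The generator exists so that every downstream stage can be verified
without any real recording. It emulates:

* **The stimulation protocol**: 3 pre-TBS and 5 post-TBS blocks of 25
  real + 25 sham single pulses in seeded random order, inter-stimulus
  intervals uniform on 6–8 s, inter-block intervals uniform on 6–10 s.
  (The source protocol description states the inter-block interval
  inconsistently in one figure caption — 4–10 s vs 6–10 s; the 6–10 s
  value from the protocol text is used.) The theta-burst trains are
  3 pulses at 50 Hz per burst, bursts at 5 Hz: cTBS as one uninterrupted
  40 s train, iTBS as 2 s trains every 10 s across 190 s — 600 pulses
  each. The delay between the last pre-TBS stimulus and the train, and
  between the train and the first post block, is not specified by the
  protocol; 60 s is used (configurable) so that filter transients die out
  before the post blocks.
* **Evoked responses**: a causal gamma-density kernel, peak-normalized to
  1, with mode 3.5 s and SD 1.5 s — a standard hemodynamic-response
  shape peaking inside the 6 s analysis window. Amplitudes are percent of
  baseline total hemoglobin, keyed by (modality, epoch, paradigm); the
  defaults give +14% for real stimuli after cTBS and 0 elsewhere,
  mirroring the condition structure under study (a real-vs-sham
  difference after cTBS, none after iTBS, none for sham). The evoked tHb
  change is split 80/20 between HbO$_2$ and HHb, reflecting the empirical
  pattern of blood-volume and HbO$_2$ increases with comparatively flat
  HHb.
* **Physiological noise**: cardiac (1.1 Hz, 1% of baseline tHb),
  respiratory (0.25 Hz, 0.5%) and Mayer-wave (0.1 Hz, 0.5%) sinusoids
  with session-random phases, plus a random-walk drift (0.01 µM/sample)
  on each chromophore. Amplitudes are typical of scalp NIRS at rest.
* **Instrument noise and artifacts**: 1% multiplicative noise on the
  intensities, 5 mrad phase noise, and Poisson motion artifacts
  (0.1/min, 1 s long) that scale each channel by an independent
  log-uniform factor up to 2× and offset its phase — breaking the
  linearity in $r$ so the $R^2$ gate catches them; their windows are also
  recorded as ground-truth labels.

All randomness flows from one session seed through a fixed
stream-splitting rule (`derive_seed`: an LCG-style mix of the seed and a
small stream id, kept below $2^{31}$), so identical (config, seed) pairs
reproduce identical schedules, tissue states and recordings bit for bit.

What the generator does **not** emulate — and hence what passing tests do
not show about real data: partial-volume and superficial-layer
contamination, heterogeneous (layered) optics, subject-specific vascular
reactivity, coupling between stimulus and motion (real subjects move in
response to TMS clicks), non-sinusoidal physiological rhythms, and slow
nonstationarity of the optical contact. Results on synthetic data verify
the *computations*, not the physiological claims.

## Statistics

The unit of analysis is the single-event summary (mean normalized change
over the 6 s window), pooled across subjects for Welch two-sample t-tests
— matching event-count-scale comparisons — with the Welch–Satterthwaite
degrees of freedom. Degenerate inputs are defined rather than erroring:
identical constant groups give $t = 0, p = 1$; zero-variance groups with
different means give $p = 0$ with df clamped at $\min(n_A, n_B) - 1$.

`run_comparisons` produces the full condition matrix per signal: real vs
sham within each epoch/paradigm, post-cTBS vs post-iTBS for each
modality, and each post condition vs the pre-TBS baseline. Pre-TBS events
are pooled across paradigms only when neither the real-vs-real nor the
sham-vs-sham pre-paradigm test is significant at $\alpha = 0.05$ — the
same gate the original analysis applied — otherwise pooling is refused
with a warning. No multiplicity adjustment is applied and the output
labels all p-values as unadjusted.

For subjects who completed both paradigms, `fit_lmm` fits a linear mixed
model (REML, via `nlme`) of the event summaries on condition
(pre / cTBS / iTBS) with a random intercept per subject. The
cTBS-vs-iTBS contrast is obtained by refitting with a different reference
level rather than by post-hoc contrast algebra. p-values are Wald
normal-approximation by default; the fit's conditional-t p-values are
available via `method = "t"` (with ~600 events per cell the two are
indistinguishable). A fit with (near-)zero between-subject variance is
flagged `singular` and, if the mixed fit fails outright, estimates fall
back to pooled OLS with a zero random-intercept SD.

## Numerical choices and degenerate inputs

* Phase is handled in radians and unwrapped across distances before
  fitting, assuming adjacent-distance jumps below $\pi$ (true for
  physiological optical properties at these separations).
* Samples with non-positive intensities are marked invalid, never raised
  as errors; an empty recording yields an empty series.
* The inversion rejects samples with $|S_{AC}| \le S_{phase}$ (which
  would give $\mu_a \le 0$) or $S_{phase} \le 0$; the formula is
  continuous at that boundary ($\mu_a \to 0^+$).
* Events whose window runs past the recording end are dropped with a
  logged reason.
* Segment means are computed over valid window samples only.

## Problem sizes used in the checks

The package's own verification runs use: 1000-pair optical round trips;
400 seeded full-pipeline null sessions for the false-positive-rate check
(real-vs-sham after cTBS with all evoked amplitudes zero, target rate
0.05 at $\alpha = 0.05$); and 200 replicate crossover cohorts (5 subjects
× both paradigms) for effect recovery. In the recovery study each
replicate's ground truth is its own noise-free limit — the same schedules
and amplitudes run through the same pipeline with all noise off — because
the bandpass and the windowed mean deterministically attenuate the +14%
peak amplitude to ≈6.5% mean change, and each replicate's schedule
carries its own exact value of that attenuated contrast. The recovery
check is therefore an unbiasedness test of the stochastic pipeline
against its deterministic limit, not a comparison against the nominal
peak amplitude. The replicate cohorts exercise the chromophore-level
pipeline directly (generator → filter → segmentation → QC → LMM); the
optical forward/inverse stage, which is exact to $10^{-8}$ and is
exercised end-to-end elsewhere, is bypassed inside the replicate loop.

## Known limitations

* The forward model's $1/r^2$ geometry is self-consistent but idealized;
  applying the inversion to real semi-infinite-medium data relies on the
  same linearity holding approximately, as it does in practice over
  2–3.5 cm.
* Absolute concentrations depend on the extinction table and on the
  homogeneous-medium assumption; relative (percent) changes, the unit of
  all statistics here, are far less sensitive to both.
* Event summaries within a session share physiological noise, so they are
  not strictly independent; the randomized real/sham interleaving keeps
  the Welch comparison approximately calibrated (verified empirically by
  the false-positive-rate check), but the model-based standard errors do
  not capture schedule-level variability of the true contrast.
* No wavelet/spline motion correction, short-channel regression, or
  systemic-physiology regression is implemented; artifact handling is
  exclusion-based, as in the analysis chain this package reproduces.
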