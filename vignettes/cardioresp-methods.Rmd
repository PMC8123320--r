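---
title: "Estimating respiratory and heart rate from chest-worn strain and inertial sensors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating respiratory and heart rate from chest-worn strain and inertial sensors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The measurement problem

A chest-worn system carries two kinds of sensors on a shared 100 Hz
clock: four conductive-textile strain elements sewn into two elastic
bands (thoracic and abdominal) whose resistance — transduced through a
bridge and amplifier into a voltage — follows the cyclic expansion of
the rib cage, and a 9-axis IMU on the left upper chest whose
accelerometer and gyroscope x-axes pick up the mechanical vibration of
the heartbeat (seismocardiography, SCG, and gyrocardiography, GCG). A
reference device supplies a respiratory waveform at 25 Hz and a
single-lead ECG at 250 Hz. The task is to estimate respiratory rate
(RR) and heart rate (HR) from the wearable channels and to quantify
agreement with the reference.

Trials follow a fixed protocol: a ~10 s breath hold at end-inspiration,
three minutes of self-paced breathing, and a second 10 s breath hold.
The holds delimit the 180 s analysis segment; all rate estimates are
computed on it.

## Respiratory rate

The four strain-channel voltages are averaged pointwise into one
respiratory signal, then band-pass filtered 0.05–2 Hz with a
third-order Butterworth design applied forward–backward
(`filtfilt`-style zero-phase filtering, so inspiratory peaks are not
displaced). The low cut discards baseline drift; the high cut keeps
everything a plausible breathing rate can reach. Because the
strain-to-voltage calibration

$$y(x) = 0.12\,x^2 - 3.81\,x + 59.97, \qquad x \in [0, 10]\ \%\ \text{strain}$$

is strictly decreasing on its domain (vertex at $x = 15.875$),
inspiration *lowers* the voltage; the pipeline negates the fused signal
(`invert_strain`) so end-inspiration appears as a maximum.

**Whole-trial RR** is read off the Welch power spectral density of the
conditioned signal: the highest peak inside 0.1–1.5 Hz, times 60. The
segmenting parameters of the Welch estimator are not fixed by the
method's description, so the package chooses 60 s Hamming-tapered
segments with 50 % overlap, and zero-pads spectra to a 0.005 Hz grid
(0.3 breaths/min) so that sub-breaths-per-minute errors are
representable. Ties in the band maximum break toward the lower
frequency.

**Breath-by-breath RR** detects inspiratory peaks with two thresholds:
a temporal one — minimum peak separation equal to the period of the
whole-trial RR estimate, $60/\mathrm{RR}$ seconds — and an amplitude
one — 50 % of the RMS of the wearable signal over the segment (40 %
for the reference waveform, whose morphology differs). When two
candidates are closer than the separation, the taller wins
(tallest-first greedy pruning, the documented behaviour of the usual
`findpeaks` implementations). The separation is enforced on the sample
grid with one sample of slack, because peak positions are quantized to
the grid.

Two properties of this rule are worth knowing. First, it sits exactly
at the mean breath period: any breath whose interval jitters below the
mean — through rate variability or through peak-position noise on the
flat top of a quasi-sinusoidal signal — loses its shorter neighbour.
At the generator's default sensor noise this costs roughly a third of
the breaths; the downstream pairing step absorbs the loss. Second, the
original procedure included a manual inspection that removed
implausible detections; the package replaces it with an automated
filter that drops peaks implying an instantaneous RR above
90 breaths/min (`max_plausible_rr`).

Per-breath rates are $60/\Delta T[n]$ for consecutive peak intervals.
Wearable and reference breaths are then paired by greedy
nearest-neighbour matching (closest pairs first) within half the median
reference interval; each peak is used at most once, and a rate pair is
only formed across *consecutive* matched reference peaks, so a missed
or spurious breath drops out instead of producing a halved or doubled
rate. The matched pairs feed the mean absolute error (plain and
percentage form — the percentage averages per-breath ratios, not the
ratio of averages) and the Bland–Altman analysis: differences
$\Delta = f_{\mathrm{ref}} - f_{\mathrm{WS}}$, mean of differences
(MOD), and limits of agreement $\mathrm{MOD} \pm 1.96\,s$ with $s$ the
*sample* (n−1) standard deviation of the differences — the
conventional choice; the method's description does not state one.

## Heart rate

The cardiac channels are modelled as an amplitude-modulated carrier:
$s(t) = h(t)\cos(2\pi f_0 t) + \epsilon(t)$, where $h(t)$ is the
heartbeat activity and $f_0$ the carrier inside the SCG band. The
chain is: band-pass 0.7–20 Hz (removes bias, breathing motion and
high-frequency noise while keeping the carrier), amplitude envelope as
the magnitude of the analytic signal,
$h(t) = \sqrt{\Re(\hat s)^2 + \Im(\hat s)^2}$ — the standard envelope
definition — and a final 0.7–5 Hz zero-phase band-pass that removes
the envelope's bias and leaves the heart-beat envelope. The analytic
signal is built by the FFT construction (negative frequencies zeroed,
positive doubled); no installed package provides it, and it is the
core primitive of the method, so it is authored and tested here
against AM-demodulation identities.

**Whole-trial HR** is the highest Welch-PSD peak of the envelope inside
0.7–4 Hz, times 60, for the accelerometer x-axis, the gyroscope
x-axis, and — as reference — the 0.7–20 Hz band-passed ECG (its PSD
peaks at the R-wave repetition rate; envelope-processing the ECG
identically is exposed as the option `ref_hr_envelope`). No harmonic
correction is applied: if motion artifact pushes an envelope harmonic
above the fundamental, the harmonic wins, which is exactly the failure
mode that makes standing-posture accelerometer estimates unreliable.

**Short-time HR** slides 30 s windows with 50 % overlap (hop 15 s, so
a 180 s segment yields 11 windows) over the envelope and takes one HR
per window from the Hamming-tapered periodogram of that window,
zero-padded to a 0.1 beats/min grid (a 30 s window natively resolves
only 2 beats/min). The reference ECG is windowed identically so the
per-window errors are time-aligned.

All conditioning is applied to the *full* recording and the analysis
segment is cut afterwards: the zero-phase filters settle inside the
breath holds instead of corrupting the first breaths of the segment.
Amplitude assertions in the tests additionally exclude the first and
last 5 s.

## The synthetic-trial generator

No recordings are distributed with the system, so the package ships a
generator ([make_trial()]) that reproduces the statistical structure
the analysis relies on, with full ground truth (breath-peak times, beat
times, instantaneous rate profiles):

* **Breathing**: strain
  $x(t) = \text{offset} + \text{depth}\,(1 - \cos\varphi(t))/2$ with
  $\dot\varphi = 2\pi\,\mathrm{rr}(t)/60$; the rate profile is a smooth
  random walk (spline through 10 s knots) with standard deviation
  `rr_wander_sd`. During the two holds the strain stays at its
  end-inspiration value, and the phase is rescaled so the final hold
  starts exactly on a peak. Thoracic and abdominal bands share the rate
  but differ in depth (ratio 0.8) and a small phase lag (0.15 rad).
* **Sensor model**: each band strain drives two channels through the
  calibration polynomial above, plus white noise (`noise_sd_strain`)
  and a sinusoidal baseline drift below 0.05 Hz — inside the stop-band
  of the respiratory filter by design.
* **Cardiac**: $h(t)$ is a train of unit-area Gaussian bumps (50 ms
  width) at the beat instants — any pulse shape whose envelope has its
  fundamental at the beat rate would do; Gaussians are smooth and keep
  the fundamental dominant over its harmonics. The carrier default is
  10 Hz, well inside 0.7–20 Hz and above the 5 Hz envelope cut.
  The gyroscope x-axis carries the clean model plus a small breathing
  leakage (10 % of cardiac RMS — the carrier band-pass is designed to
  remove it) and white noise; the accelerometer x-axis additionally
  carries band-limited (0.3–6 Hz) motion artifact scaled per posture.
* **Reference**: a narrow pulse train at the beat times plus noise
  stands in for the ECG (R-peak timing only — no P/T-wave morphology),
  and the thoracic strain resampled to 25 Hz plus independent noise
  stands in for the reference respiratory waveform.

Noise and artifact magnitudes are not published for the real system,
so the defaults are a one-time calibration chosen on physiological
grounds: strain noise sd 0.3 voltage units against a ~5.7-unit
breathing amplitude (a clean bridge/amplifier chain), IMU noise sd 0.1
against a ~1.2 RMS cardiac signal, and motion-artifact levels 0.3
(supine), 1.5 (sitting) and 8 (standing) times the cardiac RMS — body
sway while standing dwarfs the milli-g seismocardiographic signal,
which is precisely why the gyroscope outperforms the accelerometer
there. These are study conditions, not fitted quantities; passing
recovery tests under them shows the pipeline is correct under its own
model, not that the hardware achieves these errors on humans.

Features of real data the generator does **not** emulate: beat-to-beat
HR variability (respiratory sinus arrhythmia) — the rate wander is
slow by construction; ECG morphology; posture-dependent signal
morphology changes (the real supine recordings changed shape enough to
need manual peak correction); sensor nonlinearity beyond the
calibration polynomial; clock skew between the two systems
(synchronized starts are assumed, and real data must be pre-aligned).

## Reproducibility and problem sizes

Every stochastic element sits behind one integer seed:
`sim_config(seed=)` derives deterministic substreams per generator
stage, so identical configurations give bit-identical trials. The test
suite runs cohorts of 20 trials per scenario for rate-recovery
properties and 20 randomized draws for the demodulation property
(carrier 6–18 Hz, modulator 0.7–2 Hz, RMS tolerance 3 % over the
central half); at 200 s and 100 Hz per trial this keeps the whole
suite under a minute while leaving the Welch estimator its intended
180 s segment. The brute-force cross-checks — full-record DFT argmax
for spectral peaks, exhaustive scan plus tallest-first pruning for
peak detection — run on traces up to 10^4 samples.

## Known limitations

* The temporal threshold at exactly the mean breath period makes
  detection recall sensitive to breath-interval variability (see
  above). This is faithful to the described procedure; applications
  wanting higher recall should shorten the separation, at the cost of
  deviating from it.
* Highest-peak-in-band selection has no harmonic guard; heavy artifact
  can return a harmonic of the true rate.
* The published per-subject supine RR table contains one gross outlier
  (a sensor pre-strain failure); its printed scenario average is
  arithmetically inconsistent with the printed per-subject entries by
  0.0175 breaths/min, which the aggregation tests surface rather than
  hide.
* Percentage errors are undefined for a zero reference rate; the
  pipeline errors out rather than imputing.
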