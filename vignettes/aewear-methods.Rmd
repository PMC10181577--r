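---
title: "Methods: simulating and classifying joint-wear acoustic emissions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and classifying joint-wear acoustic emissions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aewear)
```

## The problem

Articulating joints under load release high-frequency stress waves —
acoustic emissions (AE) — whose statistical character depends on the wear
mechanism at the contact: abrasion, adhesion, burnishing, the
burnishing-to-scratching transition, and scratching. A passive piezoelectric
sensor converts these stress waves into a voltage trace $V(t)$, which is the
source process convolved with the propagation path and the instrument
response, i.e. $V = S * G * R$ for a source train $S$, path $G$ and
instrument $R$. `aewear` implements the full analysis chain for
classifying the five wear regimes from single-channel AE: a generative
simulator of the five signatures, disjoint windowing, two competing signal
characterisations (a handcrafted feature bank and a deep wavelet scattering
transform), a twelve-model classification benchmark, and ReliefF feature
ranking.

Because curated recordings of all five regimes are not publicly deposited,
the package ships a seeded synthetic-data module as a first-class component:
every downstream stage is developed and validated against simulated
recordings whose qualitative structure follows the published description of
the five signatures.

## The signal model

`simulate_signal()` renders one recording in four stages:

1. **Event train.** Burst onset times are drawn either as a Poisson process
   (memoryless, sporadic events) or as a jittered periodic train (the
   "many cyclical envelopes per time frame" pattern of burnishing-type
   wear). The jitter is uniform within a fraction of the period.
2. **Burst rendering.** Each event is an asymmetric-exponential envelope
   $(1 - e^{-t/\tau_r})\,e^{-t/\tau_d}$, $\tau_r < \tau_d$ — the
   characteristic fast rise, peak, and transient decay of an AE hit —
   multiplied by a carrier: band-limited Gaussian noise ("rough" broadband
   bursts) or a fixed-frequency tone with random phase (smooth, narrowband
   bursts). Event amplitudes are mean-one log-normal around the class
   amplitude scale.
3. **Instrument chain.** The superposed train is convolved with a
   unit-peak-gain second-order resonator (300 kHz, damping ratio 0.2 — a
   moderately broadband resonant AE sensor), Gaussian sensor noise is added,
   and the sum passes the acquisition bandpass (100–600 kHz), which
   conditions signal and noise alike so recorded energy concentrates in the
   AE band.
4. **Sampling.** 2 MHz nominal ("paper" preset). The "desk" preset divides
   every frequency by ten (200 kHz sampling, 10–60 kHz band) while keeping
   the envelope time constants, preserving the burst phenomenology at a
   tenth of the sample count; all tests and examples run at desk scale.

Determinism is strict: `(seed, profile, response, duration, fs)` reproduces
every sample bit-for-bit, and `simulate_dataset()` derives per-recording
seeds from one master seed.

### Default class profiles

The five default profiles (`default_profiles()`) encode the qualitative
orderings the wear regimes are described by — adhesive quieter and smoother
than abrasive; the burnishing family fast and cyclical; scratching densest
and most intense — and make the classes differ chiefly in carrier band and
burst rate:

* **abrasive** — 800 bursts/s, heavily jittered periodic, amplitude 1.0,
  broadband 100–600 kHz;
* **adhesive** — 800 bursts/s, amplitude 0.45, tonal carrier (250 kHz), the
  smoother, quieter twin of abrasive;
* **burnishing** — 1500 bursts/s periodic (jitter 0.15), amplitude 0.5,
  tonal 155 kHz (narrowband emission from smooth sliding);
* **burnishing-to-scratching** — 1500 bursts/s, amplitude 0.8, tonal
  230 kHz;
* **scratching** — 2500 bursts/s Poisson, amplitude 2.0, broadband
  250–600 kHz.

Sensor noise is 0.05 V for all classes and is the **difficulty** axis: the
`difficulty` scalar multiplies every profile's noise floor. At difficulty 0
the classes are noise-free and separable by construction; difficulty 1 is
the nominal floor; around difficulty 8 the benchmark's mean handcrafted
accuracy falls to roughly the level reported for real recordings (~90%),
which we treat as the moderate operating point. Rates were chosen so that a
tenth-of-a-window burst spacing holds for the cyclical classes and so that
every 7.5 ms desk window contains events; amplitude dispersions (0.2–0.25)
keep within-class spread well below between-class amplitude gaps, which is
what makes the difficulty-0 dataset separable.

What the generator deliberately does **not** emulate: contact-mechanics
physics, multi-path propagation and attenuation, nonstationary drifts
within a recording, inter-session sensor-coupling variation, and
hit-triggered acquisition. Consequences for interpreting results are
discussed under *Known limitations*.

## Windowing

`window_signal()` slices a recording into `n_windows` (default 10)
contiguous, disjoint, equal windows of `floor(L / n_windows)` samples; a
remainder is dropped from the end so the equal-length contract always
holds. At full scale a 1,000,000-sample recording yields ten 100,000-sample
windows. Windowing is always per recording, never across pooled files.

## The handcrafted feature bank

`extract_all()` produces 19 named values per window: MAV, WL, ZC, SSC, RMS,
AR1–AR4, SampEn, Ceps, MFL, HFD, DFA, MF, PF, NP, SSI, VAR. Parameter
defaults live in `feature_params()`: a 1 µV threshold gates the counting
features (ZC, SSC, NP); sample entropy uses templates of length 2 with
tolerance 0.2·SD (Chebyshev distance, self-matches excluded); Higuchi uses
decimations up to `Kmax = 10`; DFA uses boxes 30 to 300 in steps of 10 with
first-order detrending of the integrated, mean-removed series; the AR model
is order-4 Burg in prediction form on the demeaned window; MF and PF come
from a Welch PSD (Hann, 4096-sample segments, 50% overlap, segment capped
at the window length); Ceps is the real-cepstrum maximum over quefrencies
1 to N/2.

Conventions for degenerate windows are explicit and tested: an all-zero
window has MF = PF = Ceps = 0; zero-variance windows return SampEn = 0 and
all-zero AR coefficients with an informational note; MFL of a constant
window is floored at `log10` of the smallest positive double. The waveform
length is the pure cumulative absolute difference — the counting threshold
does not gate it, since a gated variant has no standard definition. The
order-4 AR model contributes all four coefficients (`ar_emit = "last"`
reduces to the highest order only). Features are computed on raw windows;
the counting thresholds are in absolute volts.

Every feature is validated against an independent brute-force oracle
(explicit index loops over the definitions) to 1e-12 relative tolerance on
seeded random windows, and the fractal/complexity estimators are checked
against known exponents: DFA ≈ 0.5 on white noise and ≈ 1.5 on integrated
noise, Higuchi dimension ≈ 1 for a line and ≈ 2 for white noise, AR(1)
coefficient recovery within ±0.05.

## The wavelet scattering transform

`scattering_transform()` is a from-scratch two-order scattering network:
wavelet convolution, complex modulus, low-pass averaging, cascaded twice.
The configuration mirrors the study setup — Gabor wavelets, nominal
invariance scale 1 s, 8 wavelets per octave in the first bank and 1 per
octave in the second.

Numerical choices, each with its rationale:

* **Invariance capping.** A 1 s averaging support cannot exceed a 50 ms (or
  7.5 ms desk) window; the support is capped at the window duration with a
  one-time message, and each path is then globally average-pooled to a
  single value. A low-pass wider than the signal is ill-posed; capping
  yields the one-value-per-path behaviour the classifiers consume.
* **Periodic convolution.** Filtering is frequency-domain multiplication on
  the window period. We originally prototyped mirror padding, but any
  padding scheme injects boundary content of order (filter support /
  window) into every path, and measured circular-shift feature drift was
  ~10%; with periodic convolution the modulus envelopes are exactly
  covariant to circular shifts, the pooled features drift by ~0, and the
  transform is twice as fast. The wrap-around this admits affects a region
  of one filter support, like any padding choice, and the pooled features
  are insensitive to it.
* **Gabor bank geometry.** Centre frequencies are geometric at $2^{1/Q}$
  from just below Nyquist down to $1/T_\mathrm{eff}$; bandwidths put
  adjacent crossings near −3 dB. Each wavelet carries the standard
  DC-cancellation term so its response at zero frequency is exactly zero —
  without it a one-per-octave Gaussian leaks ~4e-3 of a constant input into
  first-order coefficients.
* **Littlewood–Paley equalisation.** A lone Gaussian per octave ripples by
  25–30% in its energy coverage, so each bank is divided by
  $\sqrt{\mathrm{LP}(f) + 0.01\,\max \mathrm{LP}}$; the equalised sum is
  within a few percent of unity across the passband and rolls off smoothly
  outside it, keeping the transform non-expansive.
* **Path pruning.** Second-order paths are kept when the second wavelet's
  centre frequency lies below the first wavelet's half-power bandwidth (the
  frequency-decreasing rule); other paths carry no energy.
* **Output.** `scattering_features()` concatenates one time-averaged value
  per path (S0, then S1 by descending frequency, then S2 lexicographically);
  a `log_transform` flag applies an elementwise log with a 1e-12 floor. The
  default is the raw averaged coefficients.

The pipeline is verified against a naive oracle that materialises every
path by explicit circulant-matrix convolution on 256-sample inputs, and by
property tests: zero/constant inputs, tone localisation, translation
stability, non-expansiveness, and order-wise energy decay.

## The classifier benchmark

`make_classifier_suite()` fixes the twelve configurations: a CART decision
tree; linear discriminant analysis; kernel naive Bayes (per-feature
Gaussian KDE, Silverman bandwidth); linear, quadratic and cubic SVMs
(one-vs-one, box constraint 1, polynomial kernels with `coef0 = 1`); fine,
medium and coarse Gaussian SVMs with kernel scales $\sqrt{P}/4$,
$\sqrt{P}$, $4\sqrt{P}$ for $P$ features; and 1-, 10- and 100-nearest
neighbour classifiers (Euclidean). All hyperparameters are overridable.
When the feature count approaches the training-set size the LDA pooled
covariance is singular; the implementation then projects onto the leading
principal components (99.9% of variance, capped at the within-class rank)
before the discriminant — the pseudo-linear behaviour expected of preset
LDA implementations. The fine-Gaussian SVM has no such remedy by design:
its kernel scale is intentionally "fine", and on a few hundred z-scored
scattering dimensions it underfits badly. This mirrors the reported
behaviour of the same preset on scattering features and is left as a
property of the preset.

`eval_protocol()` fixes the validation scheme: stratified 80:20 outer
split; stratified 10-fold cross-validation entirely inside the 80%
training partition; feature standardisation fitted on training rows only
(outer train for the held-out estimate, in-fold train for each fold).
Held-out accuracy on the 20% is the headline number; the CV mean is
reported alongside. Twelve-model columns aggregate as mean ± population
standard deviation (divide by N), the convention that reproduces published
mean ± SD rows from their per-model columns.

## ReliefF ranking

`relieff_weights()` implements multiclass ReliefF with k = 10 neighbours,
all instances visited (deterministic), Manhattan distance on
range-normalised features, and miss contributions weighted by the class
prior renormalised over the other classes. Plain Relief is binary-only;
ReliefF is the standard multiclass generalisation. Range normalisation
makes the weights invariant to positive rescaling of any feature. On the
default synthetic data the top of the ranking is dominated by fractal and
frequency features (typically HFD first with MF close behind), matching
the qualitative structure reported for real recordings, where frequency
features and fractal features fill the top ranks.

## The experiment driver

`run_experiment()` executes simulate → window → both feature tables →
benchmark → ReliefF → PCA, reproducibly from a config and master seed, and
can write `manifest.csv`, `features.csv`, `dws.csv`, `table2.csv`,
`ranking.csv`, `pca.csv` and `run.json` (seed plus a config hash). The
default configuration is desk-scale: 6 recordings per class of 0.075 s
(1500-sample windows, ten per recording, 300 windows in total — about the
scale implied by the published results' 2% accuracy granularity),
difficulty 1, the default feature bank, scattering and protocol settings.
These sizes keep a full run near two minutes on one core while leaving
every per-class sample size large enough for stratified 10-fold CV.

The PCA projection defaults to all five classes; a `pca_classes` argument
subsets the projection for four-class views.

## Known limitations

* The synthetic conditions are kind to the handcrafted bank: its features
  (RMS family, counting rates, spectral peaks, AR poles) nearly coincide
  with the generator's parameters, and the difficulty axis — stationary
  additive Gaussian noise — is a nuisance classical spectral estimators
  handle as well as band-averaged scattering energies. Across difficulties
  from the noise floor to far past the moderate operating point, the
  scattering pipeline's twelve-model mean tracks 1–3 points *below* the
  handcrafted mean on this generator; the acceptance suite states the
  expected real-data-analogue ordering (scattering ≥ handcrafted) and
  records its failure rather than hiding it. Reproducing the reported
  superiority of scattering features most likely requires the
  nonstationarities and deformations of real AE recordings, which additive
  noise does not emulate. Passing tests therefore validate the machinery,
  not the claim that scattering features win on real data.
* Windows from the same recording land in both training and validation
  partitions (the split is per window, as in the study protocol), so
  accuracies partly reflect within-recording similarity.
* The desk preset trades frequency resolution for speed; absolute feature
  values differ from full-rate values, while orderings and pipeline
  behaviour are preserved.
* `class::knn` breaks exact distance ties randomly; evaluation seeds the
  RNG, so results are reproducible, but tie behaviour is not
  platform-portable in pathological all-equal-distance cases.
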