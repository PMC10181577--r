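# aewear

Classification of joint-wear pathologies from acoustic-emission (AE)
signals.

Joints under load release high-frequency stress waves — acoustic emissions —
that a passive piezoelectric sensor records as a voltage trace
`V = S * G * R` (source train, propagation path, instrument response). The
statistical character of that trace depends on the wear mechanism at the
articulating contact. `aewear` implements a complete, reproducible analysis
chain for distinguishing five wear regimes (abrasive, adhesive, burnishing,
burnishing-to-scratching, scratching) from single-channel AE, aimed at
researchers in biotribology, orthopaedic condition monitoring and AE-based
diagnostics generally.

The chain comprises:

* **`simulate_signal()` / `simulate_dataset()`** — a seeded generator of the
  five wear signatures: Poisson or jittered-periodic burst trains, asymmetric
  rise/decay envelopes over band-limited carriers, a resonant-sensor
  instrument model with a 100–600 kHz acquisition bandpass, and a
  `difficulty` scalar that scales the sensor-noise floor.
* **`window_signal()` / `window_dataset()`** — disjoint windowing into equal
  slices (ten 100,000-sample windows from a 1,000,000-sample recording at
  the full 2 MHz rate).
* **`extract_all()` / `feature_table()`** — a 19-value handcrafted feature
  bank per window: MAV, WL, ZC, SSC, RMS, AR1–AR4 (Burg), SampEn, Ceps, MFL,
  HFD, DFA, MF, PF, NP, SSI, VAR.
* **`scattering_transform()` / `scattering_table()`** — a from-scratch
  two-order deep wavelet scattering (DWS) transform: Gabor filter banks with
  8 and 1 wavelets per octave, complex modulus, low-pass averaging, pooled
  to one coefficient per path.
* **`run_benchmark()`** — twelve classical classifiers (decision tree, LDA,
  kernel naive Bayes, six SVM presets, three KNN presets) under a stratified
  80:20 split with 10-fold cross-validation inside the training partition;
  per-model accuracies aggregate as mean ± population SD.
* **`relieff_weights()`** — multiclass ReliefF feature ranking.
* **`run_experiment()`** — the end-to-end driver with CSV/JSON outputs,
  plus `tidy()`, `glance()` and `autoplot()` methods for the result objects.

## A worked example

Simulate a small labelled dataset at the fast "desk" preset (all
frequencies scaled down tenfold), window it, and look at a few features:

```r
library(aewear)

ds <- simulate_dataset(2, duration = 0.075, seed = 7, preset = "desk")
ds
#> # A tibble: 10 x 4
#>   signal_id   class          seed signal
#>   <chr>       <fct>         <int> <list>
#> 1 abrasive_01 abrasive 2099865043 <ae_signl>
#> 2 abrasive_02 abrasive  496898524 <ae_signl>
#> 3 adhesive_01 adhesive 1046923970 <ae_signl>
#> # i 7 more rows

w <- window_dataset(ds, n_windows = 10)
round(extract_all(w$samples[[1]], fs = w$fs[1])[c("RMS", "MF", "PF", "HFD", "SampEn")], 4)
#>        RMS         MF         PF        HFD     SampEn
#>     0.1947 30266.6667 30266.6667     1.8906     0.4831
```

The first abrasive window has an RMS of about 0.19 V, its median and peak
frequencies sit near 30 kHz (the desk-scale sensor resonance inside the
10–60 kHz acquisition band), the Higuchi fractal dimension of 1.89 reflects
the broadband carrier, and the low sample entropy reflects the strongly
enveloped burst structure.

Aggregating a column of twelve per-model accuracies uses the population-SD
convention:

```r
aggregate_accuracies(c(82, 100, 78, 94, 94, 96, 90, 96, 92, 96, 80, 82))
#> # A tibble: 1 x 2
#>   mean_accuracy std_accuracy
#>           <dbl>        <dbl>
#> 1            90         7.16
```

A full experiment — both feature sets, twelve models, ReliefF ranking and a
PCA projection of the scattering features — is one call:

```r
report <- run_experiment(experiment_config(seed = 1, out_dir = "results"))
glance(report$benchmark)   # mean +/- SD per feature set and metric
tidy(report$relief)        # feature, weight, rank
autoplot(report$benchmark) # per-model accuracy bars
```

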