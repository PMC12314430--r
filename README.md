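# risetap

Amplitude rise-time extraction and sensorimotor-synchronization analysis
for spoken sentences.

## What this is for

Speech rhythm research often reduces a syllable's amplitude envelope to
two holistic numbers — **rise-time**, the duration from a local energy
minimum to the following maximum, and **rise-slope**, the energy gained
over that interval per second — and anchors behaviour to the **P-centre**,
the subjectively felt beat of the syllable, operationalized as **maxD**:
the point of maximal rise of a smoothed energy-difference contour. This
package implements the full analysis chain from raw audio and finger-tap
recordings to fitted regression models, for phoneticians and auditory
neuroscientists who want the procedure as tested, reusable code rather
than one-off scripts:

* **Energy chain** — raw energy (squared amplitudes, 40-ms window, 1-ms
  hop), fricative attenuation (zero-crossing rate > 7.5/ms → ×0.25),
  zero-phase moving-average smoothing (order 6), adjacent-frame
  differencing E_T − E_{T−1}, smoothing again (order 10), per-syllable
  argmax → maxD.
* **Rise-time / rise-slope** — per-syllable local energy maximum, backward
  slope-drop search (5-ms steps, 70% drop) for the rise foot, manual
  override hook for flagged cases; plus a Hilbert-envelope backend for
  cross-method comparison.
* **Syllable features** — metrical weight, onset complexity (categorical
  0/1/2), phonological sonority (0–9 scale), nucleus duration, relative
  intensity (ratio of mean dB), serial order, with the documented
  exclusion rules.
* **Tapping** — 5-ms latency correction, cycle folding with a 300-ms
  anticipation lead (first 2 of 15 repetitions discarded), Gaussian KDE at
  1/8 of the normal-reference bandwidth 1.06·min(sd, IQR/1.34)·n^(−1/5),
  peak picking with a 40% height threshold and 100-ms separation.
* **Asynchrony** — peaks anchored to maxD within ±120 ms; signed
  (negative = anticipation) and absolute asynchronies, medians by item.
* **Regression** — log transforms (ms scale), OLS with treatment
  contrasts, backward elimination with whole-factor blocks, nested-model
  F comparison, VIFs, standardized β, predictor correlations at α = 0.001.
* **Synthetic data** — sentence-like waveforms with known onset ramps,
  simulated tap trains with planted anchors/jitter/bias/misses, and
  feature tables from a planted linear model, so everything is testable
  end-to-end with ground truth. File formats: WAV, Praat TextGrid,
  Standard MIDI, CSV.

## Worked example

Two tones that differ only in their onset ramp (25 vs 50 ms), measured
through the full chain:

```r
library(risetap)
measure <- function(ramp_s) {
  w <- synth_tone(0.6, 500, ramp_s, 0.05, 0.8)        # 0.6 s, 500 Hz tone
  pad <- rt_wave(c(numeric(6615), w$samples, numeric(6615)), 44100)
  ch <- energy_chain(pad)                              # raw -> smoothed -> diff
  syll <- c(0.15, 0.75)
  md <- find_maxD(ch$difference, syll)                 # P-centre proxy
  m <- rise_measurement(ch$smoothed, syll, md)
  c(maxd_ms = md$time_s * 1000, rise_ms = m$rise_time_s * 1000,
    slope = m$rise_slope)
}
rbind(ramp25 = measure(0.025), ramp50 = measure(0.050))
#>        maxd_ms rise_ms slope
#> ramp25     166      65 4.911
#> ramp50     184      90 3.553
```

Both measured rise-times carry the same constant ~40-ms analysis-window
smear, so their *difference* recovers the true 25-ms ramp difference
exactly; maxD falls on the ramp, inside each rise interval; the longer
ramp has the shallower slope (rise-time and rise-slope are orthogonal).

The full synthetic pipeline (10 sentences × 8 syllables, 12 participants,
15 loop repetitions, 20-ms tap jitter, −30-ms anticipation bias, 10%
misses):

```r
cfg <- rt_config("run1", seed = 1)
fits <- run_pipeline(cfg)     # simulate -> acoustics -> sms -> models
item <- read.csv("run1/results/item_asynchrony.csv")
nrow(item); mean(item$median_signed_ms); mean(item$median_abs_ms)
#> [1] 80
#> [1] -29.9
#> [1] 29.9
```

80 syllables receive item-level asynchronies and the mean signed
asynchrony recovers the planted −30 ms anticipation bias. The rise-time
model after backward elimination (on this synthetic corpus rise-slope and
relative intensity survive; coefficient tables are written in the
conventional Factor/b/SE/t/CI/β layout):

```r
fits$rise_time$final
#> <rt_fit: log_rise_time_ms ~ rise_slope + rel_intensity, n = 79, R^2 = 0.813>
#>            term      b     se      t        p  ci_low ci_high beta_std
#> 1   (Intercept) -9.556 1.5694  -6.09 4.31e-08 -12.682  -6.431       NA
#> 2    rise_slope -0.463 0.0255 -18.15 2.39e-29  -0.513  -0.412   -1.015
#> 3 rel_intensity 13.533 1.4893   9.09 9.11e-14  10.566  16.499    0.508
```

One syllable is generated with a three-consonant onset and is excluded by
rule (see `run1/results/exclusions.csv`), mirroring the documented
practice. A command-line front end covers the same stages:

```sh
Rscript -e 'risetap::rt_cli()' all --out-dir=run1 --seed=1
```

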