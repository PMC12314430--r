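---
title: "Methods: envelope landmarks, tapping peaks, and the asynchrony models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: envelope landmarks, tapping peaks, and the asynchrony models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(risetap)
```

## The problem

Amplitude rise-time — the interval from a local minimum to the following
local maximum of a syllable's energy contour — is widely used as a holistic
acoustic signature of speech rhythm, and perceptual-centre (P-centre)
models place the subjective "beat" of a syllable near the point of maximal
energy rise. `risetap` implements, as a reusable and fully testable
pipeline, the analysis chain that connects these ideas to behaviour:

1. an **energy-contour chain** that derives a smoothed energy contour and
   its smoothed first difference from mono speech audio, and locates
   **maxD** (the per-syllable maximum of the difference contour) as the
   operational P-centre;
2. a **rise-time extractor** that finds the local energy maximum of each
   syllable and walks backward to the foot of the rise, yielding rise-time
   and rise-slope (with a Hilbert-envelope alternative for cross-method
   checks);
3. a **feature assembler** for the per-syllable predictors (metrical
   weight, onset complexity, phonological sonority, nucleus duration,
   relative intensity, serial order) with the documented exclusion rules;
4. a **tapping pre-processor** that turns looped finger-tap recordings into
   per-participant density peaks — the consistently anchored taps;
5. an **asynchrony module** anchoring tapping peaks to maxD landmarks
   within ±120 ms and aggregating signed/absolute asynchronies by item;
6. a **regression workflow**: full model, backward elimination,
   nested-model comparison, VIFs, standardized coefficients, and the
   predictor correlation matrix.

Because the original recordings and tapping data are external, a
**synthetic-data module** generates waveforms, tap trains and feature
tables with known ground truth; every downstream stage is validated
against that ground truth or against an independent brute-force oracle.

## The energy chain and maxD

For a waveform $x$ sampled at $f_s$, the raw energy contour is the mean of
$x^2$ in a 40-ms window advanced in 1-ms steps (frame centres at
$t = 0, 1, 2, \dots$ ms; edge windows truncated). Using the mean rather
than the sum keeps units interpretable; landmark *times* are identical
either way because the two differ by a constant factor on interior frames.

Fricative energy is attenuated before smoothing: frames whose
zero-crossing rate strictly exceeds 7.5 crossings/ms (computed on the same
40-ms windows, expressed per ms) are multiplied by 0.25. A pure sinusoid
of frequency $f$ crosses zero $2f$ times per second, so the threshold
corresponds to ~3.75 kHz — voiced material stays untouched, noise-like
frication does not.

Smoothing uses an order-$N$ moving average applied **zero-phase**: a causal
$N$-frame average run forward and (on the reversed series) backward, the
two passes averaged. The combined impulse response is symmetric over
$2N-1$ frames, so landmarks are not delayed — a causal filter would shift
every maxD by $N/2$ ms. Affine contour segments pass through unchanged in
the interior, and impulse mass is preserved. The energy contour uses
$N = 6$; the difference contour $D_T = E_T - E_{T-1}$ (first frame 0) is
smoothed with $N = 10$.

maxD is the argmax of the smoothed difference contour over frames whose
centres lie in the half-open syllable interval $[start, end)$, ties to the
earliest frame. This is deliberately exact (no tolerance): the acceptance
suite checks equality with an exhaustive scan on 1,000 random contours.

## Rise-time and rise-slope

The per-syllable **local energy maximum** is the highest smoothed-energy
frame in the syllable. One numerical refinement matters: on plateaued
syllables (sustained vowels, synthetic tones) the frame-exact argmax lands
on microscopic plateau ripple, anywhere on the plateau. Frames within a
relative tolerance of `1e-4` of the maximum are therefore treated as tied
and the earliest — the plateau onset — is taken. If the contour is still
within tolerance of its maximum at the last in-syllable frame, the syllable
is flagged as degenerate (still rising at its edge).

The **rise foot** is found by walking backward from the maximum in 5-ms
steps on the 1-ms contour grid and comparing the slopes of consecutive
steps: the foot is the first step boundary where the slope of the step
further from the maximum falls below 30% of the step nearer the maximum
(a "slope drop of more than 70%"), with the proviso that the nearer step
must actually rise — otherwise flat stretches would qualify trivially. A
zero or negative far-side slope under a rising near-side step marks the
foot immediately. The search is bounded by the previous syllable's energy
maximum (or the contour start). If no boundary qualifies, the
minimum-energy frame in the search range is returned and **flagged for
review**; flagged syllables are the machine analogue of the small fraction
of rise-times that required manual correction in practice, and a
corrections file (`sentence_id, syllable_idx, override_min_s`) can replace
any foot, marking the measurement `corrected`.

Rise-time is $t_{max} - t_{min}$; rise-slope is
$(E_{max} - E_{min}) / (t_{max} - t_{min})$, in energy units per second.
The rise interval must span the syllable's maxD; violations are flagged,
never silently accepted. Under amplitude scaling by $c$, rise-time is
invariant and rise-slope scales by $c^2$ (energy is quadratic in
amplitude) — both are property-tested.

The 40-ms analysis window smears both endpoints outward by a constant
(~20 ms each side plus a few ms of foot-detection offset), so *absolute*
rise-times of synthetic ramps are overestimated by a constant while
*differences* between ramps are recovered accurately; the acceptance suite
asserts 25 ± 5 ms for the 25 vs 50 ms ramp pair and weak monotonicity over
ramps of 10/25/50/100 ms.

### The Hilbert alternative

`hilbert_rise()` applies the same maximum/foot logic to the analytic-signal
magnitude. Two numerical choices were forced by experiment. First, the
low-pass must be **ripple-free**: a brick-wall FFT filter leaves Gibbs
ripple on envelope plateaus which the foot search misreads as rise feet,
so the filter is a Gaussian frequency response (monotone step response).
Second, the smoothing scale defaults to **50 Hz** — the upper edge of the
conventional 2–50 Hz amplitude-envelope band — not 10 Hz: a 10-Hz filter
smears a linear onset ramp by far more than the ramp itself, making ramp
durations unrecoverable, whereas at 50 Hz a linear ramp's duration is
recovered to about 10 ms while carrier ripple (≥ 2·f0 for any speech-like
f0) is fully removed. Heavier smoothing remains available via `cutoff_hz`.
A syllable whose envelope dynamic range is below 5% of its maximum is
flagged degenerate (e.g. a constant-amplitude tone has no rise to
measure). On a synthetic corpus the two backends correlate positively but
imperfectly — the same qualitative behaviour reported for real speech.

## Per-syllable features

Sonority uses a 0–9 scale anchored at voiceless stops (0) and open vowels
(9); intermediate classes follow a conventional sonority hierarchy
(voiced stop 1, affricate 1.5, fricatives 2/3, nasal 4, lateral 5,
rhotic 6, glide 7, close vowel 8) and are configurable, since published
work rarely prints its full table. Onset sonority is the mean over onset
consonants; onset-free syllables take the nucleus value.

Relative intensity is the mean frame intensity in dB over the nucleus
divided by the mean over the sentence, with 32-ms windows, the
conventional 2·10⁻⁵ Pa reference, and a silence floor 60 dB below the
sentence maximum excluded from the denominator. This is a ratio of dB
means (as in Praat-based practice), which is *not* invariant to global
gain — a known property of the measure, not of this implementation.
Silent or degenerate nuclei yield a measurement-failure flag and are
excluded, mirroring the documented practice of dropping such syllables.

`build_feature_table()` enforces the exclusion rules (3-consonant onsets;
intensity failures), recodes onset complexity as a categorical variable
with levels 0/1/2 (reference 0) and weight as weak/strong (reference
weak), and records every exclusion with its reason. The filters are
idempotent.

## Tapping peaks

Tap times are latency-corrected (−5 ms, clipping at zero with a warning)
and folded into repetition cycles: a tap up to 300 ms before a cycle onset
counts as an anticipation of that cycle, giving cycle-relative times in
$[-0.3, \mathrm{cycle} - 0.3)$ s; taps in the first two repetitions (the
instruction is to start tapping from the third) and beyond the last are
discarded in software so the protocol holds regardless of compliance.

The tapping density is a Gaussian KDE with **1/8 of the normal-reference
bandwidth** $1.06\,\min(\mathrm{sd}, \mathrm{IQR}/1.34)\,n^{-1/5}$,
with linear-interpolation quantiles — written out explicitly so no
statistical runtime is mandated, and verified against `stats::bw.nrd` to
1e-6. The density is evaluated on a 1-ms grid extended 4 bandwidths past
the data and integrates to 1 within 1%.

Peaks are strict local maxima (plateaus contribute their centre frame)
that reach at least 40% of the global maximum; peaks closer than 100 ms —
a physiological limit on distinct synchronized movements — are resolved
greedily from the highest down, earlier peak winning ties. The greedy
order implements the stated pairwise rule ("the higher of the two")
deterministically; an exhaustive greedy-by-height oracle confirms it.

## Asynchrony

A tapping peak anchors to its nearest maxD landmark when the distance is
within an inclusive ±120 ms; equidistant peaks go to the earlier landmark,
and a landmark attracting several peaks keeps the nearest (earlier on
ties). Signed asynchrony is peak minus landmark (negative = anticipation);
absolute asynchrony its magnitude. Item-level aggregation takes the median
over participants of the signed and of the absolute values
*independently* — the median of absolute values is not the absolute value
of the median, and the two feed different regressions. Anchoring is
translation-invariant and is checked against a brute-force assignment
oracle.

## Regression workflow

Rise-times and absolute asynchronies are natural-log transformed on the
millisecond scale (so a 20-ms rise-time maps to ≈ 3.0); signed
asynchronies stay raw. Each response gets a Shapiro–Wilk diagnostic.
Models are ordinary least squares with treatment contrasts (references:
weak, onset complexity 0). Backward elimination removes, one per step, the
term with the largest marginal p ≥ 0.05, testing categorical factors as
whole blocks (`drop1` F-tests), until all remaining terms are significant;
the final model is compared to the full model with a nested-model F-test
(the reported "likelihood-ratio test" convention when F and residual df
are quoted), with a chi-square LRT emitted alongside. Standardized
coefficients are computed post hoc as $b \cdot sd(x)/sd(y)$ per expanded
model-matrix column, which makes them invariant to predictor rescaling.
VIFs are $1/(1 - R_j^2)$ over the dummy-expanded matrix; perfect
collinearity reports `Inf` with a flag rather than an error. Predictor
correlations are Pearson with a multiple-test-adjusted α = 0.001.

## What the synthetic world does and does not establish

`synth_sentence()` builds syllables as a harmonic complex (f0 + 2
partials, so intensity and zero-crossing behaviour are speech-like) under
a piecewise-linear envelope: a known linear onset ramp to the peak at the
nucleus onset, a mild 15% amplitude decline through the nucleus (natural
vowels peak early and decline — and a perfectly flat plateau would make
the energy maximum ripple-dominated and physically meaningless), then a
linear decay. Fricative onsets use high-passed noise so the attenuation
branch is exercised; obstruent onsets get a 10-ms burst. There are no
formants, no coarticulation, and no f0 movement — so a
green test establishes that the *chain of rules* behaves as specified on
signals with known ground truth, not that the rules are perceptually valid
for real speech. `synth_taps()` plants anchors with Gaussian jitter, a
constant anticipation bias and Bernoulli misses; real tappers drift,
double-tap and lapse in ways this does not model. The pipeline defaults
are the stated experimental world: 10 sentences × 8 syllables, 12
participants, 15 repetitions (first 2 skipped), 20-ms jitter, −30-ms bias,
10% misses. In the corpus generator, onset ramps are mildly lengthened
with metrical weight and onset complexity so the rise-time regression has
real structure to recover; the tap simulator's anchors are the maxD
landmarks measured on the synthesized audio itself, so the asynchrony
ground truth is exact by construction.

`synth_feature_table()` plants a linear model over realistic predictor
ranges; with the default coefficients and `noise_sd = 0.5` the planted
signal explains a moderate share of response variance. It backs three
checks: 95% CI coverage at n = 452 (93–97% pooled over 200 replicates),
first-out elimination of a pure-noise predictor, and per-term retention at
roughly the α rate under a global null.

## Degenerate inputs and tie-breaks, in one place

* maxD / energy maximum: ties → earliest frame; empty syllable/contour
  overlap → error.
* Rise foot: no qualifying slope drop → minimum-energy fallback + review
  flag; flat Hilbert envelope (< 5% dynamic range) → degenerate flag,
  `NA` rise.
* Latency correction: negative times clip to 0 with a warning.
* KDE: fewer than 2 distinct tap times, or zero bandwidth → error
  ("degenerate distribution").
* Peak picking: empty result is legal; all invariants asserted post hoc.
* Anchoring: equidistant → earlier landmark; multiple peaks → nearest,
  then earlier.
* Elimination: may return the intercept-only model; "nothing dropped" is
  the df₁ = 0 edge case with no comparison p.
* Feature table: orphan join keys and unknown sonority classes are errors
  naming the offending rows/labels.

## Known limitations

The Praat-side conventions (exact intensity windowing, the original
study's ZCR window, whether its moving averages were causal) are not fully
published; the choices here are documented above and surfaced as
parameters. The pipeline aggregates by item, as the design it follows
does; no individual-differences modelling is attempted. Reproducing the
published coefficient tables requires the original corpus and tapping
data, which the package deliberately does not depend on — `run_models()`
emits the same table *layout* so that a re-analysis with those data drops
in unchanged.
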