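---
title: "Methods: from sperm whale clicks to habitat-use statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from sperm whale clicks to habitat-use statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cachalot)
```

`cachalot` turns single-hydrophone survey recordings and GPS sightings of
sperm whales into per-individual size estimates, aggregation tables with
habitat attributes, and the statistical battery used to describe habitat
use. This vignette explains the models, the tunable parameters, the
synthetic-data generator that makes the chain testable, and the numerical
and design choices — including the ones where more than one reasonable
option existed.

## 1. The click model and IPI sizing

A sperm whale click is a packet of pulses. The emitted sound reverberates
through the spermaceti organ: a weak direct pulse p0 is followed by the
dominant pulse p1 and decaying repetitions p2, p3. The pulse spacing — the
inter-pulse interval, IPI — is a two-way travel time through the head and
therefore scales with body length.

**Synthesis.** `synth_click()` models each pulse as a Gaussian-windowed tone
burst (default carrier at the centre of a 2–8 kHz band, effective duration
0.5 ms). This places the click energy above the 1 kHz analysis high-pass
while leaving the exact spectral shape, which the sizing chain never uses,
deliberately simple. Default relative amplitudes are
(p0, p1, p2, p3) = (0.3, 1.0, 0.45, 0.2): p1 dominant, monotone decay
afterwards. Ambient noise is white Gaussian; SNR is defined as p1 peak
amplitude over noise RMS in dB (a definition the package states explicitly
because field reports rarely do). An optional sub-1 kHz "vessel" component
exists to exercise the high-pass stage. Pulses are evaluated on the
continuous time axis, not snapped to the sample grid, so generator truth is
exact.

**Measurement.** `estimate_ipi_envelope()` measures p1→p2 on the smoothed
magnitude of the analytic (Hilbert) signal: p1 is the dominant envelope
peak, p2 the largest subsequent local peak in the search window, both
refined to sub-sample precision by a parabolic fit on the log-envelope
(exact for Gaussian pulses, since their log-envelope is quadratic). Two
gates guard against fabricated values, mirroring the manual protocol of
measuring only clicks whose pulses are clearly visible:

* a *quality* floor — p2/p1 prominence must reach 0.1;
* a *noise-floor* gate — p2 must exceed the search-window envelope median
  by 4 MADs.

When either fails the function returns a no-IPI result rather than a
number. `estimate_ipi_cepstrum()` is an independent cross-check: all pulse
spacings are multiples of the IPI, so the real cepstrum of a click window
peaks at the IPI quefrency; its quality score is peak dominance (one minus
the second-highest/highest peak ratio), which rejects featureless noise
cepstra.

Two defaults deserve comment:

* the p2 **search window is (1.5, 10) ms**, not (2, 10) ms. The 2 ms floor
  is an *acceptance* rule (falsely low IPIs arise from prolonged p1
  pulses), applied in `summarize_individual()`; the estimator itself must
  still be able to measure a visually confirmed calf at 1.90 ms. The 10 ms
  ceiling is the head-size bound.
* the estimator's **envelope smoothing is 0.25 ms**, wider than the 0.1 ms
  used for detection timing, because the p2 pick must be stable against
  envelope noise while p1 timing needs full resolution.

**Summaries.** `summarize_individual()` averages repeated measurements
(the protocol takes ~10 per individual), flags short series (`low_n`) and
high spread (`high_sd` above 0.2 ms — a package choice; the field practice
is "standard deviations were checked" without a number), rejects means
below the 2 ms floor unless `calf_confirmed`, and converts to length.

**Conversion.** `size_from_ipi()` applies the two published regressions —
quadratic below 4.250 ms, linear at and above. Their stated validity
ranges overlap on [4.184, 4.250] ms; the package switches strictly at
4.250 ms. Both curves give ≈ 11 m across the overlap; the maximum gap is
0.105 m at 4.184 ms, and the forward map jumps by ~0.09 m at the switch,
so lengths in (10.99, 11.08) m are not attainable — `ipi_from_size()` maps
that band to the switch point and is an exact inverse everywhere else.
Class thresholds (2.9 and 5.0 ms) resolve boundary equality into the
middle (female/juvenile-male) class; the conversion maps them to ≈ 9 and
≈ 12 m.

## 2. Detection and train classification

`detect_clicks()` assumes high-passed input (`highpass()`, a 4th-order
Butterworth run forward-backward, hence zero-phase — click times are not
shifted — with ~48 dB attenuation one octave below the 1 kHz cutoff).
Events are local maxima of the smoothed envelope above
`median + 6·MAD` — a robust threshold, chosen over mean + k·SD because the
clicks themselves are outliers of the amplitude distribution. Three rules
clean the raw maxima:

* **refractory** (2 ms): of two closer peaks the stronger survives;
* **pulse-dominance suppression**: a peak is dropped when a ≥ 1.5× larger
  peak lies within ±25 ms. This collapses the p0/p2/p3 satellites of a
  click onto p1 (the packet spans at most ~3 × 7.8 ms). Distinct clicks —
  even in the fastest buzzes or codas — have comparable amplitudes and are
  never suppressed. The known cost: a much weaker animal clicking within
  25 ms of a loud one is missed; on a single hydrophone that trade-off is
  unavoidable;
* a **local SNR gate** (6 dB against the Rayleigh envelope noise floor).

Stereo recordings are detected per channel and deduplicated within 0.5 ms,
keeping the higher-SNR event.

`segment_trains()` starts a new train whenever the gap exceeds 2 s — the
top of the regular-click ICI range; `classify_train()` applies, in
priority order: coda (3–20 clicks, 0.2–2 s duration, median ICI < 0.5 s),
buzz (median ICI 0.02–0.2 s), regular (median ICI 0.5–2 s), else unknown.
The coda test runs first because short fast series satisfy the buzz bound
too; the median-ICI < 0.5 s condition in the coda rule is what separates a
few-click coda from a short regular series, and a "coda" slower than that
is genuinely indistinguishable from regular clicking by rate alone —
stereotyped rhythm patterns, which field analysts also use, are out of
scope. `infer_behaviours()` encodes the ethogram: hunting requires regular
clicks *and* buzzes; socialising requires a coda; moving and resting are
visual-only; behaviours may co-occur.

## 3. Aggregations and habitat attributes

"Within 1 km of each other" is implemented as **single-linkage** connected
components per survey day (`cluster_aggregations()`): chaining matches the
field practice of merging nearby GPS points into one aggregation, and the
brute-force graph-components oracle in the test suite pins the behaviour
down. Complete linkage is available as an option for users who read the
rule as pairwise. Clustering never merges across days.

Distances use the haversine formula on a sphere of radius 6,371,000 m — a
planar approximation would be simpler but harder to verify against
independent implementations. Depth queries are bilinear in the grid, with
land (`NA`) neighbours degrading to nearest-cell and all-land queries
raising an error. Slope is the central-difference gradient magnitude over
±250 m (the ~500 m window of the survey protocol), reported unsigned, with
classes light < 10%, medium [10, 20), steep ≥ 20%. The *shelf rule*
returns an undefined slope when the two half-window directional slopes
along either axis exceed 5% with opposite signs — a ridge or plateau edge
where no single slope exists; undefined slopes propagate as missing and
drop out of slope analyses only. Distance to coast densifies the coastline
polyline to ≤ 50 m steps before the vertex sweep, so its error is well
under the 100 m the protocol requires.

Grids are square in *degrees* (`cell_m` metres along a meridian), which
makes the ESRI ASCII export/import exact; the metric anisotropy of a
degree of longitude is handled at query time, and the synthetic bathymetry
expresses its offshore profile in true metres.

## 4. The synthetic survey generator

`synth_survey()` is the package's ground-truth instrument. Its defaults
encode the study conditions of a five-month survey on a steep island
margin: 19 aggregations totalling 74 individuals (27 adult males, 31
females/juvenile males, 16 immatures), aggregation sizes 1–9 with median
4, one visually confirmed calf at IPI 1.90 ms, positions between the 1,000
and 2,000 m isobaths with hunting aggregations placed deeper
(1,500–2,000 m) than others (1,000–1,400 m), codas on two aggregations,
clean 96 kHz/24-bit recordings, regular trains with ICI ~ U(0.5, 2) s and
12 clicks per individual, and 24 survey dates from mid-January to mid-May
with male-heavy aggregations surveyed earlier (emulating male departure
from the breeding ground).

Within an aggregation, true IPIs are drawn inside per-class windows kept
0.15 ms clear of the class boundaries and separated by ≥ 0.3 ms
(a spacing-transform draw, so no rejection loops), which makes acoustic
individual discrimination well-posed — the field protocol likewise counts
individuals by distinguishable IPI/click shape. Individual trains are
time-multiplexed with 2.5 s guards (longer than the 2 s segmentation gap),
mirroring the analyst's practice of reading one animal's click series at a
time. Classes are dealt to aggregations by even interleaving, so mixtures
are balanced and the per-class IPI windows are never over-packed.

What the generator does *not* emulate — and what green tests therefore do
not show about real data: overlapping simultaneous clickers, propagation
effects (spreading loss, multipath beyond construction, surface echoes),
directional hydrophone gain, animal movement during a recording, coda
rhythm types, and IPI drift within an individual. Recovery results on the
synthetic scenes are upper bounds on field performance.

## 5. The statistical battery

All tests are two-sided at α = 0.05.

* `pearson_cor()`, `two_sample_lm()` (pooled-variance t as the
  group-coefficient test of a one-factor linear model — the pooled, not
  Welch, form matches fitting `lm`), `normality_check()` (Shapiro–Wilk).
* `poisson_glm()` with `overdispersion_check()`: dispersion ratio
  = Pearson χ² / residual df, upper-tail χ² p.
* `type2_deviance_test()`: likelihood-ratio χ² dropping each predictor
  (Type-II marginality); for a single predictor this is exactly the
  full-vs-intercept LR test.
* `lm_permutation_test()`: the response rows are permuted against the
  fixed design (B = 1,000 by default) and the observed overall F compared
  with the permuted ones; `p = (1 + #{F* ≥ F}) / (B + 1)`. The add-one
  convention keeps p ≥ 1/(B+1) and avoids p = 0; permuting the response
  (rather than residuals) is the standard exact scheme for a single
  design. Implemented via the thin-QR factor of the design, so a
  1,000-permutation test is a single small matrix product. Fully seeded.
* `holm_adjust()` / `pairwise_behaviour_test()`: sequential
  Bonferroni–Holm across all unordered group pairs of per-pair
  linear-model contrasts. Published tables of such contrasts are ambiguous
  about whether printed p-values are raw or adjusted, so the pairwise
  matrix reports both.

## 6. The pipeline

`run_full_analysis()` composes the chain: simulate (or read) → high-pass →
detect → segment/classify trains → per-click IPI → IPI-space clustering
into individuals (single-linkage, 0.15 ms tolerance) → per-individual
summaries → 1 km aggregation rule → habitat attributes → the four analysis
blocks (social structure, spatial distribution, habitat use, temporal
variation with the January–March / April–May period split). Records
without GPS are excluded (with a note); recordings are matched to
aggregations by same-day position within 1 km; historical-style records
without audio can enter with visual behaviours only, so hunting can never
be asserted without acoustics. Missing bathymetry skips the habitat and
spatial blocks with an explicit notice rather than failing. Every seed
derives from the config seed and is recorded in the report provenance;
re-running a config reproduces every table cell.

## 7. Problem sizes and numerical choices in the test suite

The suite verifies (sizes chosen to exercise each property while keeping a
full run around five minutes): exact reproduction of the printed
conversion values; IPI recovery on 200 seeded clicks (IPI U(2, 7.5) ms,
SNR U(10, 25) dB, 96 kHz) with mean absolute error ≤ 0.1 ms over the
measured clicks — the quality gates reject unclear ones, as the manual
protocol does; envelope–cepstrum agreement ≤ 0.1 ms on clean clicks;
exact classification of 300 in-regime trains; clustering equivalence with
a brute-force oracle on 200 random instances of up to 50 points;
permutation-test type-I calibration over 500 null datasets at B = 1,000
(rejection rate in [0.03, 0.07]); the Poisson dispersion identity
χ²/ratio = residual df on the 19-observation design and ratio → 1 at
n = 1,000; and full recovery of the default 19-aggregation / 74-individual
survey on clean audio (aggregation count exact, classes 100%, lengths
within 0.15 m).

Numerical details worth knowing: Hilbert transforms zero-pad to 2-3-5
smooth FFT lengths; envelopes are moving-average smoothed with
zero-padded ends; the detection threshold adds a 10⁻⁶-of-maximum floor so
noise-free synthetic audio does not trip on FFT ripple; WAV I/O is 16/24
bit linear PCM little-endian; cepstra add 10⁻¹² of the spectral maximum
before the log.

## 8. Known limitations

* Per-click IPI measurement degrades below ~12 dB SNR; the gates then
  reject many clicks rather than mis-measure, so low-SNR recordings yield
  fewer (not worse) measurements.
* The dominance-suppression window assumes one dominant animal locally;
  simultaneous comparable-level clickers are split across trains by ICI
  only, not by click shape.
* Codas slower than 0.5 s median ICI are classified as regular by design;
  rhythm-based coda typing is out of scope.
* Repeated sightings of the same animal across days are not deduplicated —
  the same open question field studies face; summaries are per-day.
* The aggregation rule's linkage (single vs complete) changes results for
  chained layouts; both are exposed, single-linkage is the default.
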