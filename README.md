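# cachalot

Passive-acoustic characterisation of sperm whale (*Physeter macrocephalus*)
aggregations from small-boat surveys. Sperm whale clicks are multipulse: the
sound bounces through the spermaceti organ, producing pulses p0, p1, p2, …
whose spacing — the inter-pulse interval (IPI) — scales with head and hence
body length. Click *rate* carries behaviour: regular clicks (inter-click
interval 0.5–2 s) mark echolocation search, buzzes/creaks (ICI 0.02–0.2 s)
mark prey-capture attempts, and codas (3–20 clicks over 0.2–2 s) mark
socialising. `cachalot` implements the full chain from WAV recordings and
GPS sightings to habitat-use statistics, plus a seeded synthetic-survey
generator so every stage can be verified against known ground truth.

The package is aimed at bioacousticians and marine ecologists working with
single-hydrophone survey recordings of odontocetes.

## The core models

**Body length from IPI.** Animal size (AS, metres) follows two published
regressions on the IPI (milliseconds), a quadratic for animals under ~11 m
and a linear one above:

    AS = 4.833 + 1.453·IPI − 0.001·IPI²   (IPI < 4.250 ms)
    AS = 1.258·IPI + 5.736                (IPI ≥ 4.250 ms)

Per-individual IPIs are the mean of ~10 envelope (p1→p2) measurements,
floored at 2 ms (falsely low IPIs arise from prolonged p1 pulses) unless a
calf is confirmed visually. Three classes follow: IPI < 2.9 ms (< 9 m)
immature; 2.9–5.0 ms (9–12 m) female or juvenile male; > 5.0 ms (> 12 m)
adult male.

**The acoustic ethogram.** Hunting requires regular clicks *and* buzzes on
the recording; socialising requires codas; moving and resting are
visual-only.

**Aggregations and habitat.** Sightings within 1 km of each other on one
survey day form an aggregation (single-linkage connected components).
Each aggregation gets bathymetry (bilinear from a depth grid), distance to
coast (densified-polyline haversine, sphere radius 6,371 km) and percent
seabed slope over a ±250 m window, classed light (< 10%), medium (10–20%)
or steep (≥ 20%), with ridge/plateau points left undefined.

**Statistics.** Pearson correlations, pooled-variance t-tests via `lm`,
Poisson GLMs with Pearson-χ²/df overdispersion checks and Type-II deviance
tests, seeded Monte-Carlo permutation linear models (1,000 resamples,
add-one p), Shapiro–Wilk residual checks, and sequential Bonferroni–Holm
pairwise contrasts.

## Worked example

Synthesise one click of a 3.85 ms-IPI whale at 18 dB SNR, detect it, and
size the animal:

```r
library(cachalot)

spec     <- click_spec(ipi_ms = 3.85, snr_db = 18)
click    <- synth_click(spec, t0 = 0.01, seed = 42, duration_s = 0.05)
filtered <- highpass(click)                      # 1 kHz zero-phase high-pass
events   <- detect_clicks(filtered)
m        <- estimate_ipi_envelope(filtered, events$time_s[1])
m
#> <ipi_measurement> 3.871 ms (envelope, quality 0.47)
summarize_individual(rep(m$ipi_ms, 10))
#> <individual_estimate> IPI 3.87 +/- 0.00 ms (n=10) -> 10.44 m, female_or_juvenile_male
```

The measured IPI sits 0.02 ms from truth; the 10.44 m estimate places the
animal in the female/juvenile-male class (9–12 m).

A whole synthetic survey — clean recordings of 4 aggregations (11
individuals) on a shelf-slope margin — run end to end:

```r
rules  <- survey_composition(
  class_counts = c(adult_male = 4, female_or_juvenile_male = 4, immature = 3),
  sizes = c(2, 3, 2, 4), n_clicks = 10, ici_s = c(0.5, 0.7))
report <- run_full_analysis(list(seed = 11, B = 1000, out_dir = tempfile(),
  simulate = list(n_aggregations = 4, composition_rules = rules)))
report
#> <analysis_report>
#>   aggregations: 4 (acoustically characterised: 4)
#>   individuals:  11
#>   IPI (ms): median 4.67, Q1 2.85, Q3 5.23, mean 4.06
#>   AS (m):   median 11.6, Q1 9.0, Q3 12.3, mean 10.7
```

All 11 generated individuals are recovered with their true classes; the
report carries the four analysis blocks (social structure, spatial
distribution, habitat use, temporal variation), e.g. the Holm-corrected
behaviour-versus-bathymetry contrasts:

```r
report$habitat$bathy_pairwise[, c("group1", "group2", "estimate", "t", "p", "p_adj")]
#>    group1      group2   estimate          t         p p_adj
#> 1 hunting      moving -167.12589 -0.6996887 0.5344961     1
#> 2 hunting socialising -202.08066 -0.6421581 0.5865526     1
#> 3  moving socialising  -34.95477 -0.1096800 0.9195884     1
```

(with only four aggregations nothing is significant, as it should be).

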