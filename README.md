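# gutmotion

Quantitative analysis of in vitro intestinal motility from spatiotemporal
(ST) maps — position × time matrices of gut diameter extracted from video
recordings of isolated intestinal preparations, such as those of the
agastric ballan wrasse, whose dilated anterior "bulbous" (Segment 1, ≈ 39%
of intestine length) is the main site of digestion.

The package is written for physiologists who already have calibrated
diameter matrices (one row per position along the gut, one column per video
frame) and want the standard motility read-outs:

- **Bulbous emptying time (BET).** Let AW1(t) be the mean diameter over
  Segment-1 positions at frame t and α the 5th percentile of the 14-h AW1
  series (linear-interpolation "type 7" quantiles). Frames with
  AW1 ≤ α mark an empty bulbous; BET is the time of the first such frame.
- **Analysis sub-periods.** Six standardized 30-min windows around BET:
  t1–t3 before it (period I, bolus present), t4–t6 after it (period II);
  when BET ≤ 1.5 h, all of period I is analysed instead.
- **Contraction detection and classification.** Constrictions are pixels
  whose relative diameter reduction against a rolling 95th-percentile
  baseline exceeds 7%; 8-connected regions of such pixels (gaps of one
  frame merged, events shorter than 1.7 s discarded) are events. An event
  propagating ≤ 1.0 mm is a *standing contraction*. Otherwise position is
  regressed on time along the constriction path: R² ≥ 0.8 gives a *ripple*,
  R² < 0.8 a *slow propulsive contraction*; velocity is |slope| and the
  slope sign gives the direction (positive = anterograde, toward the anus).
- **Motility summaries.** Per segment × period × contraction type:
  frequency in contractions·min⁻¹·mm⁻¹ (cpm), pooled medians of amplitude
  (%), duration (s), distance (% of length) and velocity (mm/s), and the
  anterograde share of directed propulsive events.

Because the source videos of such experiments are rarely deposited, the
package ships a calibrated synthetic-scenario generator
(`default_params()`, `simulate()` / `generate_scenario()`) that emulates
the study conditions — resting bulbous geometry, a bolus distending
Segment 1 until a drawn evacuation time, and contraction events of the
three archetypes with right-skewed parameter distributions — with full
ground truth, so every stage of the pipeline is testable end to end.

## Worked example

```r
library(gutmotion)

# six simulated cellulose-bolus preparations, full ground truth retained
scen <- simulate(default_params("cellulose"), nsim = 2, seed = 42)
a <- analyze_preparation(scen, 1)
a
#> <motility_analysis> cellulose_01 (cellulose)
#>   BET 0.725 h (alpha 5.342 mm)
#>   analysed 43 min (period I) + 90 min (period II) in 4 windows
#>   events: 6389 standing, 210 ripple, 512 slow propulsive
```

BET here is 0.725 h against a ground-truth evacuation time of 0.705 h —
the threshold rule recovers the emptying event to within a few coarse
(0.35 fps) frames. Because BET ≤ 1.5 h, period I was analysed as one
window covering all 43 min before emptying. The per-cell summary holds the
motility parameters; e.g. the Segment-1 period-I standing-contraction cell:

```r
s <- summary(a)
s[s$segment == 1 & s$period == "I" & s$kind == "standing",
  c("n_events", "frequency_cpm_mm", "amplitude_median", "duration_median")]
#>  n_events frequency_cpm_mm amplitude_median duration_median
#>      2165             1.48             47.3            1.71
```

i.e. 1.48 contractions per minute per mm of Segment-1 length (the
generator's nominal cellulose rate is 1.5), a median amplitude of 47.3%
diameter reduction and a median duration of 1.71 s (two detection frames).

For recorded data the entry point is `analyze_motility(dm)` where `dm`
comes from `read_diameter_matrix("prep.tsv")` (a TSV of diameters plus a
`prep.tsv.meta` sidecar with spacing, frame interval, time origin and
treatment). `render_st_map()` writes the ST-map PNG; `plot(a)` shows the
AW1 series with α and BET.

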