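# ordinalhrv

Ordinal-pattern complexity analysis of RR-interval (heart-rate-variability)
time series, built around the paired comparison of emotional states.

Emotional states modulate cardiac autonomic control, and the modulation
shows up in the *temporal structure* of the beat-to-beat RR-interval series,
not only in its variance. `ordinalhrv` quantifies that structure with two
ordinal-pattern measures and provides everything needed to run the analysis
end to end on a paired multi-state cohort (each subject recorded once per
state, each non-neutral state tested against the neutral baseline within
subject):

* **Ordinal core** — a series is embedded in windows of `D` values at delay
  `tau`; each window maps to the permutation ordering its values
  (`[3, 5, 2] -> "312"`). From the pattern frequencies `p(π)`:

  - permutation entropy `PE = -Σ p(π) ln p(π)`,
  - permutation min-entropy `PME = -ln max p(π)`
    (the order-∞ Rényi member; never exceeds PE),

  both in nats, bounded by `[0, ln D!]`, computed over a `D ∈ {3,4}`,
  `tau ∈ 1..10` grid (`entropy_sweep()`).
* **Preprocessing** — symlet-8 wavelet denoising (baseline-drift band
  zeroed, finest bands soft-thresholded), difference-threshold R-peak
  detection with ground-truth-validated constants, interval extraction, and
  rule-based artifact rejection with an audit report.
* **Synthetic cohort** — AR(1) state models with per-subject random effects
  generate a 60-subject × 6-state paired cohort (and optionally raw ECG with
  drift and noise), calibrated so between-state PE gaps match study-scale
  values; `calibrate_phi()` maps a target entropy back to the AR
  coefficient.
* **Statistics** — KS normality checks, paired Student's t-tests with
  `*`/`**` significance tiers, relative-increment sensitivity comparison of
  PE vs PME, and gender subgroup analysis.
* **Pipeline** — `run_study()` chains simulate → (optional ECG round-trip)
  → entropy → compare → increments with one config (R or YAML) and writes a
  hashed run manifest; reruns are byte-identical.

## Worked example

The eight-point series `{3, 5, 2, 1, 4, 8, 5, 6}` has six embedding windows
at `D = 3, tau = 1`, one of each possible pattern:

```r
library(ordinalhrv)
x <- c(3, 5, 2, 1, 4, 8, 5, 6)
d <- pattern_distribution(x, D = 3, tau = 1)
d$counts
#> 123 132 213 231 312 321
#>   1   1   1   1   1   1
round(permutation_entropy(d), 4)      # uniform over 6 patterns: ln 6
#> [1] 1.7918
```

A full synthetic study at the default (study-shaped) configuration:

```r
coh <- generate_cohort(cohort_config(seed = 1))   # 60 subjects x 6 states
tab <- entropy_sweep(coh, dimensions = 3, delays = 1)
cmp <- compare_states(tab)                         # vs neutral, paired t
writeLines(format_comparison_report(cmp[cmp$metric == "pe", ]))
#> pe  D=3 tau=1  happiness  1.7736 +/- 0.01 vs 1.7378 +/- 0.02  P=3.67e-20 **
#> pe  D=3 tau=1  sadness    1.7594 +/- 0.02 vs 1.7378 +/- 0.02  P=8.46e-10 **
#> pe  D=3 tau=1  anger      1.7645 +/- 0.01 vs 1.7378 +/- 0.02  P=5.43e-13 **
#> pe  D=3 tau=1  fear       1.7476 +/- 0.02 vs 1.7378 +/- 0.02  P=0.000905 **
#> pe  D=3 tau=1  disgust    1.7717 +/- 0.01 vs 1.7378 +/- 0.02  P=3.81e-20 **
```

Each line reads: state mean ± SD vs neutral mean ± SD of PE (nats), the
paired-test P-value, and its significance tier. Every non-neutral state is
more entropic than neutral, with the smallest shift for fear — the ordering
the generator is calibrated to. The sensitivity comparison shows why the
min-entropy is the sharper discriminator — its relative increment over
neutral is several times larger:

```r
inc <- relative_increment(tab)
inc[inc$state == "happiness", c("metric", "mean_percent", "se_percent")]
#>   metric mean_percent se_percent
#> 1     pe         2.07      0.153
#> 2    pme        11.75      0.877
```

See `vignette("ordinal-hrv-methods")` for the model, the calibration of the
state AR(1) coefficients, preprocessing constants, and what the synthetic
cohort does and does not emulate.

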