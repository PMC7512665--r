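---
title: "Ordinal-pattern entropy analysis of RR-interval series: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ordinal-pattern entropy analysis of RR-interval series: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Emotional states modulate cardiac autonomic control, and that modulation is
visible in the beat-to-beat variability of the RR interval — the time between
successive R peaks of the ECG. Classical time- and frequency-domain HRV
indices capture the magnitude of that variability; ordinal-pattern methods
instead quantify its *temporal structure*: how often each possible rank
ordering of nearby beats occurs. `ordinalhrv` implements this analysis for a
paired multi-state design in which every subject is recorded once per
emotional state (neutral, happiness, sadness, anger, fear, disgust) and each
non-neutral state is compared against the neutral baseline within subject.

## Ordinal symbolization, PE and PME

A series $\{x(t)\}_{t=1}^N$ is embedded in windows
$[x(t), x(t+\tau), \dots, x(t+(D-1)\tau)]$, giving $N-(D-1)\tau$ windows for
embedding dimension $D$ and delay $\tau$. Each window is mapped to the
permutation of its time positions that lists the values in ascending order;
for $D=3$ the window $[3,5,2]$ becomes `"312"` (third value smallest, then
first, then second). There are $D!$ such patterns. With relative pattern
frequencies $p(\pi)$,

* permutation entropy: $\mathrm{PE} = -\sum_\pi p(\pi)\,\ln p(\pi)$,
* permutation min-entropy: $\mathrm{PME} = -\ln \max_\pi p(\pi)$,

both in nats and bounded by $[0, \ln D!]$. PME is the order-$\infty$ Rényi
member of the same family, depends only on the most frequent pattern, and
never exceeds PE. Because PME reacts only to the dominant pattern it is the
more sensitive of the two when a weak temporal correlation concentrates
probability on one pattern — the property the state comparison exploits.

Labels use the time-position convention above; `pattern_to_ranks()` /
`ranks_to_pattern()` convert to the rank-vector convention used by several
other ordinal-analysis libraries (the two are inverse permutations).

Internally windows are coded vectorially through their Lehmer code
($c_j = \#\{k>j : x_k < x_j\}$, index $\sum_j c_j (D-j)!$), which needs only
$D(D-1)/2$ vectorised comparisons per series; the test suite checks this
engine exhaustively against a per-window sorting comparator.

### Ties

Integer-millisecond RR intervals can tie. Two policies are exposed:
`tie_policy("noise")` (default) adds a perturbation of amplitude
$10^{-6}\times$ the series SD under a fixed seed before ranking;
`tie_policy("stable-rank")` ranks tied values by time position and is
bit-exact. Whether tie-breaking noise was applied to the original recordings
is not documented in studies of this design, so neither policy is claimed to
reproduce anyone's unstated choice; the default is merely stated.

### Embedding grid and series length

With 300–400 intervals per recording, reliable frequency estimation
($N \gg D!$) restricts the analysis to $D=3$ (6 patterns) and $D=4$
(24 patterns); `entropy_sweep()` defaults to $D\in\{3,4\}$,
$\tau\in 1..10$. A warning (not an error) is emitted when $N<5\,D!$; a hard
error only when no window fits, and sweep cells that short are emitted as
flagged rows (`n_windows = 0`, `NA` entropies) rather than dropped. PE and
PME are reported unnormalized; divide by $\ln D!$ if a normalized value is
needed.

## The synthetic cohort generator

No recordings ship with this package, so every downstream stage is exercised
on synthetic data whose defaults mirror the study design: 60 subjects
(30 female, 30 male), six states, series lengths uniform on 300–400
intervals, mean RR 769 ms (78 beats/min), marginal SD 40 ms.

Each state is a stationary Gaussian AR(1),
$x_t = \mu + \phi\,(x_{t-1}-\mu) + \varepsilon_t$, whose single parameter
$\phi$ sets the temporal-correlation strength and therefore the ordinal
entropy. Two facts shaped the calibration:

* Mean PE at $D=3$, $\tau=1$, $n=350$ falls from about 1.787 at $\phi=0$
  toward about 1.727 as $\phi \to 1$ — the ordinal distribution of a random
  walk ($p_{123}=p_{321}=\tfrac14$, others $\tfrac18$, PE $=1.733$) is the
  limit. A positive-$\phi$ Gaussian AR(1) therefore **cannot** reach absolute
  PE levels near 1.68 observed in real neutral-state recordings.
* The between-state *differences* are what the paired analysis measures, and
  those are reachable.

The default `state_model`s are therefore calibrated so that the
**between-state mean PE gaps** at $D=3$, $\tau=1$ equal the study-scale gaps
(happiness $+0.0371$, sadness $+0.0231$, anger $+0.0264$, fear $+0.0103$,
disgust $+0.0352$ nats above neutral), anchored at $\phi_{\text{neutral}} =
0.90$: `calibrate_phi()` bisects $\phi \in [0, 0.999]$ against a
common-random-number Monte-Carlo mean (400 replicates, $n=350$), giving
$\phi =$ 0.90 / 0.4307 / 0.6438 / 0.5947 / 0.8006 / 0.4617 for
neutral / happiness / sadness / anger / fear / disgust. Targets below the
AR(1) floor raise a convergence error reporting the achievable bracket
rather than silently returning an endpoint.

Pairing is created by two subject-level random effects shared across a
subject's states: an additive mean-RR offset (SD 30 ms) and a shift of
$\mathrm{atanh}(\phi)$ (SD 0.15). The first gives the within-subject
correlation in interval level; the second adds between-subject entropy
heterogeneity. Even so, the synthetic marginal PE SD (~0.02 nats) is smaller
than the ~0.05–0.06 of real cohorts, because the $\phi \mapsto$ PE curve is
shallow near the anchor: real between-subject physiology is richer than one
AR coefficient. Consequences for what the tests can show are discussed
below. Positivity is enforced by redrawing innovations for intervals below
250 ms (up to 100 attempts) instead of clipping, so the interval distribution
keeps no atom at the floor.

Determinism: every generator is a pure function of (parameters, seed).
Cohort series use derived seeds
$(\text{seed} + 1000003\,k) \bmod (2^{31}-1)$ with the series counter $k$,
so any single series can be regenerated in isolation.

### Synthetic ECG

`generate_ecg()` places R peaks at cumulative interval times rounded to the
sample grid (1000 Hz default), renders each beat as a unit-amplitude Ricker
(Mexican-hat) kernel of 80 ms width — sufficient for a difference-threshold
detector; no P/T waves — and adds a sinusoidal baseline drift plus white
Gaussian noise at a configured SNR (dB, relative to the clean QRS-train
power). A flat 1 s lead-in/lead-out keeps true peaks away from the
detector's trimmed edges. Ground-truth peak indices travel with the record,
so detection can be scored exactly.

## Preprocessing

`denoise_ecg()` runs a periodized orthogonal symlet-8 DWT (implemented in
the package; perfect reconstruction is unit-tested to $10^{-9}$) after
symmetric-reflection padding. Two actions follow: the deepest approximation
band is zeroed — at 1000 Hz with 8 levels that band spans roughly 0–2 Hz
and carries the baseline wander — and the finest two detail bands are
soft-thresholded with the universal threshold $\sigma\sqrt{2\ln N}$,
$\sigma$ estimated by the MAD of the finest band. Depth 8 was chosen so the
discarded band sits below the heart-rate fundamental; the threshold rule is
the standard wavelet-shrinkage default.

`detect_r_peaks()` thresholds the first difference of the trace at 0.6
times its running maximum over a trailing 2 s window (computed by an O(N)
block prefix/suffix-cummax algorithm), floored at 30% of the record-wide
maximal absolute difference so that quiescent stretches — where the
trailing maximum reflects noise only — cannot fire. It refines each
crossing to the local
signal maximum within ±50 ms, enforces a 200 ms refractory period, and
ignores the first and last 0.5 s. These constants are package decisions in
the spirit of difference-threshold QRS detectors; they are validated against
generator ground truth (noise-free F1 = 1.0; F1 ≥ 0.99 at 20 dB SNR)
rather than asserted from literature.

`clean_rri()` replaces manual error-beat editing with an auditable rule:
intervals outside [250, 2000] ms or deviating more than 30% from the
11-point running median are dropped (or merged into a neighbour), and every
decision is listed in a rejection report. Real studies edit beats by hand;
the report exists precisely because the automated surrogate must be
reviewable.

## Statistical layer

Per (metric, $D$, $\tau$, state) cell, `compare_states()` pairs subjects
with their baseline values, excludes incomplete subjects pairwise (counted
in `n_excluded`), and applies the two-sided paired Student's t-test
($t = \bar d / (s_d/\sqrt n)$, $df = n-1$). Significance tiers follow the
usual convention: `**` for $P<0.01$, `*` for $P<0.05$. No multiple-testing
correction is applied across the (metric, $D$, $\tau$, state) grid — this
matches how such results are conventionally reported, and is a documented
limitation. Normality is checked per cell with a one-sample KS test against
$N(\bar x, s)$; because the parameters are estimated from the sample the
p-value is conservative (Lilliefors caveat, recorded in an attribute). When
either group fails at 0.05, a Wilcoxon signed-rank p-value is added as a
clearly-labelled fallback column; the parametric result remains primary.

`relative_increment()` computes the per-subject percentage change
$(E_s - E_n)/E_n \times 100$ and summarises mean and standard error across
subjects. Whether such increments should be per-subject-then-averaged or a
ratio of group means is ambiguous in most reports; both are implemented
(`method = "per_subject"` is the default, `"group_means"` uses a
delta-method SE) and the choice is an explicit argument.

`subgroup_analysis()` reruns the comparison within gender groups; a group
failing the preconditions is reported as insufficient without blocking the
others.

## What the simulation checks do (and do not) show

The acceptance-level tests run at these problem sizes, chosen as the
smallest sizes at which each property is meaningfully tested:

* exhaustive oracle agreement on all sequences of length ≤ 12 over
  {1, 2, 3} (vectorised through the module's own window coder, verified on a
  2000-sequence subsample through the public API) plus 1000 Gaussian series;
* estimator behaviour with 200 replicates at $n=400$ (the Miller
  finite-sample bias $\ln 6 - 5/(2\cdot 398)$ to 0.01 nats);
* preprocessing fidelity on a full 60 × 6 noise-free cohort at 1000 Hz and
  100 noisy replicates at 20 dB;
* test size under 200 null-cohort replicates, scored on a single
  happiness-vs-neutral PE cell per replicate so the binomial error band is
  exact (cells within one replicate share data and would be correlated);
* power at the study-scale effect ($\Delta = 0.037$ nats, marginal SD 0.05,
  ICC 0.5, 60 pairs) simulated at the entropy level, because — as noted
  above — the RRI generator's between-subject entropy SD is smaller than
  0.05, and the power claim is about the statistical layer at the stated
  variance, not about the generator;
* the PME-sensitivity property (PME relative increments exceed PE's for
  every non-neutral state) over 100 calibrated cohort replicates at
  $D=3$, $\tau=1$.

Passing these shows the machinery is correct and that the qualitative
PME-vs-PE sensitivity ordering emerges under an AR(1) cohort calibrated to
study-scale gaps. It does **not** show that real emotional RRI series are
AR(1) — they are not (respiratory sinus arrhythmia, Mayer waves and
nonstationarity all shape real ordinal distributions), which is exactly why
absolute synthetic entropy levels sit above real neutral-state values while
the between-state differences are matched.

## Numerical choices and degenerate inputs

* Natural logarithms throughout; $0\ln 0 \equiv 0$.
* A constant series has zero SD; the noise tie policy then falls back to an
  absolute perturbation scale of 1, making its pattern distribution uniform
  in expectation, while `stable-rank` yields the single ascending pattern.
* `paired_t_test()` and `ks_normality()` refuse zero-variance input with
  typed errors instead of returning NaN.
* The wavelet transform requires the padded length to be a multiple of
  $2^{\text{levels}}$ with at least 16 samples at the deepest level; records
  shorter than $2^{\text{levels}}$ samples are rejected.
* `run_study()` writes a manifest with MD5 hashes of every output; rerunning
  a configuration reproduces byte-identical tables.

## Limitations

* The generator spans entropy differences, not absolute levels, for $D=3$;
  matching absolute levels would require a richer generative law (e.g.
  oscillatory AR(2)), deliberately out of scope.
* No multiple-testing correction; significance tiers are per-cell.
* The ECG model has no P/T waves, arrhythmia, or respiratory modulation;
  detector constants are tuned for this morphology class and validated on
  it only.
* Entropy values at $D=4$ with $n\approx 350$ carry substantial
  finite-sample bias; comparisons remain valid because the bias is shared
  within a cell, but absolute $D=4$ values should not be read off as
  asymptotic entropies.
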