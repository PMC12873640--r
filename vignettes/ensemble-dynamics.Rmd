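---
title: "Methods: ensemble dynamics and inter-regional coactivation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ensemble dynamics and inter-regional coactivation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the models and procedures it
implements, the parameters that matter, the numerical conventions it fixes
where the underlying method leaves room, and what its validation on synthetic
data does and does not establish.

## The analysis model

The object of study is the *neuronal ensemble*: a small group of units within
one brain region whose coordinated firing at the ~20 ms timescale is taken to
carry specific information. The package represents an ensemble as a unit-norm
projection vector $w$ over the simultaneously recorded units of a region, and
tracks three questions: (1) which ensembles exist during each behavioral
template session, (2) whether an ensemble found during one session (here, the
extinction session of a fear-conditioning experiment) reappears in earlier or
later sessions, and (3) whether ensembles in different regions activate
together during NREM sleep, particularly inside fast network oscillations.

### Extraction

Per region and template session, unit spike counts are binned at 20 ms and
z-scored within unit. The correlation matrix of a population of $N$
uncorrelated units observed over $B$ bins has its largest eigenvalue near the
Marchenko–Pastur upper edge $\lambda_{\max} = (1+\sqrt{N/B})^2$; the number of
eigenvalues above the edge estimates the number of genuine co-activity
components. ICA then rotates the leading principal subspace into that many
projection vectors. The assumptions worth keeping in mind: stationarity of the
correlation structure within the template session, enough bins per unit
($B \gg N$; the binning warns otherwise), and ensemble activity that is
sparse and super-Gaussian, which is what the log-cosh ICA contrast favors.

### Activation and events

The activation strength of ensemble $w$ in a bin with z-scored population
vector $M$ is $M^\top P M$ with $P = ww^\top$, $\mathrm{diag}(P)=0$. Zeroing
the diagonal removes single-unit terms: a bin in which only one unit fires has
strength exactly zero, so events always reflect *co*-activation. Strengths
are z-scored by their NREM mean and SD, and events are strict local maxima
above 5 z.

### Cross-session similarity

Projection vectors from different sessions are compared by absolute cosine
similarity (the ICA sign is arbitrary). Because the null distribution of
$|\cos|$ between random vectors depends on dimensionality, the significance
threshold is built per rat and region: vectors from all three template
sessions are pooled, 5000 pairs are drawn with replacement, each vector's unit
ids are permuted independently, and the 99th percentile of the shuffled
$|\cos|$ values is the threshold. Categories follow from partners: maintained
(conditioning *and* retention), initiated (retention only), terminated
(conditioning only), transient (neither); preserved = maintained or initiated.

### Inter-regional coactivation

For every cross-region ensemble pair the cross-correlogram (CCG) of the two
z-scored activation traces is computed over ±100 ms (±5 bins), restricted to
NREM, never multiplying bins across NREM segment boundaries. The null
preserves each trace's autocorrelation but destroys fine-timescale
cross-correlation: 2-s chunks of one trace are permuted and the CCG peak
recomputed; a pair is coactivated when its observed peak exceeds the null's
99.5th percentile, making 0.5% the nominal chance level. This calibration is
the package's central quantitative check (see `scripts/acceptance.R`).

### Fast oscillations

Three detectors share one primitive: band-pass filter (zero-phase 4th-order
Butterworth), sliding-window RMS, z-score by NREM statistics, threshold runs,
filter by duration and peak, merge gaps, merge across channels, cap durations
at 750 ms. Parameters (band, RMS window, entry/peak thresholds, minimum
duration, merge gap) are fixed per detector at their standard values: SWR
ripples 100–250 Hz / 13.3 ms / 1.5 z entry / 4 z peak / 30 ms / 10 ms gaps,
with the additional requirement of a co-occurring sharp wave (2–40 Hz
superficial-minus-deep difference below −2.5 z for 20–400 ms, trough inside
the ripple) on the same shank; HFO 90–180 Hz / 20 ms / 2 z sustained 30 ms /
4 z peak / 20 ms gaps, on the per-shank median LFP; cRipple 90–180 Hz /
20 ms / 3 z / 5 z peak / 50 ms / 30 ms gaps, per channel. SWRs are reported
during NREM and wakefulness, HFOs and cRipples during NREM only. The *gain*
of an ensemble is its activation-event rate inside oscillation intervals
divided by its rate over all NREM time, so a gain of 1 means no modulation.

## Parameters and defaults

| parameter | default | unit | role |
|---|---|---|---|
| bin size | 0.020 | s | analysis timescale for binning, activation, CCGs |
| activation event threshold | 5 | z | peak height for activation events |
| contributor threshold | 2.0 | z (within-vector) | significant ensemble membership |
| similarity null draws | 5000 | pairs | per-rat/region threshold |
| similarity percentile | 99 | % | significance of $\lvert\cos\rvert$ |
| CCG lag range | ±0.1 | s | coactivation peak search |
| chunk length | 2 | s | shuffle unit for the null |
| shuffles | 500 | — | null sample size (the method leaves the count open; 500 gives ±0.1% resolution at the 99.5th percentile) |
| coactivation event threshold | 25 | z² | lag-aligned product peaks |
| jitter width | ±5 | ms | monosynaptic surrogate displacement |
| jitter replicates | 1000 | — | 99% global bands |
| CCG classification window | +1 to +4 | ms | monosynaptic lag range |
| FWHM fallback | >0.6 / <0.5 | ms | excitatory / inhibitory waveform widths |

## Numerical conventions

Where the method description leaves a choice, the package fixes one and keeps
it consistent:

* **Percentiles** everywhere use linear interpolation between order statistics
  in the type-6 convention, under which a fresh exchangeable draw exceeds the
  estimated p-th quantile with probability close to 1 − p, so shuffle-null
  thresholds realize their nominal levels.
* **Intervals** are half-open $[start, end)$; a bin belongs to a state when
  its center does. Duplicate spike times within a unit are collapsed.
* **ICA**: deflation-mode fixed-point iteration, log-cosh contrast, tolerance
  $10^{-6}$, at most 1000 iterations, seeded initialization; each vector is
  normalized and sign-fixed so its largest-magnitude element is positive.
  Units with zero template variance get an all-zero z-row and drop out of the
  decomposition naturally instead of propagating NaNs.
* **Peak plateaus** (activation and coactivation events) count once, at the
  first bin of the plateau.
* **Matched-bin z-scoring**: activation strengths outside the template are
  computed from per-unit statistics over the whole recording (configurable to
  template statistics). The method description leaves this open; whole-recording
  statistics keep strengths comparable across sessions, which the
  cross-session analyses need.
* **NREM z-basis**: all NREM epochs by default, restrictable to specific
  home-cage sessions.
* **Jittering**: only the target train of a pair is displaced. Displacing one
  train by Uniform(±5 ms) or both is distributionally equivalent only up to a
  doubled relative jitter width, so target-only preserves the stated ±5 ms
  scale exactly. Pairs with fewer than 50 reference spikes are skipped — the
  method states no floor, but percentile bands over 1000 surrogates are
  meaningless for a handful of coincidences; the floor is configurable.
* **CCG normalization**: Pearson-style (traces standardized over the NREM bins
  used, sums divided by the number of valid products). Peak height has no
  canonical units here; because significance is shuffle-relative, the
  scale convention cannot affect which pairs are flagged.
* **Chunk shuffling**: trailing partial chunks are dropped so chunk statistics
  stay homogeneous; the observed peak entering the significance comparison is
  computed on the same chunked bins as the null. The second trace of a pair
  is the one shuffled.
* **RMS windows** are centered, sample-step (sliding); "13.3 ms" is realized
  as `round(0.0133 * sample_rate)` samples. The stride is unstated in the
  source; sliding windows give smooth power traces and sub-window peak times.
* **Merged oscillation events** re-derive their peak time/power from the
  pointwise channel maximum over the merged span, and report the channel
  attaining it.
* **Exact signed-rank**: two-sided $p = 2\,P(W \le W_{obs})$ capped at 1,
  enumerated by dynamic programming over rank sums for $n \le 25$ (midranks
  doubled to stay integral); a tie-corrected normal approximation beyond.
  A note on the test form: a reported statistic of $T = 22$ for $n = 15$
  paired subjects is impossible for a rank-sum statistic, whose minimum is
  120 at those sizes; such a value identifies a paired signed-rank
  computation, which is what the package implements.
* **Fisher's exact test** reports the sample odds ratio $ad/bc$ alongside the
  conditional hypergeometric p-value; Bonferroni-adjusted p-values are
  truncated at 1.00.

## The synthetic-data generator

`synth_config()` defaults describe one desk-scale subject: three regions
(vCA1 12, PL5 40, BLA 24 units — proportions matching a mid-sized recorded
animal), 2 Hz Poisson background firing, the five-session behavioral schedule
(baseline, conditioning, context retrieval, cue retrieval/extinction,
retention) interleaved with home-cage periods whose bulk is NREM, compressed
to about one hour. Planted ensembles are 20 ms windows, aligned to the
analysis grid, in which member units receive +50 Hz of rate (25× background,
comfortably above the 5× regime where recovery is expected to saturate),
emitted at 0.5 Hz within each active session. The default plant spans all
four dynamic categories and includes one PL5–BLA coactivated pair at a 20 ms
lag. Monosynaptic couplings inject (excitatory) or thin (inhibitory) target
spikes 1–4 ms after source spikes. LFP channels carry pink (1/f power) noise —
chosen over white noise so band-power z-thresholds face realistic slow
variability — plus band-limited transients with a Tukey(0.2) envelope; the
flat-topped envelope makes a plant's nominal duration track the duration the
detectors actually measure on the smoothed power trace, which a Hann envelope
would understate. Sharp waves are injected as a low-frequency deflection on
the deepest channel so that the superficial-minus-deep difference swings
negative, as the SWR detector requires.

What the generator does *not* emulate: background correlations beyond planted
structure (real cortex is never i.i.d. Poisson), theta/spindle rhythms and
REM-specific dynamics, behavioral (freezing) signals, electrode drift, and
spike-sorting errors. Passing the suite therefore shows the pipeline is
correct and well-calibrated under its own statistical assumptions, not that
those assumptions hold in any particular recording.

## Validation scale and known limitations

The test suite runs the pipeline end to end on the one-hour default suite and
calibrates the coactivation null on 2000 simulated pairs with 30 minutes of
NREM each (500 shuffles per pair; the compiled chunk-pair decomposition makes
this a few minutes' work). Two properties of the method itself are worth
stating plainly, because the suite measures them:

* **Null Marchenko–Pastur exceedances.** The largest eigenvalue of a finite
  null correlation matrix fluctuates around the asymptotic edge on the
  Tracy–Widom scale, with roughly 12% of its mass above it at any matrix
  size. Using the plain edge — as the method prescribes — therefore yields
  one spurious (marginal) component in roughly one null dataset in eight,
  rather than never. Practitioners should treat a component count of 1 with
  an eigenvalue just above the edge with caution.
* **Chunk-permutation exactness.** The chunk-shuffle test is an exact
  permutation test when the shuffled trace's 2-s chunks are exchangeable
  under the null, which holds to excellent approximation whenever the trace's
  autocorrelation time is much shorter than a chunk. Activation-strength
  traces are nearly white at 20 ms bins (lag-1 autocorrelation below 0.02 on
  the default synthetic suite), far inside that regime, and the calibration
  utility simulates its surrogate traces accordingly
  (`calibrate_coactivation_null(ar = 0.1)`). With a finite number of
  shuffles the interpolated 99.5th-percentile threshold makes the realized
  level approximately 0.5–0.8% rather than exactly 0.5%.
* **HFO false positives.** Band-limited RMS power in a 20 ms window carries
  only $2BT \approx 3.6$ effective degrees of freedom, so on purely Gaussian
  background the HFO thresholds (2 z sustained 30 ms, peak 4 z) fire at
  roughly 0.5 events/min. The SWR detector is protected by the sharp-wave
  co-occurrence requirement and the cRipple detector by its stricter 5 z /
  50 ms rules (both measure ≲0.05 events/min on noise). HFO counts on real
  data should be interpreted against this noise floor, or gated on
  co-occurring events when purity matters.

Other limitations: template sessions are whole epochs (no sub-session
templates); no alternative assembly detectors (PCA-only, convolutional NMF);
no within-region coactivation or directed measures; sleep states are taken as
input labels, never scored.
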