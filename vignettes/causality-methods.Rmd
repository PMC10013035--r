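---
title: "Detecting directed physiological couplings: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting directed physiological couplings: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(causalphysio)
```

## The problem

During sleep, heart rate, breathing rate and cortical activity influence
each other through autonomic pathways whose strength and direction change
with sleep stage. `causalphysio` provides two complementary ways to detect
and quantify such directed couplings from time series, a testing framework
for both, and a pipeline that turns overnight three-channel recordings into
a small directed network per sleep stage and temporal resolution.

The two detectors are deliberately different in character:

* **Granger causality (G-causality)** models the data. A signal $z$
  G-causes $x$ if the past of $z$ improves the least-squares forecast of
  $x$ beyond what the past of $x$ (and, in the conditional version, of
  other signals) already achieves. It is parametric, requires
  stationarity, and supports a conditional form that separates direct from
  indirect links.
* **Bivariate Phase Rectified Signal Averaging (BPRSA)** does not model
  the data. Windows of the target signal are anchored at trigger events
  defined on the source signal (by default: the source rises) and
  averaged point-wise. Any systematic structure in the averaged curve
  indicates a relation; phase-aligned averaging makes the method robust to
  non-stationarities slower than the window length, but it cannot
  distinguish direct from indirect links.

## Nested autoregressive models and the G-value

For a model order $p$, the restricted and unrestricted models of a target
$x_t$ are

$$x_t = \sum_{i=1}^{p} \phi_i\, x_{t-i} + w^{(1)}_t, \qquad
  x_t = \sum_{i=1}^{p} \phi_i\, x_{t-i} + \sum_{i=1}^{p} \psi_i\, z_{t-i}
  + w^{(2)}_t,$$

each fitted by least squares on the identical rows $t = p+1,\dots,n$. With
residual standard deviations $\sigma^{(1)} \ge \sigma^{(2)}$, the G-value
is $G_{z \to x} = \ln(\sigma^{(1)}/\sigma^{(2)}) \ge 0$. The conditional
version adds the past of a third signal $y$ to **both** models, so that
only information beyond $y$ counts: $G_{z \to x \mid y} =
\ln(\sigma^{(3)}/\sigma^{(4)})$.

Design choices worth knowing:

* **No intercept.** All inputs are standardized (the pipeline standardizes
  every patch to zero mean, unit variance), matching models without a
  constant term. Consequently sub-patches accepted by the stationarity
  splitter are re-standardized before fitting.
* **Identical rows.** Both nested models use rows $t = p+1..n$, which the
  F-test requires; the test statistic is
  $F = \frac{(\mathrm{RSS}_1 - \mathrm{RSS}_2)/p}
  {\mathrm{RSS}_2/(n_\mathrm{obs} - k_u)}$ with $p$ numerator degrees of
  freedom and $k_u$ the number of unrestricted coefficients. A
  chi-squared variant ($pF$ with $p$ df) is available via `test = "chi2"`.
* **$\sigma$ normalization** uses $1/n_\mathrm{obs}$; the convention
  cancels in the ratio defining $G$.
* **Degenerate inputs.** A numerically perfect unrestricted fit with a
  non-trivial restricted residual (deterministic dependence) is reported
  as $G = \infty$, $p = 0$. Rank-deficient designs are flagged
  `collinear` with $p = 1$; constant series fall in this class.
* **Default order $p = 5$** for the benchmark experiments, chosen to cover
  the built-in coupling lags (3 in the two-node system, 2 and 4 in the
  common-driver system). Lag-0 (instantaneous) terms are never included:
  at physiological sampling rates a genuine effect needs at least one
  sample of delay, and instantaneous cross-talk would be read as
  causality.

## BPRSA and its significance tests

Trigger positions $t_\nu$ are the rises of the trigger signal
($z_{t_\nu} > z_{t_\nu - 1}$; any boolean criterion function can be
plugged in). Around each anchor a window of width $2L$ (default
$2L = 30$) of the *target* is taken; windows crossing a boundary are
discarded; the BPRSA curve is the point-wise mean of the $m$ surviving
windows. Under the no-coupling null the trigger positions are unrelated to
the target, each curve value is an average of many effectively random
samples, and the $2L$ values resemble a normal sample — so causality is
probed with normality tests (rejection ⇒ relation):

* `ad` (Anderson–Darling) and `sw` (Shapiro–Wilk) applied to the raw
  curve values in their composite forms (both are location-scale
  invariant). These are the strongest of the four.
* `ks1`: one-sided one-sample Kolmogorov–Smirnov against N(0,1) after
  standardizing the curve values *by their own sample mean and SD*. Both
  one-sided statistics are computed; the larger is reported with its own
  one-sided p-value. Estimating location and scale from the sample while
  keeping standard KS critical values is conservative (the Lilliefors
  effect), which makes `ks1` measurably weaker than `ad`/`sw` — by a
  factor of roughly 1.5–2 in critical coupling strength. A theoretically
  tempting alternative — scaling by $s_x \sqrt{m}$ under the independence
  assumption — is *not* used: the $2L$ windows overlap heavily and the
  anchors nearly exhaust the series, so that scaling is badly
  miscalibrated (measured null standard deviation ≈ 0.63 instead of 1,
  which would turn the test into a false-positive machine and invert the
  detector ordering).
* `ks2`: two-sample KS between the real curve and a curve recomputed at
  $m$ uniformly random anchors (`n_surrogate` pooled surrogate curves,
  default 1, seeded). On the 1/f benchmark this test has essentially no
  power anywhere below extreme couplings; it is retained for completeness.

The minimum useful window is enforced as $2L \ge 8$; with 64-sample
series and $L = 15$ nearly every window crosses a boundary, which is why
BPRSA cannot detect anything on very short series regardless of coupling
strength.

## Stationarity: ADF test and recursive splitting

G-causality needs stationary inputs. The package probes stationarity with
an augmented Dickey–Fuller regression containing a constant but no trend
term (patches are standardized to zero mean; genuine trend
non-stationarity should cause rejection, not be absorbed by the
regression): rejection of the unit-root null at `alpha = 0.05` counts as
stationary. The tau p-value is interpolated from the published
constant-case quantile table over both sample size and probability, and
clamped to $[0.01, 0.99]$ — ample for decisions at conventional levels;
the implementation's t-statistic agrees with an independent reference
implementation to full precision (see the test suite).

The splitting algorithm tries model orders 5, 4, 3 on all three channels
of a patch; the first order at which all three pass is accepted, and that
order is also used for the subsequent AR fits. If none passes, the patch
is split in half — the left half receives the extra sample for odd
lengths (an arbitrary but fixed convention) — and the procedure recurses.
Patches shorter than six samples (six times the temporal resolution, e.g.
90 s at 15 s resolution) are discarded as non-stationary. Six samples
cannot actually support an order-5 regression; such patches simply fail
the test and recurse/discard, so the floor acts as a hard stop rather
than a fitting guarantee.

## From raw recordings to node series

The pipeline does not process raw ECG or airflow waveforms; it takes
*event times* (heart beats, breath extrema) and a raw EEG trace:

* `rate_from_events()` converts inter-event intervals to instantaneous
  rates $1/\Delta t$, places them at interval midpoints, and interpolates
  (linear by default, previous-value optional) onto the integer-second
  grid.
* `eeg_alpha_amplitude()` band-passes 7.8–15.6 Hz with a zero-phase
  4th-order Butterworth filter, takes the analytic-signal magnitude (a
  rectified-amplitude alternative is selectable), and averages over
  non-overlapping 1 s windows. The first and last seconds carry filter
  edge effects.
* `coarse_grain()` block-averages the 1 Hz series to resolutions of 2,
  5, 10, 15, … seconds; the trailing partial block is dropped.
* `partition_by_stage()` cuts the aligned triple at sleep-stage changes
  (30 s epochs), drops wake, keeps only samples fully inside a run, and
  standardizes each channel per patch — in that order, so normalization
  is per patch, not global.

## Network reconstruction, weighting, surrogates

Per accepted stationary patch, the six conditional G-values (each ordered
pair, conditioned on the remaining channel) are computed at the accepted
order. Per directed pair, stage and resolution, the point estimate is the
**patch-length-weighted** mean while the bootstrap (100 resamples of the
patch set, **unweighted** mean per resample, SD of the resample means)
gives the standard error — this asymmetry is kept deliberately, with
`weighted_bootstrap = TRUE` available; edges with no surviving patches
are reported absent rather than zero. No multiple-testing correction is
applied across the 6 edges × stages × resolutions; significance is judged
against surrogate networks instead.

Surrogate networks recombine channels across subjects (a fixed cyclic
derangement: subject $i$ donates heart rate, $i+1$ breathing, $i+2$ EEG
amplitude; hypnogram from the heart-rate donor; channels truncated to the
shortest donor) so that no genuine coupling can survive. One caveat is
intrinsic and worth stating plainly: since $G \ge 0$ by construction,
*every* null edge has a small positive mean of order $p/(2 n_\mathrm{obs})$
(half a scaled $\chi^2_p$), while the bootstrap SE measures only
patch-to-patch spread. A surrogate edge therefore sits several SE above
literal zero even in the complete absence of coupling; the meaningful
comparison is the surrogate *level* against the real edges (in the
synthetic experiments below, surrogate means are under 5% of a planted
edge), not a z-score against zero.

## The synthetic sleeper

Real polysomnography is not distributable with the package, so
`synthetic_sleeper()` generates the three 1 Hz node series with a
hypnogram. Within each run of a stage, every channel is unit-variance
$1/f^{0.5}$ noise; directed couplings use the same lagged-mixture form as
the two-node benchmark (target $= q \cdot$ source noise shifted
$+ (1-q) \cdot$ own noise), with stage-dependent strengths and lags;
segment boundaries add mean and variance shifts, and an optional slow
random-walk trend makes individual segments non-stationary to exercise
the splitter. The generator emulates the *statistical* features the
pipeline cares about — 1/f-type spectra, stage-piecewise couplings,
nonstationarity across segments — and none of the waveform physiology
(no QRS morphology, no apnea events, no realistic spectral peaks), so
passing tests demonstrate that the pipeline recovers plantable structure,
not that it handles every artifact of real recordings.

## Benchmark experiments and the numbers behind them

Two generators drive the method-comparison experiments. The two-node
system couples $x_t = q\, z_{t-3} + (1-q)\, o_t$ with independent
unit-variance $1/f^{0.5}$ noises (Fourier-filtering generator: white
noise, spectral rescaling by $f^{-\alpha/2}$ with the DC component zeroed,
inverse transform, exact standardization; generated on a highly composite
FFT grid and truncated). The three-node system routes a driver $y$ into
$z$ (lag 2, strength $q_{y\to z}$) and $x$ (lag 4, strength $q_{y\to x}$)
with no direct $z \to x$ term.

* **Detection isolines.** For each series length, each detector's
  p-values are averaged over 20 realizations per coupling-strength grid
  point (24 log-spaced points in $[0.005, 0.95]$ by default; per-cell
  seeds derived from a master seed by a deterministic hash), and the
  critical coupling is the log-interpolated crossing of mean p = 0.05.
  Rejection-fraction aggregation is available as an alternative. The
  bootstrap band resamples the 20 realizations 100 times. Typical
  outcome at $N = 2^{14}$: critical $q \approx 0.03$ for the F-test,
  0.06–0.08 for AD/SW, ~0.13 for the one-sided KS, nothing for the
  two-sample KS; the F-test's critical coupling falls roughly like
  $N^{-1/2}$.
* **Region classification.** At $N = 2^{15}$, each cell of the
  common-driver coupling grid is classified by the majority outcome of
  20 realizations: neither test rejects (Region 1), pairwise only
  (Region 2 — the correct identification of an indirect link), both
  (Region 3 — a spurious direct link). Along the diagonal the Region-2
  window opens near coupling product ~0.013 and closes near ~0.08 in
  this implementation.

A limitation surfaces at strong couplings: an order-5 AR model cannot
fully capture $1/f^{0.5}$ long-memory, so residuals keep weak
autocorrelation and the F-test overrejects slightly (measured ~0.088 at
$n = 2^{12}$ on 1/f inputs vs 0.050 on white inputs). At large $n$ this
is exactly the mechanism that opens Region 3 — the conditional test
starts rejecting although no direct link exists — and in this
implementation Region 3 begins at weaker couplings (diagonal product
~0.08) than a reading of "very tightly coupled" might suggest. The
type-I calibration checks in the test suite therefore use white noise
for the F-test (where the test's assumptions hold) and the 1/f benchmark
for the BPRSA tests (which are insensitive to this issue).

## Problem sizes used in the checks

The packaged checks run at desk scale, chosen to keep the full suite in
the minutes range while leaving each claim clearly resolvable: isoline
ordering at $N = 2^{12}$ and sensitivity ratios at $N = 2^{14}$ with 20
realizations per cell; the F-test scaling fit over $N = 2^8..2^{16}$;
the region boundary on a 10-point diagonal product grid $[0.005, 0.08]$
at $N = 2^{15}$; null calibration on 800–1000 realizations; pipeline
recovery on 10 cohorts of three synthetic sleepers (140 epochs each,
planted coupling 0.5).

## Known limitations

* Linear G-causality only; no spectral, time-varying or nonlinear
  extensions.
* BPRSA has no conditional form; it cannot separate direct from indirect
  links.
* The ADF p-value is table-interpolated and clamped to $[0.01, 0.99]$;
  decisions far from conventional levels should not lean on its exact
  value.
* The 6-sample patch floor is a stop rule, not a guarantee that an
  order-5 model is estimable on the shortest surviving patches (they are
  effectively rejected by the rank check instead).
* G-value means are positively biased by $\sim p/(2 n_\mathrm{obs})$
  under the null; compare against surrogate levels, not against zero.
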